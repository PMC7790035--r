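#' @useDynLib crosstrait, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats pnorm qnorm optim quantile lm coef sd median rnorm runif
#' @importFrom utils head
"_PACKAGE"

.VALID_ALLELES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Default column mapping for summary-statistics files
#'
#' Maps the canonical internal field names to the column names expected in a
#' delimited summary-statistics file. Override individual entries to read
#' files with other headers, e.g. `sumstats_columns(p = "PVAL")`.
#'
#' @param snp_id,chrom,pos,a1,a2,z,beta,se,n,p column names in the file.
#' @return Named character vector of column names.
#' @export
sumstats_columns <- function(snp_id = "SNP", chrom = "CHR", pos = "BP",
                             a1 = "A1", a2 = "A2", z = "Z", beta = "BETA",
                             se = "SE", n = "N", p = "P") {
  c(snp_id = snp_id, chrom = chrom, pos = pos, a1 = a1, a2 = a2, z = z,
    beta = beta, se = se, n = n, p = p)
}

#' Read and validate GWAS summary statistics
#'
#' Reads a delimited text file of per-SNP association records into a
#' validated `sumstats` table. A signed z-score is required, either directly
#' or derivable as `beta / se`; the two-sided p-value is derived from z when
#' absent. Rows failing validation (missing alleles, non-ACGT alleles,
#' identical alleles, non-positive position, non-finite z) are dropped with a
#' reported count. p-values of zero (or below `p_floor`) are clamped to
#' `p_floor`, and z is capped at the matching normal quantile.
#'
#' @param path path to a (optionally gzipped) delimited text file.
#' @param column_map named vector from [sumstats_columns()].
#' @param sep field separator; `"auto"` lets `data.table::fread` sniff it.
#' @param p_floor smallest representable p-value (default `1e-300`).
#' @return A `data.table` of class `sumstats` with columns
#'   `snp_id, chrom, pos, a1, a2, z, n, p`.
#' @export
read_sumstats <- function(path, column_map = sumstats_columns(), sep = "auto",
                          p_floor = 1e-300) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = c("NA", "", "."))
  required <- c("snp_id", "chrom", "pos", "a1", "a2")
  for (f in required) {
    if (!column_map[[f]] %in% names(dt))
      stop("missing column ", column_map[[f]])
  }
  has <- function(f) column_map[[f]] %in% names(dt)
  if (!has("z") && !(has("beta") && has("se")) && !has("p"))
    stop("need a Z column, or BETA and SE columns, or a P column")

  out <- data.table::data.table(
    snp_id = as.character(dt[[column_map[["snp_id"]]]]),
    chrom  = as.character(dt[[column_map[["chrom"]]]]),
    pos    = as.numeric(dt[[column_map[["pos"]]]]),
    a1     = toupper(as.character(dt[[column_map[["a1"]]]])),
    a2     = toupper(as.character(dt[[column_map[["a2"]]]]))
  )
  if (has("z")) {
    out[, z := as.numeric(dt[[column_map[["z"]]]])]
  } else if (has("beta") && has("se")) {
    out[, z := as.numeric(dt[[column_map[["beta"]]]]) /
          as.numeric(dt[[column_map[["se"]]]])]
  } else {
    stop("missing column ", column_map[["z"]],
         " (and no ", column_map[["beta"]], "/", column_map[["se"]],
         " pair to derive it)")
  }
  out[, n := if (has("n")) as.numeric(dt[[column_map[["n"]]]]) else NA_real_]
  out[, p := if (has("p")) as.numeric(dt[[column_map[["p"]]]])
             else 2 * stats::pnorm(-abs(z))]

  n0 <- nrow(out)
  keep <- !is.na(out$snp_id) & !is.na(out$pos) & out$pos >= 1L &
    out$a1 %in% .VALID_ALLELES & out$a2 %in% .VALID_ALLELES &
    out$a1 != out$a2 & is.finite(out$z) & !is.na(out$p) & out$p <= 1
  dropped <- n0 - sum(keep)
  if (dropped > 0)
    message(dropped, " row(s) dropped during validation")
  out <- out[keep]
  out <- unique(out, by = "snp_id")
  if (nrow(out) == 0) stop("no rows survived validation: ", path)

  clamp_sumstats(out, p_floor = p_floor)
}

# Clamp p to the floor and cap |z| at the equivalent quantile.
clamp_sumstats <- function(s, p_floor = 1e-300) {
  n_clamped <- sum(s$p < p_floor)
  if (n_clamped > 0) {
    warning(n_clamped, " p-value(s) clamped to floor ", p_floor)
    s[p < p_floor, p := p_floor]
  }
  z_cap <- stats::qnorm(p_floor / 2, lower.tail = FALSE)
  s[abs(z) > z_cap, z := sign(z) * z_cap]
  data.table::setattr(s, "class", unique(c("sumstats", class(s))))
  s[]
}

#' Construct a sumstats table in memory
#'
#' Convenience constructor used by the simulator and in tests; applies the
#' same validation invariants as [read_sumstats()].
#'
#' @param snp_id,chrom,pos,a1,a2,z,n vectors of equal length.
#' @param p two-sided p-values; derived from `z` when `NULL`.
#' @param p_floor smallest representable p-value.
#' @return A `sumstats` data.table.
#' @export
sumstats <- function(snp_id, chrom, pos, a1, a2, z, n, p = NULL,
                     p_floor = 1e-300) {
  s <- data.table::data.table(
    snp_id = as.character(snp_id), chrom = as.character(chrom),
    pos = as.numeric(pos), a1 = a1, a2 = a2, z = as.numeric(z),
    n = as.numeric(n),
    p = if (is.null(p)) 2 * stats::pnorm(-abs(as.numeric(z))) else p)
  if (anyDuplicated(s$snp_id)) stop("duplicate snp_id")
  if (any(s$p > 1 | s$p < 0)) stop("p outside [0, 1]")
  clamp_sumstats(s, p_floor = p_floor)
}

#' Default long-range LD exclusion mask
#'
#' Intervals conventionally removed before building empirical FDR lookup
#' tables: the extended MHC (chr6:26-34 Mb) and the chr8p23.1 inversion
#' (chr8:7-13 Mb). Coordinates are 1-based inclusive.
#'
#' @return A data.table with columns `chrom, start, end`.
#' @export
default_exclusion_mask <- function() {
  data.table::data.table(chrom = c("6", "8"),
                         start = c(26e6, 7e6),
                         end   = c(34e6, 13e6))
}

#' Read a BED file as a region mask
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' 1-based inclusive convention.
#'
#' @param path BED file (first three columns used).
#' @return A region-mask data.table (`chrom, start, end`).
#' @export
read_region_mask <- function(path) {
  bed <- data.table::fread(path, header = FALSE)
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns")
  data.table::data.table(chrom = sub("^chr", "", as.character(bed[[1]])),
                         start = as.numeric(bed[[2]]) + 1,
                         end   = as.numeric(bed[[3]]))
}

#' Remove SNPs falling inside masked regions
#'
#' Membership is inclusive at both interval ends.
#'
#' @param s a `sumstats` or harmonized-pair table with `chrom` and `pos`.
#' @param mask region mask (`chrom, start, end`, 1-based inclusive), e.g.
#'   [default_exclusion_mask()].
#' @return The table without SNPs inside any mask interval.
#' @export
exclude_regions <- function(s, mask = default_exclusion_mask()) {
  if (is.null(mask) || nrow(mask) == 0) return(s)
  stopifnot(all(mask$start <= mask$end), all(mask$start >= 0))
  chrom_plain <- sub("^chr", "", as.character(s$chrom))
  drop <- rep(FALSE, nrow(s))
  for (i in seq_len(nrow(mask))) {
    drop <- drop | (chrom_plain == sub("^chr", "", mask$chrom[i]) &
                      s$pos >= mask$start[i] & s$pos <= mask$end[i])
  }
  s[!drop]
}

#' Harmonize two summary-statistics sets onto shared SNPs
#'
#' Inner-joins two traits on `snp_id` and aligns trait B's z-score to trait
#' A's effect allele: if B reports the same allele pair the z-score is kept;
#' if the alleles are swapped the z-score is negated; strand-complemented
#' records are complemented before matching. Strand-ambiguous SNPs (A/T,
#' C/G) cannot be oriented without allele frequencies and are dropped by
#' default. SNPs whose allele sets cannot be reconciled are dropped.
#'
#' @param a,b `sumstats` tables.
#' @param drop_ambiguous drop A/T and C/G SNPs (default `TRUE`).
#' @param min_shared emit a warning below this number of shared SNPs.
#' @return A `harmonized_pair` data.table with columns
#'   `snp_id, chrom, pos, a1, a2, z_a, z_b, n_a, n_b, p_a, p_b` and a
#'   `drop_counts` attribute (named counts per reason).
#' @export
harmonize_pair <- function(a, b, drop_ambiguous = TRUE, min_shared = 1000) {
  m <- merge(
    a[, .(snp_id, chrom, pos, a1, a2, z_a = z, n_a = n, p_a = p)],
    b[, .(snp_id, b_a1 = a1, b_a2 = a2, z_b = z, n_b = n, p_b = p)],
    by = "snp_id")
  if (nrow(m) == 0) stop("no shared SNPs between the two traits")

  ambiguous <- m$a1 == .COMPLEMENT[m$a2]      # A/T or C/G pairs
  same  <- m$b_a1 == m$a1 & m$b_a2 == m$a2
  swap  <- m$b_a1 == m$a2 & m$b_a2 == m$a1
  comp_same <- .COMPLEMENT[m$b_a1] == m$a1 & .COMPLEMENT[m$b_a2] == m$a2
  comp_swap <- .COMPLEMENT[m$b_a1] == m$a2 & .COMPLEMENT[m$b_a2] == m$a1

  flip <- (swap | (comp_swap & !ambiguous)) & !same
  ok <- same | swap | comp_same | comp_swap
  drop_amb <- ambiguous & drop_ambiguous
  keep <- ok & !drop_amb

  counts <- c(shared = nrow(m),
              kept = sum(keep),
              flipped = sum(flip & keep),
              dropped_ambiguous = sum(drop_amb & ok),
              dropped_mismatch = sum(!ok))
  m[flip, z_b := -z_b]
  out <- m[keep, .(snp_id, chrom, pos, a1, a2, z_a, z_b, n_a, n_b, p_a, p_b)]
  if (nrow(out) == 0) stop("no SNPs survived allele harmonization")
  if (nrow(out) < min_shared)
    warning("only ", nrow(out), " shared SNPs after harmonization")
  data.table::setkey(out, chrom, pos)
  data.table::setattr(out, "drop_counts", counts)
  data.table::setattr(out, "class",
                      unique(c("harmonized_pair", class(out))))
  out[]
}

#' Split a harmonized pair back into two aligned sumstats tables
#'
#' @param pair a `harmonized_pair`.
#' @return List of two `sumstats` tables on identical alleles.
#' @export
pair_to_sumstats <- function(pair) {
  list(
    a = sumstats(pair$snp_id, pair$chrom, pair$pos, pair$a1, pair$a2,
                 pair$z_a, pair$n_a, pair$p_a),
    b = sumstats(pair$snp_id, pair$chrom, pair$pos, pair$a1, pair$a2,
                 pair$z_b, pair$n_b, pair$p_b))
}

#' Write sumstats or a harmonized pair as TSV
#'
#' Harmonized pairs are written with the conventional header
#' `SNP CHR BP A1 A2 Z_A Z_B N_A N_B P_A P_B`.
#'
#' @param x a `sumstats` or `harmonized_pair` table.
#' @param path output path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- data.table::copy(x)
  if (inherits(x, "harmonized_pair")) {
    data.table::setnames(out,
      c("snp_id", "chrom", "pos", "a1", "a2", "z_a", "z_b",
        "n_a", "n_b", "p_a", "p_b"),
      c("SNP", "CHR", "BP", "A1", "A2", "Z_A", "Z_B",
        "N_A", "N_B", "P_A", "P_B"))
  } else {
    data.table::setnames(out,
      c("snp_id", "chrom", "pos", "a1", "a2", "z", "n", "p"),
      c("SNP", "CHR", "BP", "A1", "A2", "Z", "N", "P"))
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
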