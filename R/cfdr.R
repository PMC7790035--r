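#' Build a conditional FDR lookup grid
#'
#' Tabulates the empirical-Bayes conditional FDR of the primary trait given
#' the secondary trait over a 2D grid in `-log10 p`. For grid cell
#' `(p1, p2)` the value is `min(1, p1 * C2(p2) / C12(p1, p2))`, where
#' `C2` counts SNPs with secondary p-value at or below `p2` and `C12`
#' counts SNPs passing both thresholds. To undo the inflation of counts by
#' LD, each count is averaged (as a real number) over `n_prune` random LD
#' prunings at `r^2 < r2_prune` before the division. Cells whose averaged
#' `C12` falls below 1 inherit the nearest less-stringent defined cell, and
#' the grid is made nonincreasing along the primary axis by a running
#' maximum toward less-significant `p1`. The null proportion is
#' conservatively fixed at 1.
#'
#' @param pair a `harmonized_pair` (exclusion mask already applied).
#' @param ld an `ld_structure` covering the pair's SNPs.
#' @param primary which trait's FDR the grid tabulates: `"a"` for
#'   condFDR(A|B), `"b"` for condFDR(B|A).
#' @param grid_step bin width in `-log10 p` (default 0.1).
#' @param grid_max upper end of the `-log10 p` axes (default 20).
#' @param n_prune number of random pruning iterations (default 100).
#' @param r2_prune pruning threshold (default 0.1).
#' @param seed integer seed for the pruning draws.
#' @param monotone apply the running-maximum monotone enforcement
#'   (default `TRUE`; disable to inspect raw counting-formula cells).
#' @return An `fdr_grid`: `edges`, `values` (matrix, rows = primary axis),
#'   averaged counts, and the build metadata.
#' @export
build_fdr_grid <- function(pair, ld, primary = c("a", "b"), grid_step = 0.1,
                           grid_max = 20, n_prune = 100, r2_prune = 0.1,
                           seed = 1, monotone = TRUE) {
  primary <- match.arg(primary)
  p1 <- if (primary == "a") pair$p_a else pair$p_b
  p2 <- if (primary == "a") pair$p_b else pair$p_a
  if (length(unique(p1)) < 2 || length(unique(p2)) < 2)
    stop("degenerate input: p-values are constant")
  edges <- seq(0, grid_max, by = grid_step)
  K <- length(edges)
  x1 <- pmin(-log10(p1), grid_max)
  x2 <- pmin(-log10(p2), grid_max)
  b1 <- findInterval(x1, edges)
  b2 <- findInterval(x2, edges)
  cell <- (b2 - 1L) * K + b1
  row_of <- stats::setNames(seq_len(nrow(pair)), pair$snp_id)

  pruner <- make_pruner(ld, pair$snp_id, r2_prune)
  set.seed(seed)
  cnt <- numeric(K * K)
  for (it in seq_len(n_prune)) {
    kept <- row_of[pruner()]
    cnt <- cnt + tabulate(cell[kept], nbins = K * K)
  }
  cnt <- matrix(cnt / n_prune, K, K)

  # C12[i, j] = average number of kept SNPs with -log10 p1 >= edges[i]
  # and -log10 p2 >= edges[j]
  C12 <- cnt[K:1, K:1, drop = FALSE]
  C12 <- apply(C12, 2, cumsum)
  C12 <- t(apply(C12, 1, cumsum))
  C12 <- C12[K:1, K:1, drop = FALSE]
  C2 <- C12[1, ]

  vals <- 10^(-edges) * sweep(1 / C12, 2, C2, `*`)
  vals[!is.finite(vals)] <- NA_real_
  defined <- C12 >= 1
  for (j in seq_len(K)) {
    if (C2[j] < 1) {            # empty column: inherit less-stringent p2
      vals[, j] <- if (j > 1) vals[, j - 1] else 1
      next
    }
    for (i in seq_len(K)[-1]) {
      if (!defined[i, j]) vals[i, j] <- vals[i - 1, j]
    }
  }
  vals <- pmin(vals, 1)
  if (monotone) {
    # running maximum toward less-significant p1
    for (i in rev(seq_len(K - 1))) {
      vals[i, ] <- pmax(vals[i, ], vals[i + 1, ])
    }
  }
  structure(list(edges = edges, values = vals, counts = C12, c2 = C2,
                 primary = primary, grid_step = grid_step,
                 grid_max = grid_max, n_prune = n_prune,
                 r2_prune = r2_prune, seed = seed),
            class = "fdr_grid")
}

#' @export
print.fdr_grid <- function(x, ...) {
  cat("condFDR lookup grid, primary trait", toupper(x$primary), "\n")
  cat(sprintf("  %d x %d cells, step %.2f in -log10 p; %d prunings at r2 < %.2f\n",
              length(x$edges), length(x$edges), x$grid_step, x$n_prune,
              x$r2_prune))
  invisible(x)
}

# Bilinear interpolation of an fdr_grid at (-log10 p1, -log10 p2) points.
interp_grid <- function(grid, x1, x2) {
  edges <- grid$edges
  K <- length(edges)
  step <- grid$grid_step
  x1 <- pmin(pmax(x1, 0), grid$grid_max)
  x2 <- pmin(pmax(x2, 0), grid$grid_max)
  i <- pmin(findInterval(x1, edges), K - 1L)
  j <- pmin(findInterval(x2, edges), K - 1L)
  tx <- (x1 - edges[i]) / step
  ty <- (x2 - edges[j]) / step
  V <- grid$values
  v00 <- V[cbind(i, j)]
  v10 <- V[cbind(i + 1L, j)]
  v01 <- V[cbind(i, j + 1L)]
  v11 <- V[cbind(i + 1L, j + 1L)]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

#' Assign per-SNP conditional FDR values from a lookup grid
#'
#' Every SNP of the pair (not only pruned ones) receives the bilinear
#' interpolation of the grid at its `(-log10 p_primary, -log10 p_secondary)`
#' coordinates; points beyond the grid range are clamped to the edge.
#'
#' @param pair a `harmonized_pair`.
#' @param grid an `fdr_grid` built from a compatible SNP set.
#' @return Numeric vector of condFDR values aligned with `pair` rows.
#' @export
condfdr_assign <- function(pair, grid) {
  p1 <- if (grid$primary == "a") pair$p_a else pair$p_b
  p2 <- if (grid$primary == "a") pair$p_b else pair$p_a
  interp_grid(grid, -log10(p1), -log10(p2))
}

#' Score SNPs with conditional and conjunctional FDR
#'
#' The conjunctional FDR of a SNP is the maximum of its two reciprocal
#' condFDR values — a conservative estimate of the FDR for association with
#' both phenotypes.
#'
#' @param pair a `harmonized_pair`.
#' @param grid_ab `fdr_grid` with primary `"a"` (condFDR A|B).
#' @param grid_ba `fdr_grid` with primary `"b"` (condFDR B|A).
#' @return A `scored_snps` data.table: pair columns plus
#'   `condfdr_a_given_b`, `condfdr_b_given_a`, `conjfdr`.
#' @export
conjfdr_assign <- function(pair, grid_ab, grid_ba) {
  if (grid_ab$primary != "a" || grid_ba$primary != "b")
    stop("grid_ab must have primary 'a' and grid_ba primary 'b'")
  out <- data.table::copy(pair)
  out[, condfdr_a_given_b := condfdr_assign(pair, grid_ab)]
  out[, condfdr_b_given_a := condfdr_assign(pair, grid_ba)]
  out[, conjfdr := pmax(condfdr_a_given_b, condfdr_b_given_a)]
  data.table::setattr(out, "class",
                      unique(c("scored_snps", "harmonized_pair", class(out))))
  out[]
}

#' Full conjunctional FDR analysis of a harmonized pair
#'
#' Builds both condFDR lookup grids and scores every SNP.
#'
#' @param pair a `harmonized_pair` (exclusion mask already applied).
#' @param ld an `ld_structure`.
#' @param ... passed to [build_fdr_grid()] (`n_prune`, `r2_prune`,
#'   `grid_step`, ...).
#' @param seed integer seed; the two grids use derived sub-seeds.
#' @return A `scored_snps` table with a `grids` attribute.
#' @export
conjfdr_analysis <- function(pair, ld, seed = 1, ...) {
  seeds <- derive_seeds(seed, 2)
  grid_ab <- build_fdr_grid(pair, ld, primary = "a", seed = seeds[1], ...)
  grid_ba <- build_fdr_grid(pair, ld, primary = "b", seed = seeds[2], ...)
  scored <- conjfdr_assign(pair, grid_ab, grid_ba)
  data.table::setattr(scored, "grids", list(ab = grid_ab, ba = grid_ba))
  scored[]
}

#' Trio conjunctional FDR from three pairwise analyses
#'
#' A SNP's trio conjFDR is the maximum of its three pairwise conjFDR
#' values, so significance at threshold `tau` requires significance in all
#' three pairwise analyses.
#'
#' @param scored_ab,scored_ac,scored_bc `scored_snps` tables for the three
#'   trait pairs, sharing a common SNP universe.
#' @return data.table `snp_id, chrom, pos, conjfdr_ab, conjfdr_ac,
#'   conjfdr_bc, trio_conjfdr`.
#' @export
trio_conjfdr <- function(scored_ab, scored_ac, scored_bc) {
  ab <- scored_ab[, .(snp_id, chrom, pos, conjfdr_ab = conjfdr)]
  ac <- scored_ac[, .(snp_id, conjfdr_ac = conjfdr)]
  bc <- scored_bc[, .(snp_id, conjfdr_bc = conjfdr)]
  out <- merge(merge(ab, ac, by = "snp_id"), bc, by = "snp_id")
  if (nrow(out) == 0) stop("empty SNP intersection across the three pairs")
  out[, trio_conjfdr := pmax(conjfdr_ab, conjfdr_ac, conjfdr_bc)]
  data.table::setkey(out, chrom, pos)
  out[]
}

#' Write scored SNPs as TSV
#'
#' Columns follow the conventional
#' `SNP CHR BP Z_A Z_B P_A P_B CONDFDR_A_B CONDFDR_B_A CONJFDR` layout.
#'
#' @param scored a `scored_snps` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scored_snps <- function(scored, path) {
  out <- scored[, .(SNP = snp_id, CHR = chrom, BP = pos, Z_A = z_a,
                    Z_B = z_b, P_A = p_a, P_B = p_b,
                    CONDFDR_A_B = condfdr_a_given_b,
                    CONDFDR_B_A = condfdr_b_given_a, CONJFDR = conjfdr)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
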