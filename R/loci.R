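#' Define independent genomic loci from scored SNPs
#'
#' FUMA-style locus definition on conjFDR-scored SNPs:
#' \enumerate{
#'   \item Independent significant SNPs: `conjfdr < sig_thresh`, selected
#'     greedily by ascending conjFDR (ties broken by chromosome, then
#'     position) so that kept SNPs are mutually at `r^2 < r2_indep`.
#'   \item Lead SNPs: the subset of independent significant SNPs that is
#'     mutually at `r^2 < r2_lead` (same greedy order).
#'   \item Candidate SNPs: `conjfdr < cand_thresh` and `r^2 >= r2_indep`
#'     with at least one independent significant SNP; every independent
#'     significant SNP is its own candidate.
#'   \item Loci: the positional envelope (min-max candidate position) of
#'     each independent significant SNP, merged with other envelopes on the
#'     same chromosome whenever they overlap or lie within `merge_kb` kb of
#'     each other. The locus lead is the member independent significant SNP
#'     with the smallest conjFDR.
#' }
#' r-squared between SNPs in different LD blocks is 0.
#'
#' @param scored a `scored_snps` table (needs `conjfdr`; any column named
#'   `conjfdr` works, so condFDR-only analyses can pass their values there).
#' @param ld an `ld_structure`.
#' @param sig_thresh significance threshold on conjFDR (default 0.05).
#' @param cand_thresh candidate threshold on conjFDR (default 0.10).
#' @param r2_indep r-squared defining independence / candidate linkage
#'   (default 0.6).
#' @param r2_lead r-squared separating lead SNPs (default 0.1).
#' @param merge_kb merge window in kb between envelopes (default 250).
#' @return A `loci` data.table, one row per locus: `chrom, start, end,
#'   lead_snp, lead_conjfdr, z_a, z_b, concordant, n_ind_sig, n_cand` plus
#'   list-columns `ind_sig_snps`, `cand_snps`. Empty (0-row) when nothing is
#'   significant.
#' @export
define_loci <- function(scored, ld, sig_thresh = 0.05, cand_thresh = 0.10,
                        r2_indep = 0.6, r2_lead = 0.1, merge_kb = 250) {
  empty <- data.table::data.table(
    chrom = character(0), start = numeric(0), end = numeric(0),
    lead_snp = character(0), lead_conjfdr = numeric(0),
    z_a = numeric(0), z_b = numeric(0), concordant = logical(0),
    n_ind_sig = integer(0), n_cand = integer(0),
    ind_sig_snps = list(), cand_snps = list())
  data.table::setattr(empty, "class", unique(c("loci", class(empty))))

  sig <- scored[scored$conjfdr < sig_thresh]
  if (nrow(sig) == 0) return(empty[])
  idx <- ld_index(ld)
  sig <- merge(sig, idx, by = "snp_id", all.x = TRUE)
  data.table::setorder(sig, conjfdr, chrom, pos)

  # (1) greedy selection of independent significant SNPs
  kept <- integer(0)
  kept_by_block <- list()
  for (i in seq_len(nrow(sig))) {
    bi <- sig$block[i]
    ok <- TRUE
    if (!is.na(bi)) {
      prev <- kept_by_block[[as.character(bi)]]
      if (length(prev)) {
        R <- ld$blocks[[bi]]$R
        ok <- all(R[sig$slot[i], prev]^2 < r2_indep)
      }
    }
    if (ok) {
      kept <- c(kept, i)
      if (!is.na(bi)) {
        key <- as.character(bi)
        kept_by_block[[key]] <- c(kept_by_block[[key]], sig$slot[i])
      }
    }
  }
  ind_sig <- sig[kept]

  # (2) lead SNPs: mutually r^2 < r2_lead among independent significant
  lead_keep <- integer(0)
  lead_by_block <- list()
  for (i in seq_len(nrow(ind_sig))) {
    bi <- ind_sig$block[i]
    ok <- TRUE
    if (!is.na(bi)) {
      prev <- lead_by_block[[as.character(bi)]]
      if (length(prev)) {
        R <- ld$blocks[[bi]]$R
        ok <- all(R[ind_sig$slot[i], prev]^2 < r2_lead)
      }
    }
    if (ok) {
      lead_keep <- c(lead_keep, i)
      if (!is.na(bi)) {
        key <- as.character(bi)
        lead_by_block[[key]] <- c(lead_by_block[[key]], ind_sig$slot[i])
      }
    }
  }
  ind_sig[, is_lead := seq_len(.N) %in% lead_keep]

  # (3) candidate SNPs per independent significant SNP
  cand_pool <- merge(scored[scored$conjfdr < cand_thresh], idx,
                     by = "snp_id", all.x = TRUE)
  envelopes <- lapply(seq_len(nrow(ind_sig)), function(i) {
    bi <- ind_sig$block[i]
    cands <- ind_sig$snp_id[i]
    if (!is.na(bi)) {
      pool <- cand_pool[!is.na(cand_pool$block) & cand_pool$block == bi]
      if (nrow(pool)) {
        R <- ld$blocks[[bi]]$R
        r2 <- R[pool$slot, ind_sig$slot[i]]^2
        cands <- union(cands, pool$snp_id[r2 >= r2_indep])
      }
    }
    pos <- scored$pos[match(cands, scored$snp_id)]
    list(chrom = ind_sig$chrom[i], start = min(pos), end = max(pos),
         ind_sig = ind_sig$snp_id[i], cands = cands)
  })

  # (4) merge envelopes within merge_kb on the same chromosome
  env <- data.table::data.table(
    chrom = vapply(envelopes, `[[`, character(1), "chrom"),
    start = vapply(envelopes, function(e) as.numeric(e$start), numeric(1)),
    end = vapply(envelopes, function(e) as.numeric(e$end), numeric(1)),
    i = seq_along(envelopes))
  data.table::setorder(env, chrom, start, end)
  gap <- merge_kb * 1000
  locus_id <- integer(nrow(env))
  cur <- 0L
  cur_end <- -Inf
  cur_chr <- ""
  for (r in seq_len(nrow(env))) {
    if (env$chrom[r] != cur_chr || env$start[r] - cur_end > gap) {
      cur <- cur + 1L
      cur_chr <- env$chrom[r]
      cur_end <- env$end[r]
    } else {
      cur_end <- max(cur_end, env$end[r])
    }
    locus_id[r] <- cur
  }
  env[, locus := locus_id]

  loci <- env[, {
    members <- envelopes[i]
    is_ids <- vapply(members, `[[`, character(1), "ind_sig")
    cands <- sort(unique(unlist(lapply(members, `[[`, "cands"))))
    sub <- ind_sig[match(is_ids, ind_sig$snp_id)]
    data.table::setorder(sub, conjfdr, chrom, pos)
    lead <- sub[1]
    cpos <- scored$pos[match(cands, scored$snp_id)]
    list(start = min(cpos), end = max(cpos),
         lead_snp = lead$snp_id, lead_conjfdr = lead$conjfdr,
         z_a = lead$z_a, z_b = lead$z_b,
         concordant = sign(lead$z_a) * sign(lead$z_b) > 0,
         n_ind_sig = length(is_ids), n_cand = length(cands),
         ind_sig_snps = list(is_ids), cand_snps = list(cands))
  }, by = .(chrom, locus)]
  loci[, locus := NULL]
  data.table::setorder(loci, chrom, start)
  data.table::setattr(loci, "class", unique(c("loci", class(loci))))
  loci[]
}

#' Effect-direction concordance at shared loci
#'
#' A locus is concordant when the signs of the two traits' z-scores agree
#' at its lead SNP (default), or — with `method = "candidates"` — when the
#' majority of its candidate SNPs have agreeing signs. Loci with a zero or
#' missing z-score are excluded from the percentage and counted
#' separately.
#'
#' @param loci a `loci` table from [define_loci()].
#' @param method `"lead"` (sign at the lead SNP) or `"candidates"`
#'   (majority vote over candidate SNPs; requires `scored`).
#' @param scored the `scored_snps` table the loci were defined from; only
#'   needed for the candidate vote.
#' @return List: `n_loci`, `n_evaluable`, `n_concordant`,
#'   `pct_concordant` (percentage of evaluable loci; `NA` when none),
#'   `n_na` (excluded loci).
#' @export
effect_concordance <- function(loci, method = c("lead", "candidates"),
                               scored = NULL) {
  method <- match.arg(method)
  n <- nrow(loci)
  if (method == "candidates") {
    if (is.null(scored)) stop("candidate vote needs the scored table")
    vote <- vapply(seq_len(n), function(i) {
      rows <- match(loci$cand_snps[[i]], scored$snp_id)
      s <- sign(scored$z_a[rows]) * sign(scored$z_b[rows])
      s <- s[!is.na(s) & s != 0]
      if (length(s) == 0) NA else mean(s > 0) > 0.5
    }, logical(1))
    evaluable <- !is.na(vote)
    conc <- vote[evaluable]
    return(list(n_loci = n, n_evaluable = sum(evaluable),
                n_concordant = sum(conc),
                pct_concordant = if (sum(evaluable) > 0)
                  100 * sum(conc) / sum(evaluable) else NA_real_,
                n_na = n - sum(evaluable)))
  }
  evaluable <- !is.na(loci$z_a) & !is.na(loci$z_b) &
    loci$z_a != 0 & loci$z_b != 0
  conc <- sign(loci$z_a[evaluable]) * sign(loci$z_b[evaluable]) > 0
  list(n_loci = n,
       n_evaluable = sum(evaluable),
       n_concordant = sum(conc),
       pct_concordant = if (sum(evaluable) > 0)
         100 * sum(conc) / sum(evaluable) else NA_real_,
       n_na = n - sum(evaluable))
}

#' Write loci as TSV (optionally BED)
#'
#' The TSV uses the conventional
#' `CHR START END LEAD_SNP CONJFDR N_IND_SIG N_CAND Z_A Z_B CONCORDANT`
#' header with 1-based inclusive coordinates; BED output converts to
#' 0-based half-open.
#'
#' @param loci a `loci` table.
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    out <- data.table::data.table(chrom = paste0("chr", loci$chrom),
                                  start = loci$start - 1L,
                                  end = loci$end,
                                  name = loci$lead_snp)
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  } else {
    out <- loci[, .(CHR = chrom, START = start, END = end,
                    LEAD_SNP = lead_snp, CONJFDR = lead_conjfdr,
                    N_IND_SIG = n_ind_sig, N_CAND = n_cand,
                    Z_A = z_a, Z_B = z_b, CONCORDANT = concordant)]
    data.table::fwrite(out, path, sep = "\t")
  }
  invisible(path)
}
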