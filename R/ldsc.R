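# Closed-form weighted least squares of y on x with intercept, from partial
# sums. Returns c(intercept, slope).
wls_fit <- function(sw, swx, swxx, swy, swxy) {
  den <- swxx * sw - swx^2
  slope <- (swxy * sw - swx * swy) / den
  intercept <- (swy - slope * swx) / sw
  c(intercept, slope)
}

#' Per-trait SNP heritability by LD score regression
#'
#' Fits `E[z_j^2] = intercept + N h2 l_j / m` by weighted least squares
#' (weights `1 / l_j`, a heteroskedasticity proxy). The intercept absorbs
#' residual inflation; `h2` is returned as fitted, including negative
#' values (with a warning), never silently truncated.
#'
#' @param s a `sumstats` table (or any table with `z` and `n`).
#' @param scores data.table `snp_id, ld_score` from [ld_scores()].
#' @param m total SNP count backing the LD scores.
#' @return List `h2`, `intercept`, `n_snps`.
#' @export
univariate_h2 <- function(s, scores, m) {
  d <- merge(data.table::as.data.table(s)[, .(snp_id, z, n)], scores,
             by = "snp_id")
  if (nrow(d) == 0) stop("no shared SNPs between sumstats and LD scores")
  n_eff <- stats::median(d$n, na.rm = TRUE)
  w <- 1 / d$ld_score
  x <- d$ld_score
  y <- d$z^2
  fit <- wls_fit(sum(w), sum(w * x), sum(w * x^2), sum(w * y),
                 sum(w * x * y))
  h2 <- fit[2] * m / n_eff
  if (h2 < 0) warning("fitted h2 is negative (", signif(h2, 3), ")")
  list(h2 = h2, intercept = fit[1], n_snps = nrow(d))
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Fits `E[z_A z_B] = intercept + sqrt(N_A N_B) rho_gcov l_j / m` and the
#' two univariate heritability regressions, assembles
#' `rg = gcov / sqrt(h2_A h2_B)` (clamped to `[-1, 1]`), and attaches a
#' delete-one block-jackknife standard error over `n_blocks_jk` contiguous
#' SNP blocks with a two-sided normal p-value. The cross-trait intercept
#' absorbs correlated residuals from sample overlap.
#'
#' @param pair a `harmonized_pair`.
#' @param scores data.table `snp_id, ld_score`.
#' @param m total SNP count backing the LD scores.
#' @param n_blocks_jk jackknife blocks (default 200).
#' @return An `rg_estimate` list: `rg`, `se`, `p`, `gcov`, `h2_a`, `h2_b`,
#'   `intercept`, `n_snps`, and `reason` when `rg` is undefined.
#' @export
cross_trait_rg <- function(pair, scores, m, n_blocks_jk = 200) {
  d <- merge(
    data.table::as.data.table(pair)[, .(snp_id, chrom, pos, z_a, z_b,
                                        n_a, n_b)],
    scores, by = "snp_id")
  data.table::setorder(d, chrom, pos)
  n <- nrow(d)
  if (n < n_blocks_jk * 10)
    warning("fewer than ", n_blocks_jk * 10, " SNPs for ", n_blocks_jk,
            "-block jackknife")
  na <- stats::median(d$n_a, na.rm = TRUE)
  nb <- stats::median(d$n_b, na.rm = TRUE)

  w <- 1 / d$ld_score
  x <- d$ld_score
  ys <- cbind(ab = d$z_a * d$z_b, aa = d$z_a^2, bb = d$z_b^2)
  blk <- ceiling(seq_len(n) / (n / n_blocks_jk))

  # per-block partial sums of every moment the three regressions need
  sums <- function(v) as.numeric(rowsum(v, blk))
  ps <- list(w = sums(w), wx = sums(w * x), wxx = sums(w * x^2),
             wy = apply(ys, 2, function(y) sums(w * y)),
             wxy = apply(ys, 2, function(y) sums(w * x * y)))

  assemble <- function(drop = 0L) {
    keep <- if (drop == 0L) seq_len(n_blocks_jk) else
      setdiff(seq_len(n_blocks_jk), drop)
    sw <- sum(ps$w[keep]); swx <- sum(ps$wx[keep]); swxx <- sum(ps$wxx[keep])
    f_ab <- wls_fit(sw, swx, swxx, sum(ps$wy[keep, "ab"]),
                    sum(ps$wxy[keep, "ab"]))
    f_aa <- wls_fit(sw, swx, swxx, sum(ps$wy[keep, "aa"]),
                    sum(ps$wxy[keep, "aa"]))
    f_bb <- wls_fit(sw, swx, swxx, sum(ps$wy[keep, "bb"]),
                    sum(ps$wxy[keep, "bb"]))
    gcov <- f_ab[2] * m / sqrt(na * nb)
    h2a <- f_aa[2] * m / na
    h2b <- f_bb[2] * m / nb
    rg <- if (h2a > 0 && h2b > 0)
      max(-1, min(1, gcov / sqrt(h2a * h2b))) else NA_real_
    list(gcov = gcov, h2a = h2a, h2b = h2b, rg = rg,
         intercept = f_ab[1], int_a = f_aa[1], int_b = f_bb[1])
  }

  full <- assemble()
  out <- list(rg = full$rg, gcov = full$gcov, h2_a = full$h2a,
              h2_b = full$h2b, intercept = full$intercept,
              intercept_a = full$int_a, intercept_b = full$int_b,
              se = NA_real_, p = NA_real_, n_snps = n,
              n_blocks_jk = n_blocks_jk, reason = NA_character_)
  if (is.na(full$rg)) {
    out$reason <- "non-positive heritability estimate in at least one trait"
    class(out) <- "rg_estimate"
    return(out)
  }
  jk <- vapply(seq_len(n_blocks_jk), function(b) assemble(b)$rg, numeric(1))
  jk <- jk[is.finite(jk)]
  B <- length(jk)
  out$se <- sqrt((B - 1) / B * sum((jk - mean(jk))^2))
  out$p <- if (out$se > 0)
    2 * stats::pnorm(-abs(out$rg / out$se)) else NA_real_
  class(out) <- "rg_estimate"
  out
}

#' @export
print.rg_estimate <- function(x, ...) {
  if (is.na(x$rg)) {
    cat("rg: undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("rg = %.3f (SE %.3f, p = %.3g), h2: %.3f / %.3f, cross intercept %.3f\n",
                x$rg, x$se, x$p, x$h2_a, x$h2_b, x$intercept))
  }
  invisible(x)
}

#' Bonferroni significance flags for genetic correlations
#'
#' An estimate is flagged significant when `p < 0.05 / n_tests`.
#'
#' @param estimates list of `rg_estimate` objects (or numeric p-values).
#' @param n_tests number of tests in the family.
#' @return Logical vector of flags.
#' @export
bonferroni_flag <- function(estimates, n_tests) {
  stopifnot(n_tests >= 1)
  p <- if (is.numeric(estimates)) estimates
       else vapply(estimates, function(e) e$p, numeric(1))
  !is.na(p) & p < 0.05 / n_tests
}
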