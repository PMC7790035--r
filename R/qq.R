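#' Conditional Q-Q table of cross-trait enrichment
#'
#' For each secondary-trait p-value threshold `t`, restricts to SNPs with
#' `p_b <= t` and computes the observed `-log10 p_a` at `n_points` evenly
#' spaced empirical quantile levels; the expected curve is `-log10` of those
#' same levels (uniform null). Successive leftward/upward deflection of the
#' curves with increasing conditioning stringency indicates pleiotropic
#' enrichment. Swap the traits' roles by passing the reverse pair (or a
#' table with `p_a`/`p_b` exchanged) to obtain the reverse conditional Q-Q.
#'
#' @param pair a `harmonized_pair` (any table with `p_a` and `p_b`).
#' @param thresholds secondary-trait p-value cutoffs, strictly decreasing,
#'   in `(0, 1]`.
#' @param n_points quantile levels per curve.
#' @param cap curves are capped at this `-log10 p` for display.
#' @return A `qq_table` data.table with columns `stratum` (threshold),
#'   `level`, `expected`, `observed`, `n_snps`, `sparse` (stratum below 100
#'   SNPs).
#' @export
conditional_qq <- function(pair, thresholds = c(1, 0.1, 0.01, 0.001),
                           n_points = 1000, cap = 20) {
  stopifnot(nrow(pair) > 0, all(thresholds > 0), all(thresholds <= 1),
            all(diff(thresholds) < 0))
  levels <- (seq_len(n_points) - 0.5) / n_points
  out <- data.table::rbindlist(lapply(thresholds, function(t) {
    p1 <- pair$p_a[pair$p_b <= t]
    n <- length(p1)
    if (n == 0) {
      return(data.table::data.table(stratum = t, level = levels,
                                    expected = pmin(-log10(levels), cap),
                                    observed = NA_real_, n_snps = 0L,
                                    sparse = TRUE))
    }
    obs <- -log10(stats::quantile(p1, probs = levels, names = FALSE))
    data.table::data.table(stratum = t, level = levels,
                           expected = pmin(-log10(levels), cap),
                           observed = pmin(obs, cap),
                           n_snps = n, sparse = n < 100)
  }))
  data.table::setattr(out, "class", unique(c("qq_table", class(out))))
  out[]
}

#' Check conditional Q-Q strata against a DKW null band
#'
#' For each stratum, computes the exact Kolmogorov-Smirnov-type maximum
#' deviation of the stratum's primary p-values from the uniform cdf and
#' compares it with the Dvoretzky-Kiefer-Wolfowitz bound
#' `sqrt(log(2/alpha) / (2 n))`. Under the global null each stratum stays
#' inside the band with probability at least `1 - alpha`.
#'
#' @param pair the table the Q-Q was built from (`p_a`, `p_b`).
#' @param thresholds secondary p-value cutoffs.
#' @param alpha band level (default 0.05 gives the 95% band).
#' @return data.table `stratum, n_snps, max_dev, band, inside`.
#' @export
qq_null_band <- function(pair, thresholds = c(1, 0.1, 0.01, 0.001),
                         alpha = 0.05) {
  data.table::rbindlist(lapply(thresholds, function(t) {
    p1 <- sort(pair$p_a[pair$p_b <= t])
    n <- length(p1)
    if (n == 0)
      return(data.table::data.table(stratum = t, n_snps = 0L,
                                    max_dev = NA_real_, band = NA_real_,
                                    inside = NA))
    d_plus <- max(seq_len(n) / n - p1)
    d_minus <- max(p1 - (seq_len(n) - 1) / n)
    dev <- max(d_plus, d_minus)
    band <- sqrt(log(2 / alpha) / (2 * n))
    data.table::data.table(stratum = t, n_snps = n, max_dev = dev,
                           band = band, inside = dev <= band)
  }))
}

#' Median enrichment per stratum
#'
#' Median observed `-log10 p_a` within each conditioning stratum; a
#' nondecreasing sequence across increasingly stringent strata is the
#' tabular analogue of successive Q-Q deflection.
#'
#' @param pair table with `p_a`, `p_b`.
#' @param thresholds secondary p-value cutoffs.
#' @return data.table `stratum, n_snps, median_neglog_p`.
#' @export
stratum_medians <- function(pair, thresholds = c(1, 0.1, 0.01, 0.001)) {
  data.table::rbindlist(lapply(thresholds, function(t) {
    p1 <- pair$p_a[pair$p_b <= t]
    data.table::data.table(stratum = t, n_snps = length(p1),
                           median_neglog_p = stats::median(-log10(p1)))
  }))
}

#' Write a Q-Q table as long-format TSV
#'
#' @param qq a `qq_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qq_table <- function(qq, path) {
  data.table::fwrite(qq, path, sep = "\t")
  invisible(path)
}
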