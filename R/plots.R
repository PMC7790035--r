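#' Quick-look conditional Q-Q plot
#'
#' One curve per conditioning stratum against the null diagonal. Requires
#' ggplot2.
#'
#' @param qq a `qq_table` from [conditional_qq()].
#' @return A ggplot object.
#' @export
plot_qq <- function(qq) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  dat <- qq[!is.na(qq$observed)]
  dat$stratum <- factor(dat$stratum, levels = sort(unique(dat$stratum),
                                                   decreasing = TRUE))
  ggplot2::ggplot(dat, ggplot2::aes(x = expected, y = observed,
                                    colour = stratum)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  colour = "p2 threshold") +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of conjunctional FDR
#'
#' Plots `-log10(conjFDR)` by genomic position; SNPs below the
#' significance threshold (conjFDR < 0.05, i.e. `-log10 > 1.3`) are drawn
#' enlarged, and locus lead SNPs (when a `loci` table is supplied) are
#' circled.
#'
#' @param scored a `scored_snps` table.
#' @param loci optional `loci` table; leads get a black ring.
#' @param sig_thresh significance threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scored, loci = NULL, sig_thresh = 0.05) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- data.table::as.data.table(scored)
  d <- d[order(suppressWarnings(as.numeric(chrom)), pos)]
  d[, cum_pos := seq_len(.N)]
  d[, sig := conjfdr < sig_thresh]
  g <- ggplot2::ggplot(d, ggplot2::aes(x = cum_pos, y = -log10(conjfdr),
                                       colour = chrom)) +
    ggplot2::geom_point(ggplot2::aes(size = sig), show.legend = FALSE) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 0.4, `TRUE` = 1.6)) +
    ggplot2::geom_hline(yintercept = -log10(sig_thresh), linetype = 2) +
    ggplot2::labs(x = "SNP (genome order)", y = expression(-log[10](conjFDR))) +
    ggplot2::theme_minimal()
  if (!is.null(loci) && nrow(loci) > 0) {
    leads <- d[d$snp_id %in% loci$lead_snp]
    g <- g + ggplot2::geom_point(data = leads, shape = 21, size = 3,
                                 colour = "black", fill = NA)
  }
  g
}
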