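#' Assemble a run configuration
#'
#' A flat key-value configuration driving [run_pair_analysis()] /
#' [run_trio_analysis()]. Provide either simulation parameters (`sim`, a
#' list passed to [generative_params()], or `trio_sim` for three traits) or
#' input paths (`sumstats_a`, `sumstats_b`, optionally `sumstats_c`, and
#' `ld_triplets`). Every analysis threshold is exposed with its
#' conventional default.
#'
#' @param sim list of [generative_params()] arguments (pair simulation).
#' @param trio_sim list of [simulate_gwas_trio()] arguments.
#' @param sumstats_a,sumstats_b,sumstats_c summary-statistics file paths.
#' @param ld_triplets LD triplet TSV path (see [read_ld_triplets()]).
#' @param exclude apply the long-range-LD exclusion mask. Defaults to
#'   `TRUE` for file inputs and `FALSE` for simulated coordinates (which do
#'   not live on the real genome).
#' @param mask region mask used when `exclude` is `TRUE`.
#' @param qq_thresholds conditional Q-Q strata (secondary p cutoffs).
#' @param fit_mixture fit the bivariate causal mixture (slowest stage).
#' @param aic_diagnostics also run the min/max-overlap AIC comparison.
#' @param r2_fit_prune pruning threshold before the mixture fit.
#' @param n_prune,r2_prune condFDR lookup pruning iterations / threshold.
#' @param grid_step,grid_max condFDR lookup grid geometry in `-log10 p`.
#' @param sig_thresh,cand_thresh conjFDR locus thresholds (0.05 / 0.10).
#' @param r2_indep,r2_lead,merge_kb FUMA-style locus parameters
#'   (0.6 / 0.1 / 250 kb).
#' @param n_blocks_jk jackknife blocks for LD score regression.
#' @param seed master seed for every random stage.
#' @param out_dir optional directory for TSV/JSON outputs.
#' @param verbose one log line per stage.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, trio_sim = NULL, sumstats_a = NULL,
                       sumstats_b = NULL, sumstats_c = NULL,
                       ld_triplets = NULL, exclude = NULL,
                       mask = default_exclusion_mask(),
                       qq_thresholds = c(1, 0.1, 0.01, 0.001),
                       fit_mixture = TRUE, aic_diagnostics = FALSE,
                       r2_fit_prune = 0.1, n_prune = 100, r2_prune = 0.1,
                       grid_step = 0.1, grid_max = 20, sig_thresh = 0.05,
                       cand_thresh = 0.10, r2_indep = 0.6, r2_lead = 0.1,
                       merge_kb = 250, n_blocks_jk = 200, seed = 1,
                       out_dir = NULL, verbose = TRUE) {
  simulating <- !is.null(sim) || !is.null(trio_sim)
  if (!simulating) {
    for (p in c(sumstats_a, sumstats_b, sumstats_c, ld_triplets)) {
      if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
    }
    if (is.null(sumstats_a) || is.null(sumstats_b) || is.null(ld_triplets))
      stop("need either simulation parameters or sumstats paths plus LD")
  }
  stopifnot(sig_thresh > 0, sig_thresh < 1, cand_thresh >= sig_thresh,
            r2_indep > 0, r2_indep <= 1, r2_lead > 0, r2_lead <= r2_indep,
            merge_kb >= 0, n_prune >= 1, r2_prune > 0, r2_prune <= 1)
  cfg <- list(sim = sim, trio_sim = trio_sim, sumstats_a = sumstats_a,
              sumstats_b = sumstats_b, sumstats_c = sumstats_c,
              ld_triplets = ld_triplets,
              exclude = if (is.null(exclude)) !simulating else exclude,
              mask = mask, qq_thresholds = qq_thresholds,
              fit_mixture = fit_mixture, aic_diagnostics = aic_diagnostics,
              r2_fit_prune = r2_fit_prune, n_prune = n_prune,
              r2_prune = r2_prune, grid_step = grid_step,
              grid_max = grid_max, sig_thresh = sig_thresh,
              cand_thresh = cand_thresh, r2_indep = r2_indep,
              r2_lead = r2_lead, merge_kb = merge_kb,
              n_blocks_jk = n_blocks_jk, seed = as.integer(seed),
              out_dir = out_dir, verbose = verbose)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files")
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[setdiff(names(cfg), "verbose")]), f)
  unname(tools::md5sum(f))
}

# Swap the roles of traits A and B in a harmonized pair.
reverse_pair <- function(pair) {
  out <- pair[, .(snp_id, chrom, pos, a1, a2, z_a = z_b, z_b = z_a,
                  n_a = n_b, n_b = n_a, p_a = p_b, p_b = p_a)]
  data.table::setattr(out, "class", class(pair))
  out[]
}

pair_inputs <- function(cfg, log) {
  if (!is.null(cfg$sim)) {
    gp <- do.call(generative_params,
                  utils::modifyList(cfg$sim, list(seed = cfg$seed)))
    sim <- simulate_gwas_pair(gp)
    log("simulate: ", nrow(sim$pair), " SNPs, ",
        sum(sim$effects$label != "null"), " causal")
    list(pair = sim$pair, ld = sim$ld, effects = sim$effects)
  } else {
    a <- read_sumstats(cfg$sumstats_a)
    b <- read_sumstats(cfg$sumstats_b)
    pair <- harmonize_pair(a, b)
    log("harmonize: ", nrow(a), " + ", nrow(b), " -> ", nrow(pair),
        " shared SNPs")
    list(pair = pair, ld = read_ld_triplets(cfg$ld_triplets),
         effects = NULL)
  }
}

analyze_pair <- function(pair, ld, cfg, log, seed_offset = 0L) {
  seeds <- derive_seeds(cfg$seed + seed_offset, 4)
  if (cfg$exclude) {
    n0 <- nrow(pair)
    pair <- exclude_regions(pair, cfg$mask)
    log("exclude_regions: ", n0, " -> ", nrow(pair), " SNPs")
  }
  m <- nrow(pair)

  qq_ab <- conditional_qq(pair, cfg$qq_thresholds)
  qq_ba <- conditional_qq(reverse_pair(pair), cfg$qq_thresholds)
  log("qq: ", length(cfg$qq_thresholds), " strata per direction")

  mixer <- NULL
  if (cfg$fit_mixture) {
    pruned <- prune_for_fit(pair, ld, r2_max = cfg$r2_fit_prune,
                            seed = seeds[1])
    fit <- suppressWarnings(fit_bivariate(pruned, seed = seeds[2]))
    venn <- venn_summary(fit, m)
    aic <- if (cfg$aic_diagnostics) overlap_aic(fit, pruned) else NULL
    log("mixer: ", nrow(pruned), " pruned SNPs, pi12=",
        signif(fit$params$pi_12, 3))
    mixer <- list(fit = fit, venn = venn, aic = aic, pruned_n = nrow(pruned),
                  implied_rg = implied_rg(fit))
  }

  scored <- conjfdr_analysis(pair, ld, seed = seeds[3],
                             n_prune = cfg$n_prune,
                             r2_prune = cfg$r2_prune,
                             grid_step = cfg$grid_step,
                             grid_max = cfg$grid_max)
  log("conjfdr: ", sum(scored$conjfdr < cfg$sig_thresh),
      " SNPs below ", cfg$sig_thresh)

  loci <- define_loci(scored, ld, sig_thresh = cfg$sig_thresh,
                      cand_thresh = cfg$cand_thresh,
                      r2_indep = cfg$r2_indep, r2_lead = cfg$r2_lead,
                      merge_kb = cfg$merge_kb)
  conc <- effect_concordance(loci)
  log("loci: ", nrow(loci), " shared loci, ",
      ifelse(is.na(conc$pct_concordant), "na",
             sprintf("%.1f%%", conc$pct_concordant)), " concordant")

  scores <- ld_scores(ld)
  rg <- suppressWarnings(cross_trait_rg(pair, scores, m = m,
                                        n_blocks_jk = cfg$n_blocks_jk))
  log("rg: ", ifelse(is.na(rg$rg), "undefined", sprintf("%.3f", rg$rg)))

  list(pair = pair, qq = list(ab = qq_ab, ba = qq_ba), mixer = mixer,
       scored = scored, loci = loci, concordance = conc, rg = rg)
}

#' Run the full two-trait analysis
#'
#' Executes simulate/read -> harmonize -> region exclusion -> conditional
#' Q-Q (both directions) -> bivariate mixture with Venn counts (and
#' optional AIC diagnostics) -> cond/conjFDR -> locus definition ->
#' effect-direction concordance -> LD score regression, and returns a
#' result bundle. Re-running with the same configuration and seed
#' reproduces all outputs.
#'
#' @param cfg a [run_config()].
#' @return A `result_bundle` list: `pair`, `qq`, `mixer`, `scored`,
#'   `loci`, `concordance`, `rg`, `effects` (simulation truth, if any),
#'   `provenance`.
#' @export
run_pair_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- function(...) if (isTRUE(cfg$verbose)) message(...)
  inp <- pair_inputs(cfg, log)
  res <- analyze_pair(inp$pair, inp$ld, cfg, log)
  res$effects <- inp$effects
  res$ld <- inp$ld
  res$provenance <- list(seed = cfg$seed, config_hash = config_hash(cfg),
                         package_version =
                           as.character(utils::packageVersion("crosstrait")),
                         timestamp = format(Sys.time(), tz = "UTC"))
  class(res) <- "result_bundle"
  if (!is.null(cfg$out_dir)) write_bundle(res, cfg$out_dir)
  res
}

#' Run the three-trait analysis
#'
#' Performs the three pairwise analyses, combines their conjFDR values into
#' the trio conjFDR (maximum of the three), and defines trio loci at the
#' same significance threshold.
#'
#' @param cfg a [run_config()] with `trio_sim` or three sumstats paths.
#' @return A `result_bundle` with `pairwise` (list ab/ac/bc), `trio`
#'   (scored trio table), `trio_loci`, `provenance`.
#' @export
run_trio_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- function(...) if (isTRUE(cfg$verbose)) message(...)
  if (!is.null(cfg$trio_sim)) {
    sim <- do.call(simulate_gwas_trio,
                   utils::modifyList(cfg$trio_sim, list(seed = cfg$seed)))
    ss <- sim$sumstats
    ld <- sim$ld
    effects <- sim$effects
  } else {
    if (is.null(cfg$sumstats_c)) stop("trio analysis needs three traits")
    ss <- list(a = read_sumstats(cfg$sumstats_a),
               b = read_sumstats(cfg$sumstats_b),
               c = read_sumstats(cfg$sumstats_c))
    ld <- read_ld_triplets(cfg$ld_triplets)
    effects <- NULL
  }
  pairs <- list(
    ab = suppressWarnings(harmonize_pair(ss$a, ss$b)),
    ac = suppressWarnings(harmonize_pair(ss$a, ss$c)),
    bc = suppressWarnings(harmonize_pair(ss$b, ss$c)))
  res <- lapply(seq_along(pairs), function(i) {
    log("pair ", names(pairs)[i], ":")
    analyze_pair(pairs[[i]], ld, cfg, log, seed_offset = i)
  })
  names(res) <- names(pairs)
  trio <- trio_conjfdr(res$ab$scored, res$ac$scored, res$bc$scored)
  log("trio: ", sum(trio$trio_conjfdr < cfg$sig_thresh),
      " SNPs below ", cfg$sig_thresh)
  trio_scored <- merge(
    res$ab$scored[, .(snp_id, chrom, pos, z_a, z_b, p_a, p_b)],
    trio[, .(snp_id, conjfdr = trio_conjfdr)], by = "snp_id")
  trio_loci <- define_loci(trio_scored, ld, sig_thresh = cfg$sig_thresh,
                           cand_thresh = cfg$cand_thresh,
                           r2_indep = cfg$r2_indep, r2_lead = cfg$r2_lead,
                           merge_kb = cfg$merge_kb)
  log("trio loci: ", nrow(trio_loci))
  out <- list(pairwise = res, trio = trio, trio_loci = trio_loci,
              effects = effects, ld = ld,
              provenance = list(seed = cfg$seed,
                                config_hash = config_hash(cfg),
                                package_version =
                                  as.character(utils::packageVersion("crosstrait")),
                                timestamp = format(Sys.time(), tz = "UTC")))
  class(out) <- "result_bundle"
  out
}

# Write the bundle's tables under a directory.
write_bundle <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(res$pair, file.path(dir, "harmonized.tsv"))
  write_qq_table(res$qq$ab, file.path(dir, "qq_a_given_b.tsv"))
  write_qq_table(res$qq$ba, file.path(dir, "qq_b_given_a.tsv"))
  write_scored_snps(res$scored, file.path(dir, "scored_snps.tsv"))
  write_loci(res$loci, file.path(dir, "loci.tsv"))
  summary_lines <- c(
    sprintf("n_shared_loci\t%d", nrow(res$loci)),
    sprintf("pct_concordant\t%s", format(res$concordance$pct_concordant)),
    sprintf("rg\t%s", format(res$rg$rg)),
    sprintf("rg_se\t%s", format(res$rg$se)))
  if (!is.null(res$mixer)) {
    v <- res$mixer$venn
    summary_lines <- c(summary_lines,
      sprintf("venn_unique_a_k\t%.1f", v$unique_a),
      sprintf("venn_unique_b_k\t%.1f", v$unique_b),
      sprintf("venn_shared_k\t%.1f", v$shared))
  }
  writeLines(summary_lines, file.path(dir, "summary.tsv"))
  invisible(dir)
}
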