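# Derive independent sub-seeds from one master seed so that stages can be
# re-run separately yet reproducibly.
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Parameters of the bivariate generative model
#'
#' Defines a four-component causal architecture for two traits: a fraction
#' `pi_a` of SNPs is causal for trait A only, `pi_b` for B only, `pi_12` for
#' both, and the remainder is null. Causal effects are Gaussian on the
#' standardized-genotype scale with per-SNP variances `sigma_b2_a`,
#' `sigma_b2_b`; within the shared component the two traits' effects are
#' correlated with `rho12`. Residual inflation of the z-scores has variances
#' `sigma02_a`, `sigma02_b` and cross-trait correlation `rho0` (nonzero only
#' under sample overlap; the default 0 reflects non-overlapping cohorts).
#'
#' @param m total SNP count.
#' @param pi_a,pi_b,pi_12 causal fractions (A-only, B-only, shared).
#' @param sigma_b2_a,sigma_b2_b per-causal-SNP effect variances. The default
#'   `1e-3` with the default polygenicity gives SNP heritabilities around
#'   0.15 at `m = 5e4`, typical of complex behavioural traits.
#' @param rho12 effect correlation within the shared component, in `[-1, 1]`.
#' @param sigma02_a,sigma02_b residual variances of z (1 = no inflation).
#' @param rho0 residual cross-trait z correlation.
#' @param n_a,n_b GWAS sample sizes.
#' @param seed master seed; all sub-draws derive from it.
#' @return A `generative_params` list.
#' @export
generative_params <- function(m = 5e4, pi_a = 1e-3, pi_b = 1e-3,
                              pi_12 = 2e-3, sigma_b2_a = 1e-3,
                              sigma_b2_b = 1e-3, rho12 = 0.5,
                              sigma02_a = 1, sigma02_b = 1, rho0 = 0,
                              n_a = 1e5, n_b = 1e5, seed = 1) {
  gp <- list(m = as.integer(m), pi_a = pi_a, pi_b = pi_b, pi_12 = pi_12,
             sigma_b2_a = sigma_b2_a, sigma_b2_b = sigma_b2_b,
             rho12 = rho12, sigma02_a = sigma02_a, sigma02_b = sigma02_b,
             rho0 = rho0, n_a = n_a, n_b = n_b, seed = as.integer(seed))
  with(gp, {
    if (pi_a < 0 || pi_b < 0 || pi_12 < 0 || pi_a + pi_b + pi_12 > 1)
      stop("causal fractions must be nonnegative and sum to at most 1")
    if (sigma_b2_a <= 0 || sigma_b2_b <= 0 || sigma02_a <= 0 || sigma02_b <= 0)
      stop("variances must be positive")
    if (abs(rho12) > 1 || abs(rho0) > 1) stop("correlations must be in [-1, 1]")
    if (n_a <= 0 || n_b <= 0 || m < 1) stop("m and sample sizes must be positive")
  })
  structure(gp, class = "generative_params")
}

#' Simulate a block-diagonal LD structure
#'
#' Builds `n_blocks` exchangeable-correlation blocks of `block_size` SNPs
#' each (pairwise r equal to `rho_within`, which may be a vector recycled
#' over blocks). SNP positions are spaced 5 kb within a block, so a 50-SNP
#' block spans 245 kb — the scale of one genomic locus. Blocks are assigned
#' to chromosomes 1-22 round-robin; consecutive blocks on the same
#' chromosome are separated by 500 kb so that distinct blocks form distinct
#' loci unless signal is dense.
#'
#' @param n_blocks number of blocks.
#' @param block_size SNPs per block.
#' @param rho_within pairwise within-block correlation(s), `|rho| < 1` and
#'   `rho >= -1/(block_size - 1)` (positive semidefiniteness).
#' @param seed integer seed (reserved; the construction is deterministic).
#' @return An `ld_structure` with an attached SNP map (`snp_id, chrom, pos`).
#' @export
simulate_ld_blocks <- function(n_blocks, block_size, rho_within, seed = 1) {
  stopifnot(n_blocks >= 1, block_size >= 1)
  rho <- rep_len(rho_within, n_blocks)
  if (any(abs(rho) >= 1)) stop("|rho_within| must be < 1")
  if (block_size > 1 && any(rho < -1 / (block_size - 1)))
    stop("rho_within below -1/(k-1): block matrix not positive semidefinite")
  spacing <- 5000
  gap <- 500000
  chrom <- as.character((seq_len(n_blocks) - 1L) %% 22L + 1L)
  blk_on_chr <- stats::ave(seq_len(n_blocks), chrom, FUN = seq_along)
  all_ids <- sprintf("snp_%07d", seq_len(n_blocks * block_size))
  blocks <- lapply(seq_len(n_blocks), function(b) {
    R <- matrix(rho[b], block_size, block_size)
    diag(R) <- 1
    list(snp_id = all_ids[(b - 1L) * block_size + seq_len(block_size)], R = R)
  })
  within <- rep(seq_len(block_size) - 1, n_blocks)
  starts <- (blk_on_chr - 1) * (block_size * spacing + gap) + 1
  map <- data.table::data.table(
    snp_id = all_ids,
    chrom = rep(chrom, each = block_size),
    pos = rep(starts, each = block_size) + within * spacing)
  ld <- ld_structure(blocks)
  attr(ld, "snp_map") <- map
  ld
}

# Default LD used by the pair/trio simulators: 50-SNP blocks whose
# within-block correlation varies across blocks (drawn once, uniformly in
# [0.2, 0.9] under a derived seed) so that LD scores vary across the genome
# — required for LD score regression to be identified.
default_sim_ld <- function(m, seed, block_size = 50L) {
  n_blocks <- ceiling(m / block_size)
  set.seed(derive_seeds(seed, 3)[3])
  rho <- stats::runif(n_blocks, 0.2, 0.9)
  ld <- simulate_ld_blocks(n_blocks, block_size, rho)
  trim_ld(ld, m)
}

# Restrict an ld_structure (with snp_map) to its first m SNPs.
trim_ld <- function(ld, m) {
  total <- sum(vapply(ld$blocks, function(b) length(b$snp_id), integer(1)))
  if (total == m) return(ld)
  map <- attr(ld, "snp_map")
  keep_ids <- utils::head(unlist(lapply(ld$blocks, `[[`, "snp_id")), m)
  blocks <- lapply(ld$blocks, function(b) {
    sel <- b$snp_id %in% keep_ids
    if (!any(sel)) return(NULL)
    list(snp_id = b$snp_id[sel], R = b$R[sel, sel, drop = FALSE])
  })
  out <- ld_structure(Filter(Negate(is.null), blocks))
  attr(out, "snp_map") <- map[snp_id %in% keep_ids]
  out
}

#' Draw causal-component labels and joint effect sizes
#'
#' Labels are i.i.d. from `(pi0, pi_a, pi_b, pi_12)`; effects are Gaussian
#' with the component's variance, bivariate with correlation `rho12` in the
#' shared component.
#'
#' @param gp a [generative_params()] object.
#' @return data.table `snp_index, label, beta_a, beta_b` of `gp$m` rows,
#'   with `label` in `{null, a_only, b_only, shared}`.
#' @export
simulate_joint_effects <- function(gp) {
  set.seed(derive_seeds(gp$seed, 3)[1])
  m <- gp$m
  u <- stats::runif(m)
  lab <- rep("null", m)
  c1 <- gp$pi_a; c2 <- c1 + gp$pi_b; c3 <- c2 + gp$pi_12
  lab[u < c1] <- "a_only"
  lab[u >= c1 & u < c2] <- "b_only"
  lab[u >= c2 & u < c3] <- "shared"
  beta_a <- numeric(m); beta_b <- numeric(m)
  ia <- lab == "a_only"; ib <- lab == "b_only"; is <- lab == "shared"
  beta_a[ia] <- stats::rnorm(sum(ia), 0, sqrt(gp$sigma_b2_a))
  beta_b[ib] <- stats::rnorm(sum(ib), 0, sqrt(gp$sigma_b2_b))
  ns <- sum(is)
  if (ns > 0) {
    xa <- stats::rnorm(ns); xb <- stats::rnorm(ns)
    beta_a[is] <- sqrt(gp$sigma_b2_a) * xa
    beta_b[is] <- sqrt(gp$sigma_b2_b) *
      (gp$rho12 * xa + sqrt(1 - gp$rho12^2) * xb)
  }
  data.table::data.table(snp_index = seq_len(m), label = lab,
                         beta_a = beta_a, beta_b = beta_b)
}

#' Simulate paired GWAS z-scores from effects and LD
#'
#' The marginal GWAS z-score of SNP j for trait t is
#' `z_tj = sqrt(N_t) * sum_k r_jk beta_tk + eps_tj`, with residuals
#' `(eps_aj, eps_bj)` bivariate normal (variances `sigma02`, correlation
#' `rho0`) independent across SNPs. Genotypes are never materialized.
#'
#' @param effects output of [simulate_joint_effects()], aligned to `ld`'s
#'   SNP order.
#' @param ld an `ld_structure` with a `snp_map` attribute (from
#'   [simulate_ld_blocks()]).
#' @param gp a [generative_params()] object.
#' @return List of two `sumstats` tables (`a`, `b`) on identical alleles.
#' @export
simulate_zscores <- function(effects, ld, gp) {
  map <- attr(ld, "snp_map")
  if (is.null(map)) stop("ld must carry a snp_map attribute")
  if (nrow(map) != nrow(effects)) stop("effects and ld cover different SNP sets")
  set.seed(derive_seeds(gp$seed, 3)[2])
  m <- nrow(map)
  mu_a <- ld_mult(ld, effects$beta_a) * sqrt(gp$n_a)
  mu_b <- ld_mult(ld, effects$beta_b) * sqrt(gp$n_b)
  ea <- stats::rnorm(m); eb <- stats::rnorm(m)
  eps_a <- sqrt(gp$sigma02_a) * ea
  eps_b <- sqrt(gp$sigma02_b) * (gp$rho0 * ea + sqrt(1 - gp$rho0^2) * eb)
  z_a <- mu_a + eps_a
  z_b <- mu_b + eps_b
  list(
    a = sumstats(map$snp_id, map$chrom, map$pos, "A", "G", z_a, gp$n_a),
    b = sumstats(map$snp_id, map$chrom, map$pos, "A", "G", z_b, gp$n_b))
}

#' Simulate a harmonized two-trait GWAS with known ground truth
#'
#' Convenience wrapper: builds (or accepts) an LD structure, draws joint
#' effects and z-scores, and returns the harmonized pair together with the
#' truth table.
#'
#' @param gp a [generative_params()] object.
#' @param ld optional `ld_structure`; by default, 50-SNP exchangeable blocks
#'   with per-block correlations drawn uniformly in `[0.2, 0.9]`.
#' @param no_ld if `TRUE`, use identity LD (1-SNP blocks).
#' @return List with `pair` (harmonized_pair), `effects`, `ld`, `gp`.
#' @export
simulate_gwas_pair <- function(gp, ld = NULL, no_ld = FALSE) {
  if (is.null(ld)) {
    ld <- if (no_ld) default_sim_ld(gp$m, gp$seed, block_size = 1L)
          else default_sim_ld(gp$m, gp$seed)
  }
  effects <- simulate_joint_effects(gp)
  ss <- simulate_zscores(effects, ld, gp)
  pair <- suppressWarnings(harmonize_pair(ss$a, ss$b))
  map <- attr(ld, "snp_map")
  effects[, snp_id := map$snp_id]
  list(pair = pair, effects = effects, ld = ld, gp = gp)
}

#' Simulate three traits sharing causal components
#'
#' Extends the pair generator to three traits. Component labels are drawn
#' i.i.d. over the eight subsets of `{A, B, C}`; within any shared
#' component the participating traits' effects are exchangeably correlated
#' with `rho12`.
#'
#' @param m SNP count.
#' @param pi named causal fractions; any of
#'   `a, b, c, ab, ac, bc, abc` (missing entries are 0).
#' @param sigma_b2 per-causal-SNP effect variance (all traits).
#' @param rho12 effect correlation within shared components.
#' @param n sample size (all traits).
#' @param seed master seed.
#' @param ld optional `ld_structure`.
#' @return List with `sumstats` (list a/b/c), `effects`, `ld`.
#' @export
simulate_gwas_trio <- function(m = 5e4,
                               pi = c(a = 1e-3, b = 1e-3, c = 1e-3,
                                      abc = 1e-3),
                               sigma_b2 = 1e-3, rho12 = 0.9, n = 1e5,
                               seed = 1, ld = NULL) {
  comps <- c("a", "b", "c", "ab", "ac", "bc", "abc")
  pi_full <- stats::setNames(numeric(7), comps)
  pi_full[names(pi)] <- pi
  if (sum(pi_full) > 1) stop("causal fractions sum above 1")
  if (is.null(ld)) ld <- default_sim_ld(m, seed)
  map <- attr(ld, "snp_map")
  seeds <- derive_seeds(seed, 5)
  set.seed(seeds[1])
  u <- stats::runif(m)
  edges <- cumsum(pi_full)
  lab <- rep("null", m)
  lo <- 0
  for (i in seq_along(comps)) {
    lab[u >= lo & u < edges[i]] <- comps[i]
    lo <- edges[i]
  }
  beta <- matrix(0, m, 3, dimnames = list(NULL, c("a", "b", "c")))
  set.seed(seeds[2])
  for (comp in comps) {
    rows <- which(lab == comp)
    if (length(rows) == 0) next
    traits <- unique(unlist(strsplit(comp, "")))
    kt <- length(traits)
    x <- matrix(stats::rnorm(length(rows) * kt), ncol = kt)
    if (kt > 1) {
      Ssub <- matrix(rho12, kt, kt); diag(Ssub) <- 1
      x <- x %*% chol(Ssub)
    }
    beta[rows, traits] <- sqrt(sigma_b2) * x
  }
  set.seed(seeds[3])
  out <- vector("list", 3)
  names(out) <- c("a", "b", "c")
  for (t in 1:3) {
    z <- sqrt(n) * ld_mult(ld, beta[, t]) + stats::rnorm(m)
    out[[t]] <- sumstats(map$snp_id, map$chrom, map$pos, "A", "G", z, n)
  }
  effects <- data.table::data.table(snp_id = map$snp_id, label = lab,
                                    beta_a = beta[, 1], beta_b = beta[, 2],
                                    beta_c = beta[, 3])
  list(sumstats = out, effects = effects, ld = ld)
}
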