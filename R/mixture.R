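#' Parameters of the four-component bivariate causal mixture
#'
#' The joint distribution of a pruned SNP's z-score pair is modelled as a
#' mixture over four causal configurations: null, causal for A only, causal
#' for B only, and causal for both. Under configuration c the pair is
#' zero-mean bivariate normal with covariance `Sigma_c`: the null covariance
#' is `[[s0A, rho0*sqrt(s0A*s0B)], [., s0B]]`; the A-only component adds
#' `nA * sigma_b2_a` to the (A,A) entry; B-only adds `nB * sigma_b2_b` to
#' (B,B); the shared component adds both plus a covariance term
#' `rho12 * sqrt(nA * nB * sigma_b2_a * sigma_b2_b)`.
#'
#' @param pi0,pi_a,pi_b,pi_12 mixture weights; must sum to 1 (within 1e-9).
#' @param sigma_b2_a,sigma_b2_b per-causal-SNP effect variances (> 0).
#' @param sigma02_a,sigma02_b residual z variances (> 0).
#' @param rho12 effect correlation in the shared component.
#' @param rho0 residual correlation (sample overlap).
#' @return A `mixture_params` list.
#' @export
mixture_params <- function(pi0, pi_a, pi_b, pi_12, sigma_b2_a, sigma_b2_b,
                           sigma02_a = 1, sigma02_b = 1, rho12 = 0,
                           rho0 = 0) {
  w <- c(pi0, pi_a, pi_b, pi_12)
  if (any(w < 0)) stop("mixture weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) stop("mixture weights must sum to 1")
  if (sigma_b2_a <= 0 || sigma_b2_b <= 0 || sigma02_a <= 0 || sigma02_b <= 0)
    stop("variances must be positive")
  if (abs(rho12) > 1 || abs(rho0) > 1) stop("correlations must be in [-1, 1]")
  structure(list(pi0 = pi0, pi_a = pi_a, pi_b = pi_b, pi_12 = pi_12,
                 sigma_b2_a = sigma_b2_a, sigma_b2_b = sigma_b2_b,
                 sigma02_a = sigma02_a, sigma02_b = sigma02_b,
                 rho12 = rho12, rho0 = rho0),
            class = "mixture_params")
}

#' Component covariance matrices of the mixture at given sample sizes
#'
#' @param params a [mixture_params()] object.
#' @param n_a,n_b GWAS sample sizes.
#' @return List with vectors `w`, `sa`, `sb`, `cab` (one entry per
#'   component, in the order null, A-only, B-only, shared).
#' @export
component_covariances <- function(params, n_a, n_b) {
  p <- params
  cov0 <- p$rho0 * sqrt(p$sigma02_a * p$sigma02_b)
  cov12 <- p$rho12 * sqrt(n_a * n_b * p$sigma_b2_a * p$sigma_b2_b)
  list(w = c(p$pi0, p$pi_a, p$pi_b, p$pi_12),
       sa = c(p$sigma02_a,
              p$sigma02_a + n_a * p$sigma_b2_a,
              p$sigma02_a,
              p$sigma02_a + n_a * p$sigma_b2_a),
       sb = c(p$sigma02_b,
              p$sigma02_b,
              p$sigma02_b + n_b * p$sigma_b2_b,
              p$sigma02_b + n_b * p$sigma_b2_b),
       cab = c(cov0, cov0, cov0, cov0 + cov12))
}

# Effective (constant) sample sizes of a harmonized pair.
pair_n <- function(pair) {
  c(a = stats::median(pair$n_a, na.rm = TRUE),
    b = stats::median(pair$n_b, na.rm = TRUE))
}

#' Negative log-likelihood of a harmonized pair under the mixture
#'
#' Sums `-log` mixture density over SNPs, treating pruned SNPs as
#' independent. Sample sizes are taken as the per-trait medians of the
#' pair's `n` columns.
#'
#' @param params a [mixture_params()] object.
#' @param pair a pruned `harmonized_pair`.
#' @return Scalar negative log-likelihood.
#' @export
pair_neg_log_likelihood <- function(params, pair) {
  if (!inherits(params, "mixture_params"))
    params <- do.call(mixture_params, params)
  n <- pair_n(pair)
  cv <- component_covariances(params, n[["a"]], n[["b"]])
  det <- cv$sa * cv$sb - cv$cab^2
  if (any(det <= 0)) stop("component covariance not positive definite")
  bivariate_mixture_nll_cpp(pair$z_a, pair$z_b, cv$w, cv$sa, cv$sb, cv$cab)
}

#' LD-prune a harmonized pair for mixture fitting
#'
#' Greedy random pruning: SNPs are visited in a seeded random order and kept
#' iff their r-squared with every previously kept SNP of the same LD block
#' is below `r2_max`. The mixture likelihood treats the surviving SNPs as
#' independent.
#'
#' @param pair a `harmonized_pair`.
#' @param ld an `ld_structure`.
#' @param r2_max pruning threshold in `(0, 1]`.
#' @param seed integer seed.
#' @return The pruned `harmonized_pair`.
#' @export
prune_for_fit <- function(pair, ld, r2_max = 0.1, seed = 1) {
  stopifnot(r2_max > 0, r2_max <= 1)
  set.seed(seed)
  kept <- prune_random(ld, pair$snp_id, r2_max)
  out <- pair[pair$snp_id %in% kept]
  data.table::setattr(out, "class", class(pair))
  out[]
}

# --- parameter encoding -----------------------------------------------------
# Weights use a softmax with the null component's logit fixed at 0; variances
# are optimized on the log scale and correlations through atanh. `constraint`
# selects which weights are free:
#   none        : pi_a, pi_b, pi_12 free (8 params; 9 with rho0 free)
#   min_overlap : pi_12 = 0, rho12 dropped (6 params)
#   max_overlap : pi_a = 0, so pi_12 = min of the two total polygenicities
#                 by construction (7 params); traits are relabelled by the
#                 caller so that A is the less polygenic trait.

encode_params <- function(p, constraint = "none", fix_rho0 = TRUE) {
  lw <- function(x) log(max(x, 1e-12) / max(p$pi0, 1e-12))
  th <- switch(constraint,
    none = c(lw(p$pi_a), lw(p$pi_b), lw(p$pi_12)),
    min_overlap = c(lw(p$pi_a), lw(p$pi_b)),
    max_overlap = c(lw(p$pi_12), lw(p$pi_b)))
  th <- c(th, log(p$sigma_b2_a), log(p$sigma_b2_b),
          log(p$sigma02_a), log(p$sigma02_b))
  if (constraint != "min_overlap") th <- c(th, atanh(min(max(p$rho12, -0.99), 0.99)))
  if (!fix_rho0) th <- c(th, atanh(min(max(p$rho0, -0.99), 0.99)))
  th
}

decode_params <- function(th, constraint = "none", fix_rho0 = TRUE,
                          rho0 = 0) {
  nw <- if (constraint == "none") 3L else 2L
  e <- exp(pmin(th[seq_len(nw)], 30))
  denom <- 1 + sum(e)
  w <- e / denom
  pi0 <- 1 / denom
  i <- nw
  sb2a <- exp(th[i + 1]); sb2b <- exp(th[i + 2])
  s0a <- exp(th[i + 3]); s0b <- exp(th[i + 4])
  i <- i + 4
  r12 <- 0
  if (constraint != "min_overlap") { i <- i + 1; r12 <- tanh(th[i]) }
  r0 <- if (fix_rho0) rho0 else tanh(th[i + 1])
  switch(constraint,
    none = mixture_params(pi0, w[1], w[2], w[3], sb2a, sb2b, s0a, s0b,
                          r12, r0),
    min_overlap = mixture_params(pi0, w[1], w[2], 0, sb2a, sb2b, s0a, s0b,
                                 0, r0),
    max_overlap = mixture_params(pi0, 0, w[2], w[1], sb2a, sb2b, s0a, s0b,
                                 r12, r0))
}

# Univariate two-component fit of one trait's z-scores: z ~ (1-pi) N(0, s0)
# + pi N(0, s0 + n * sigma_b2). Used to initialize the bivariate fit.
fit_univariate_margin <- function(z, n, maxit = 500, n_sub = 20000) {
  nll_on <- function(x) {
    function(th) {
      pi1 <- stats::plogis(th[1])
      s0 <- exp(th[2]); sb2 <- exp(th[3])
      univariate_mixture_nll_cpp(x, c(1 - pi1, pi1), c(s0, s0 + n * sb2))
    }
  }
  fn <- nll_on(z)
  fn_explore <- if (length(z) > n_sub)
    nll_on(z[sample.int(length(z), n_sub)]) else fn
  excess <- max(mean(z^2) - 1, 1e-4)
  best <- NULL
  for (pi_start in c(1e-4, 1e-3, 1e-2)) {
    th0 <- c(stats::qlogis(pi_start), log(1), log(excess / (n * pi_start)))
    fit <- stats::optim(th0, fn_explore, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best <- stats::optim(best$par, fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-8))
  list(pi_t = stats::plogis(best$par[1]), sigma02 = exp(best$par[2]),
       sigma_b2 = exp(best$par[3]), nll = best$value)
}

fit_mixture_core <- function(za, zb, n_a, n_b, starts, constraint = "none",
                             fix_rho0 = TRUE, rho0 = 0, maxit = 600,
                             reltol = 1e-8, n_sub = 20000) {
  nll_on <- function(x, y) {
    function(th) {
      p <- decode_params(th, constraint, fix_rho0, rho0)
      cv <- component_covariances(p, n_a, n_b)
      bivariate_mixture_nll_cpp(x, y, cv$w, cv$sa, cv$sb, cv$cab)
    }
  }
  fn <- nll_on(za, zb)
  # explore starts on a subsample, polish the winner on the full data
  if (length(za) > n_sub) {
    sub <- sample.int(length(za), n_sub)
    fn_explore <- nll_on(za[sub], zb[sub])
  } else {
    fn_explore <- fn
  }
  best <- NULL
  trace <- numeric(length(starts))
  for (i in seq_along(starts)) {
    th0 <- encode_params(starts[[i]], constraint, fix_rho0)
    fit <- tryCatch(
      stats::optim(th0, fn_explore, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    trace[i] <- if (is.null(fit)) Inf else fit$value
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best) || !is.finite(best$value))
    stop("no optimizer start converged to a finite likelihood")
  best <- stats::optim(best$par, fn, method = "Nelder-Mead",
                       control = list(maxit = 2 * maxit, reltol = reltol))
  if (!is.finite(best$value))
    stop("optimizer failed to reach a finite likelihood on the full data")
  k <- length(best$par)
  params <- decode_params(best$par, constraint, fix_rho0, rho0)
  structure(list(params = params, nll = best$value, k = k,
                 aic = 2 * k + 2 * best$value,
                 convergence = best$convergence,
                 start_nll = trace, constraint = constraint),
            class = "mixer_fit")
}

# AIC-style parsimony: near the null the product pi * sigma_b2 is weakly
# identified and the optimizer may land on a large weight with a negligible
# variance. A causal component whose removal (weight reassigned to the null)
# costs less than one log-likelihood unit per freed parameter is therefore
# pruned to zero.
drop_negligible_components <- function(fit, za, zb, n_a, n_b, tol = 1) {
  p <- fit$params
  nll_of <- function(q) {
    cv <- component_covariances(q, n_a, n_b)
    bivariate_mixture_nll_cpp(za, zb, cv$w, cv$sa, cv$sb, cv$cab)
  }
  rebuild <- function(pa, pb, p12) {
    mixture_params(1 - pa - pb - p12, pa, pb, p12, p$sigma_b2_a,
                   p$sigma_b2_b, p$sigma02_a, p$sigma02_b,
                   if (p12 > 0) p$rho12 else 0, p$rho0)
  }
  drop_a <- p$pi_a > 0 && nll_of(rebuild(0, p$pi_b, p$pi_12)) - fit$nll < tol
  drop_b <- p$pi_b > 0 && nll_of(rebuild(p$pi_a, 0, p$pi_12)) - fit$nll < tol
  drop_s <- p$pi_12 > 0 &&
    nll_of(rebuild(p$pi_a, p$pi_b, 0)) - fit$nll < 2 * tol
  if (drop_a || drop_b || drop_s) {
    q <- rebuild(if (drop_a) 0 else p$pi_a, if (drop_b) 0 else p$pi_b,
                 if (drop_s) 0 else p$pi_12)
    fit$params <- q
    fit$nll <- nll_of(q)
    fit$aic <- 2 * fit$k + 2 * fit$nll
    fit$dropped <- c("a_only", "b_only", "shared")[c(drop_a, drop_b, drop_s)]
  }
  fit
}

#' Fit the bivariate causal mixture to a pruned pair
#'
#' Maximizes the mixture likelihood over transformed parameters (softmax
#' weights, log variances, atanh correlations) by derivative-free local
#' search from multiple seeded starts. The two univariate margins are fitted
#' first and their total polygenicities and variance components anchor the
#' bivariate starts, which differ in the assumed shared fraction and the
#' sign of the shared-effect correlation.
#'
#' @param pair a pruned `harmonized_pair` (warns below 10,000 SNPs).
#' @param n_starts number of optimizer starts (default 8).
#' @param seed integer seed controlling start jitter.
#' @param fix_rho0 keep the residual correlation fixed (at `rho0`); the
#'   default reflects non-overlapping GWAS cohorts.
#' @param rho0 value of the residual correlation when fixed.
#' @param maxit,reltol Nelder-Mead control.
#' @return A `mixer_fit`: `params` ([mixture_params()]), `nll`, `k` (free
#'   parameters), `aic = 2k + 2 nll`, convergence diagnostics, `n_snps`,
#'   and the univariate margin fits.
#' @export
fit_bivariate <- function(pair, n_starts = 8, seed = 1, fix_rho0 = TRUE,
                          rho0 = 0, maxit = 600, reltol = 1e-8) {
  if (nrow(pair) < 10000)
    warning("fewer than 10,000 pruned SNPs; mixture estimates will be noisy")
  n <- pair_n(pair)
  ua <- fit_univariate_margin(pair$z_a, n[["a"]])
  ub <- fit_univariate_margin(pair$z_b, n[["b"]])
  t_min <- max(min(ua$pi_t, ub$pi_t), 1e-8)

  set.seed(seed)
  fracs <- rep(c(0.2, 0.5, 0.8, 0.95), length.out = n_starts)
  r_sign <- rep(c(1, -1), each = 4, length.out = n_starts)
  jitter <- matrix(stats::rnorm(n_starts * 2, 0, 0.1), ncol = 2)
  starts <- lapply(seq_len(n_starts), function(i) {
    pi12 <- fracs[i] * t_min
    pi_a <- max(ua$pi_t - pi12, 1e-9)
    pi_b <- max(ub$pi_t - pi12, 1e-9)
    mixture_params(1 - pi_a - pi_b - pi12, pi_a, pi_b, pi12,
                   ua$sigma_b2 * exp(jitter[i, 1]),
                   ub$sigma_b2 * exp(jitter[i, 2]),
                   ua$sigma02, ub$sigma02,
                   rho12 = r_sign[i] * 0.5, rho0 = rho0)
  })
  fit <- fit_mixture_core(pair$z_a, pair$z_b, n[["a"]], n[["b"]], starts,
                          constraint = "none", fix_rho0 = fix_rho0,
                          rho0 = rho0, maxit = maxit, reltol = reltol)
  fit <- drop_negligible_components(fit, pair$z_a, pair$z_b,
                                    n[["a"]], n[["b"]])
  fit$n_snps <- nrow(pair)
  fit$n_a <- n[["a"]]; fit$n_b <- n[["b"]]
  fit$univariate <- list(a = ua, b = ub)
  fit
}

#' @export
print.mixer_fit <- function(x, ...) {
  p <- x$params
  cat("bivariate causal mixture fit (", x$n_snps, " SNPs)\n", sep = "")
  cat(sprintf("  pi_a=%.3g pi_b=%.3g pi_12=%.3g rho12=%.3f rho0=%.3f\n",
              p$pi_a, p$pi_b, p$pi_12, p$rho12, p$rho0))
  cat(sprintf("  sigma_b2: %.3g / %.3g   sigma0^2: %.3f / %.3f\n",
              p$sigma_b2_a, p$sigma_b2_b, p$sigma02_a, p$sigma02_b))
  cat(sprintf("  nll=%.2f  k=%d  AIC=%.2f\n", x$nll, x$k, x$aic))
  invisible(x)
}

#' Causal variants explaining 90% of SNP heritability
#'
#' For i.i.d. Gaussian causal effects, the heritability fraction carried by
#' variants whose standardized squared effect exceeds `t` equals
#' `P(chisq_3 > t)` (from the identity `E[X 1{X>t}] = k P(chisq_{k+2} > t)`
#' for `X ~ chisq_k` at `k = 1`). Solving `P(chisq_3 > t*) = 0.90`, the
#' fraction of causal variants retained is `q* = P(chisq_1 > t*)`, and the
#' reported count is `q*` times the total causal count. The transform is
#' linear, so per-component counts add.
#'
#' @param n_causal total causal-variant count (vectorized, `>= 0`).
#' @return `q* * n_causal`.
#' @export
n_causal_90 <- function(n_causal) {
  if (any(n_causal < 0)) stop("n_causal must be nonnegative")
  t_star <- stats::qchisq(0.90, df = 3, lower.tail = FALSE)
  q_star <- stats::pchisq(t_star, df = 1, lower.tail = FALSE)
  q_star * n_causal
}

#' Venn counts of unique and shared causal variants
#'
#' Applies the 90%-of-SNP-heritability transform per mixture component, so
#' each trait's total equals its unique count plus the shared count.
#' Counts are reported in thousands, rounded to one decimal.
#'
#' @param fit a `mixer_fit`.
#' @param m total SNP count the mixture weights refer to.
#' @return List with `unique_a`, `unique_b`, `shared`, `total_a`, `total_b`
#'   (thousands of causal variants).
#' @export
venn_summary <- function(fit, m) {
  p <- fit$params
  k <- function(x) round(n_causal_90(x * m) / 1000, 1)
  list(unique_a = k(p$pi_a), unique_b = k(p$pi_b), shared = k(p$pi_12),
       total_a = k(p$pi_a) + k(p$pi_12), total_b = k(p$pi_b) + k(p$pi_12))
}

#' Genetic correlation implied by a mixture fit
#'
#' `rg = rho12 * pi_12 / sqrt((pi_a + pi_12) * (pi_b + pi_12))`, assuming a
#' common effect-variance scale across components.
#'
#' @param fit a `mixer_fit` (or `mixture_params`).
#' @return Scalar genetic correlation.
#' @export
implied_rg <- function(fit) {
  p <- if (inherits(fit, "mixer_fit")) fit$params else fit
  ta <- p$pi_a + p$pi_12
  tb <- p$pi_b + p$pi_12
  if (ta <= 0 || tb <= 0) return(0)
  p$rho12 * p$pi_12 / sqrt(ta * tb)
}

#' AIC comparison against minimum- and maximum-overlap scenarios
#'
#' Refits the mixture with the shared weight constrained to zero
#' (minimum overlap) and to the smaller trait's total polygenicity
#' (maximum overlap: the less polygenic trait's causal variants are all
#' shared), and reports `AIC_constrained - AIC_best` for each. Positive
#' deltas mean the data distinguish the best fit from the constrained
#' scenario; a non-positive delta is flagged indistinguishable.
#'
#' @param fit a `mixer_fit` from [fit_bivariate()].
#' @param pair the pruned `harmonized_pair` used for the fit.
#' @param n_starts optimizer starts per constrained fit.
#' @param seed integer seed (start exploration subsampling).
#' @param maxit,reltol Nelder-Mead control.
#' @return List with `delta_aic_vs_min`, `delta_aic_vs_max`,
#'   `distinguishable` flag, and the two constrained fits.
#' @export
overlap_aic <- function(fit, pair, n_starts = 4, seed = 1, maxit = 600,
                        reltol = 1e-8) {
  set.seed(seed)
  p <- fit$params
  n <- pair_n(pair)
  fix_rho0 <- TRUE
  t_a <- p$pi_a + p$pi_12
  t_b <- p$pi_b + p$pi_12
  swap <- t_b < t_a   # relabel so trait A is the less polygenic one
  za <- if (swap) pair$z_b else pair$z_a
  zb <- if (swap) pair$z_a else pair$z_b
  na <- if (swap) n[["b"]] else n[["a"]]
  nb <- if (swap) n[["a"]] else n[["b"]]
  base <- if (swap)
    mixture_params(p$pi0, p$pi_b, p$pi_a, p$pi_12, p$sigma_b2_b,
                   p$sigma_b2_a, p$sigma02_b, p$sigma02_a, p$rho12, p$rho0)
  else p

  mk_starts <- function(mod) {
    lapply(seq_len(n_starts), function(i) {
      q <- base
      if (mod == "min") {
        q <- mixture_params(1 - (q$pi_a + q$pi_12) - q$pi_b,
                            q$pi_a + q$pi_12, q$pi_b, 0,
                            q$sigma_b2_a, q$sigma_b2_b,
                            q$sigma02_a, q$sigma02_b, 0, q$rho0)
      } else {
        t_min <- q$pi_a + q$pi_12
        q <- mixture_params(1 - t_min - q$pi_b, 0, q$pi_b, t_min,
                            q$sigma_b2_a, q$sigma_b2_b,
                            q$sigma02_a, q$sigma02_b,
                            if (i %% 2 == 0) -max(abs(q$rho12), 0.3)
                            else max(abs(q$rho12), 0.3),
                            q$rho0)
      }
      # scale variance starts across restarts
      mixture_params(q$pi0, q$pi_a, q$pi_b, q$pi_12,
                     q$sigma_b2_a * c(1, 0.5, 2, 1)[(i - 1) %% 4 + 1],
                     q$sigma_b2_b * c(1, 2, 0.5, 1)[(i - 1) %% 4 + 1],
                     q$sigma02_a, q$sigma02_b, q$rho12, q$rho0)
    })
  }

  fit_min <- tryCatch(
    fit_mixture_core(za, zb, na, nb, mk_starts("min"),
                     constraint = "min_overlap", fix_rho0 = fix_rho0,
                     rho0 = p$rho0, maxit = maxit, reltol = reltol),
    error = function(e) NULL)
  fit_max <- tryCatch(
    fit_mixture_core(za, zb, na, nb, mk_starts("max"),
                     constraint = "max_overlap", fix_rho0 = fix_rho0,
                     rho0 = p$rho0, maxit = maxit, reltol = reltol),
    error = function(e) NULL)

  d_min <- if (is.null(fit_min)) NA_real_ else fit_min$aic - fit$aic
  d_max <- if (is.null(fit_max)) NA_real_ else fit_max$aic - fit$aic
  list(delta_aic_vs_min = d_min, delta_aic_vs_max = d_max,
       distinguishable = isTRUE(d_min > 0) && isTRUE(d_max > 0),
       fit_min = fit_min, fit_max = fit_max)
}

#' Simulate z-score pairs from a fitted mixture
#'
#' @param fit a `mixer_fit`.
#' @param m number of SNPs to draw.
#' @param seed integer seed.
#' @return data.table `z_a, z_b, component`.
#' @export
simulate_from_fit <- function(fit, m, seed = 1) {
  set.seed(seed)
  cv <- component_covariances(fit$params, fit$n_a, fit$n_b)
  comp <- sample.int(4, m, replace = TRUE, prob = cv$w)
  x <- stats::rnorm(m); y <- stats::rnorm(m)
  sa <- cv$sa[comp]; sb <- cv$sb[comp]; cab <- cv$cab[comp]
  z_a <- sqrt(sa) * x
  z_b <- (cab / sqrt(sa)) * x + sqrt(pmax(sb - cab^2 / sa, 0)) * y
  data.table::data.table(z_a = z_a, z_b = z_b, component = comp)
}

#' Modeled versus actual conditional Q-Q tables
#'
#' Simulates z-pairs from the fitted mixture (same SNP count as the data)
#' and builds conditional Q-Q tables for both the simulated and the actual
#' pair, for visual assessment of model fit.
#'
#' @param fit a `mixer_fit`.
#' @param pair the pruned `harmonized_pair` the fit used.
#' @param seed integer seed for the model draw.
#' @param thresholds,n_points passed to [conditional_qq()].
#' @return List of two `qq_table`s: `actual` and `modeled`.
#' @export
model_vs_actual_qq <- function(fit, pair, seed = 1,
                               thresholds = c(1, 0.1, 0.01, 0.001),
                               n_points = 1000) {
  sim <- simulate_from_fit(fit, nrow(pair), seed = seed)
  sim_pair <- data.table::data.table(
    snp_id = paste0("sim_", seq_len(nrow(sim))),
    p_a = 2 * stats::pnorm(-abs(sim$z_a)),
    p_b = 2 * stats::pnorm(-abs(sim$z_b)))
  list(actual = conditional_qq(pair, thresholds, n_points),
       modeled = conditional_qq(sim_pair, thresholds, n_points))
}
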