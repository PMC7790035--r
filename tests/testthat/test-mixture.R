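random_params <- function(seed) {
  set.seed(seed)
  w <- c(0.9, runif(3))
  w <- w / sum(w)
  mixture_params(w[1], w[2], w[3], w[4],
                 sigma_b2_a = runif(1, 1e-4, 1e-2),
                 sigma_b2_b = runif(1, 1e-4, 1e-2),
                 sigma02_a = runif(1, 0.8, 1.3),
                 sigma02_b = runif(1, 0.8, 1.3),
                 rho12 = runif(1, -0.9, 0.9), rho0 = runif(1, -0.3, 0.3))
}

test_that("null-only likelihood reduces to the standard bivariate normal", {
  set.seed(1)
  pair <- make_pair(paste0("s", 1:100), 1, 1:100, rnorm(100), rnorm(100),
                    n_a = 1e4, n_b = 1e4)
  p0 <- mixture_params(1, 0, 0, 0, 1e-3, 1e-3, 1, 1, 0, 0)
  nll <- pair_neg_log_likelihood(p0, pair)
  expect_equal(nll, sum(log(2 * pi) + (pair$z_a^2 + pair$z_b^2) / 2),
               tolerance = 1e-10)
})

test_that("likelihood matches a direct high-precision mixture oracle", {
  for (s in 1:5) {
    set.seed(s)
    pair <- make_pair(paste0("s", 1:10), 1, 1:10, rnorm(10, sd = 2),
                      rnorm(10, sd = 2), n_a = 5e4, n_b = 5e4)
    p <- random_params(100 + s)
    cv <- component_covariances(p, 5e4, 5e4)
    expect_equal(pair_neg_log_likelihood(p, pair),
                 bf_mixture_nll(pair$z_a, pair$z_b, cv$w, cv$sa, cv$sb,
                                cv$cab),
                 tolerance = 1e-10)
  }
})

test_that("invalid mixture weights are rejected", {
  expect_error(mixture_params(0.5, 0.5, 0.1, 0.1, 1e-3, 1e-3),
               "sum to 1")
  expect_error(mixture_params(1.2, -0.2, 0, 0, 1e-3, 1e-3), "nonnegative")
  expect_error(mixture_params(1, 0, 0, 0, -1, 1e-3), "positive")
})

test_that("pruning respects the r2 threshold and keeps maximal sets", {
  ids <- paste0("s", 1:20)
  pair <- make_pair(ids, 1, 1:20, rnorm(20), rnorm(20))
  # identity LD: everything kept
  expect_equal(nrow(prune_for_fit(pair, identity_ld(ids), 0.1)), 20)
  # exchangeable above threshold: one per block
  ld_hi <- grouped_ld(ids, 5, 0.8)
  expect_equal(nrow(prune_for_fit(pair, ld_hi, r2_max = 0.1, seed = 2)), 4)
  # random blocks: kept set valid and maximal vs brute force
  for (s in 1:20) {
    set.seed(s)
    R <- cov2cor(crossprod(matrix(rnorm(400), 20, 20)))
    ld <- ld_structure(list(list(snp_id = ids, R = R)))
    kept <- prune_for_fit(pair, ld, r2_max = 0.3, seed = s)$snp_id
    expect_true(bf_prune_valid(ld, kept, 0.3))
    for (drop in setdiff(ids, kept)) {
      r2 <- R[match(drop, ids), match(kept, ids)]^2
      expect_true(any(r2 >= 0.3))   # every dropped SNP conflicts with kept
    }
  }
})

test_that("n_causal_90 applies the chi-square tail transform", {
  expect_equal(n_causal_90(0), 0)
  expect_equal(n_causal_90(2 * 1234), 2 * n_causal_90(1234))
  expect_error(n_causal_90(-1))
  # Monte-Carlo order-statistics oracle (reduced draw; the acceptance
  # suite repeats this at 1e6 draws)
  set.seed(42)
  x <- rchisq(2e5, df = 1)
  xs <- sort(x, decreasing = TRUE)
  q_mc <- which(cumsum(xs) >= 0.9 * sum(xs))[1] / length(x)
  expect_lt(abs(n_causal_90(1) - q_mc) / q_mc, 0.02)
})

test_that("venn counts add per trait and match hand arithmetic", {
  p <- mixture_params(1 - 3e-3 - 1e-3 - 2e-3, 3e-3, 1e-3, 2e-3,
                      1e-3, 1e-3)
  fit <- structure(list(params = p), class = "mixer_fit")
  v <- venn_summary(fit, m = 1e6)
  q <- pchisq(qchisq(0.9, 3, lower.tail = FALSE), 1, lower.tail = FALSE)
  expect_equal(v$unique_a, round(q * 3e-3 * 1e6 / 1000, 1))
  expect_equal(v$shared, round(q * 2e-3 * 1e6 / 1000, 1))
  expect_equal(v$total_a, v$unique_a + v$shared)
  expect_equal(v$total_b, v$unique_b + v$shared)
  p0 <- mixture_params(1 - 4e-3, 3e-3, 1e-3, 0, 1e-3, 1e-3)
  v0 <- venn_summary(structure(list(params = p0), class = "mixer_fit"), 1e6)
  expect_equal(v0$shared, 0)
})

test_that("the fit-implied genetic correlation is the stated plug-in", {
  p <- mixture_params(1 - 4e-3, 1e-3, 2e-3, 1e-3, 1e-3, 1e-3, rho12 = 0.8)
  expect_equal(implied_rg(structure(list(params = p), class = "mixer_fit")),
               0.8 * 1e-3 / sqrt(2e-3 * 3e-3))
})

test_that("fits are deterministic given data and seed", {
  gp <- generative_params(m = 2e4, pi_a = 1e-3, pi_b = 1e-3, pi_12 = 2e-3,
                          rho12 = 0.9, n_a = 5e4, n_b = 5e4, seed = 7)
  sim <- simulate_gwas_pair(gp, no_ld = TRUE)
  f1 <- suppressWarnings(fit_bivariate(sim$pair, seed = 3))
  f2 <- suppressWarnings(fit_bivariate(sim$pair, seed = 3))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$nll, f2$nll)
  expect_identical(f1$aic, 2 * f1$k + 2 * f1$nll)
  s1 <- simulate_from_fit(f1, 100, seed = 5)
  s2 <- simulate_from_fit(f1, 100, seed = 5)
  expect_identical(s1, s2)
})

test_that("modeled-vs-actual Q-Q separates a deliberately wrong model", {
  gp <- generative_params(m = 3e4, pi_a = 1e-3, pi_b = 1e-3, pi_12 = 2e-3,
                          rho12 = 0.9, n_a = 5e4, n_b = 5e4, seed = 13)
  sim <- simulate_gwas_pair(gp, no_ld = TRUE)
  fit <- suppressWarnings(fit_bivariate(sim$pair, seed = 2))
  mv <- model_vs_actual_qq(fit, sim$pair, seed = 1)
  # self-consistent fit: the most stringent stratum agrees within MC noise
  a <- median(mv$actual[stratum == 0.001 & is.finite(observed)]$observed)
  m_ <- median(mv$modeled[stratum == 0.001 & is.finite(observed)]$observed)
  expect_lt(abs(a - m_), 0.3)
  # wrong model: force pi12 = 0, the conditional stratum must deflate
  p_wrong <- fit$params
  p_wrong <- mixture_params(p_wrong$pi0 + p_wrong$pi_12, p_wrong$pi_a,
                            p_wrong$pi_b, 0, p_wrong$sigma_b2_a,
                            p_wrong$sigma_b2_b, p_wrong$sigma02_a,
                            p_wrong$sigma02_b, 0, p_wrong$rho0)
  fit_wrong <- fit; fit_wrong$params <- p_wrong
  mw <- model_vs_actual_qq(fit_wrong, sim$pair, seed = 1)
  w_ <- median(mw$modeled[stratum == 0.001 & is.finite(observed)]$observed)
  expect_gt(a - w_, 0.3)
})
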