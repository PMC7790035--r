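# A constructed 1000-SNP input with exact counts: 100 SNPs with p2 <= 0.1,
# 20 of them also with p1 <= 0.01. Identity LD makes pruning a no-op, so
# averaged counts are exact.
counting_pair <- function() {
  m <- 1000
  p1 <- rep(0.5, m); p2 <- rep(0.5, m)
  p2[1:100] <- 0.1
  p1[1:20] <- 0.01
  p1[21:100] <- 0.2
  # vary the remainder so the input is not degenerate
  p1[101:m] <- seq(0.21, 0.99, length.out = m - 100)
  p2[101:m] <- seq(0.11, 0.99, length.out = m - 100)
  make_pair(paste0("s", 1:m), 1, 1:m, z_a = qnorm(p1 / 2),
            z_b = qnorm(p2 / 2), p_a = p1, p_b = p2)
}

test_that("grid cells follow the counting formula before enforcement", {
  pair <- counting_pair()
  grid <- build_fdr_grid(pair, identity_ld(pair$snp_id), primary = "a",
                         n_prune = 3, monotone = FALSE)
  i <- which(grid$edges == 2)   # -log10 p1 = 2
  j <- which(grid$edges == 1)   # -log10 p2 = 1
  expect_equal(grid$counts[i, j], 20)
  expect_equal(grid$c2[j], 100)
  expect_equal(grid$values[i, j], 0.01 * 100 / 20)
})

test_that("the p2 = 1 column is the unconditional empirical-Bayes FDR", {
  pair <- counting_pair()
  grid <- build_fdr_grid(pair, identity_ld(pair$snp_id), primary = "a",
                         n_prune = 2, monotone = FALSE)
  m <- nrow(pair)
  x1 <- -log10(pair$p_a)
  for (i in which(grid$counts[, 1] >= 1)) {
    c1 <- sum(x1 >= grid$edges[i])
    expect_equal(grid$values[i, 1], min(1, 10^(-grid$edges[i]) * m / c1))
  }
})

test_that("grids are monotone, anchored at 1, and in [0, 1]", {
  set.seed(3)
  m <- 5000
  pair <- make_pair(paste0("s", 1:m), 1, 1:m, rnorm(m), rnorm(m))
  grid <- build_fdr_grid(pair, identity_ld(pair$snp_id), n_prune = 2)
  expect_true(all(grid$values >= 0 & grid$values <= 1))
  expect_true(all(grid$values[1, ] == 1))
  expect_true(all(apply(grid$values, 2, function(v) all(diff(v) <= 1e-12))))
})

test_that("degenerate constant p-values are rejected", {
  pair <- make_pair(paste0("s", 1:10), 1, 1:10, rep(1, 10), rep(1, 10))
  expect_error(build_fdr_grid(pair, identity_ld(pair$snp_id)),
               "degenerate")
})

test_that("interpolation is exact at nodes and bounded between them", {
  pair <- counting_pair()
  ld <- identity_ld(pair$snp_id)
  grid <- build_fdr_grid(pair, ld, primary = "a", n_prune = 2)
  # SNP sitting exactly on a node
  node_pair <- make_pair("x", 1, 1, z_a = qnorm(0.01 / 2),
                         z_b = qnorm(0.1 / 2), p_a = 0.01, p_b = 0.1)
  i <- which(grid$edges == 2); j <- which(grid$edges == 1)
  expect_equal(condfdr_assign(node_pair, grid), grid$values[i, j])
  # between nodes: within the surrounding cell values
  mid <- make_pair("y", 1, 1, z_a = 1, z_b = 1,
                   p_a = 10^-2.05, p_b = 10^-1.03)
  v <- condfdr_assign(mid, grid)
  cell <- grid$values[i:(i + 1), j:(j + 1)]
  expect_gte(v, min(cell)); expect_lte(v, max(cell))
  # monotone in p1 at fixed p2
  two <- make_pair(c("a", "b"), 1, 1:2, z_a = c(1, 1), z_b = c(1, 1),
                   p_a = c(0.001, 0.01), p_b = c(0.05, 0.05))
  vv <- condfdr_assign(two, grid)
  expect_lte(vv[1], vv[2])
})

test_that("conjFDR is the exact maximum and symmetric in the traits", {
  set.seed(4)
  m <- 3000
  pair <- make_pair(paste0("s", 1:m), 1, 1:m, rnorm(m) * c(1, 2),
                    rnorm(m) * c(2, 1))
  ld <- identity_ld(pair$snp_id)
  scored <- conjfdr_analysis(pair, ld, n_prune = 2, seed = 5)
  expect_identical(scored$conjfdr,
                   pmax(scored$condfdr_a_given_b, scored$condfdr_b_given_a))
  expect_true(all(scored$conjfdr >= scored$condfdr_a_given_b))
  expect_true(all(scored$conjfdr >= scored$condfdr_b_given_a))
  # swapping the traits leaves conjfdr unchanged
  rev <- data.table::copy(pair)
  data.table::setnames(rev, c("z_a", "z_b", "p_a", "p_b", "n_a", "n_b"),
                       c("z_b", "z_a", "p_b", "p_a", "n_b", "n_a"))
  grids <- attr(scored, "grids")
  g_ab <- build_fdr_grid(rev, ld, primary = "b", n_prune = 2,
                         seed = grids$ab$seed)
  g_ba <- build_fdr_grid(rev, ld, primary = "a", n_prune = 2,
                         seed = grids$ba$seed)
  scored_rev <- conjfdr_assign(rev, g_ba, g_ab)
  expect_equal(scored_rev$conjfdr, scored$conjfdr)
})

test_that("grid build is order-invariant and seed-deterministic", {
  gp <- generative_params(m = 5000, pi_a = 2e-3, pi_12 = 2e-3, seed = 6)
  sim <- simulate_gwas_pair(gp)
  g1 <- build_fdr_grid(sim$pair, sim$ld, n_prune = 10, seed = 9)
  g2 <- build_fdr_grid(sim$pair[sample.int(nrow(sim$pair))], sim$ld,
                       n_prune = 10, seed = 9)
  expect_identical(g1$values, g2$values)
})

test_that("trio conjFDR is the max of the three pairwise values", {
  s <- function(v) {
    dt <- data.table::data.table(snp_id = c("s1", "s2"), chrom = "1",
                                 pos = 1:2, conjfdr = v)
    dt
  }
  trio <- trio_conjfdr(s(c(0.01, 0.2)), s(c(0.02, 0.01)), s(c(0.03, 0.01)))
  expect_equal(trio$trio_conjfdr, c(0.03, 0.2))
  # max dominance: any pairwise value above tau forces the trio above tau
  expect_true(all(trio$trio_conjfdr >= trio$conjfdr_ab))
  expect_error(trio_conjfdr(s(c(1, 1))[0], s(c(1, 1)), s(c(1, 1))),
               "empty")
})

test_that("three-way planted overlap enriches trio-significant SNPs", {
  trio <- simulate_gwas_trio(m = 3e4, pi = c(abc = 1e-3, ab = 1e-3),
                             rho12 = 0.9, n = 2e5, seed = 21)
  pr <- list(
    ab = suppressWarnings(harmonize_pair(trio$sumstats$a, trio$sumstats$b)),
    ac = suppressWarnings(harmonize_pair(trio$sumstats$a, trio$sumstats$c)),
    bc = suppressWarnings(harmonize_pair(trio$sumstats$b, trio$sumstats$c)))
  sc <- lapply(seq_along(pr), function(i)
    conjfdr_analysis(pr[[i]], trio$ld, n_prune = 10, seed = 30 + i))
  tt <- trio_conjfdr(sc[[1]], sc[[2]], sc[[3]])
  tt <- merge(tt, trio$effects[, .(snp_id, label)], by = "snp_id")
  idx <- crosstrait:::ld_index(trio$ld)
  tt <- merge(tt, idx[, .(snp_id, block)], by = "snp_id")
  abc_blocks <- tt[label == "abc", unique(block)]
  ab_blocks <- setdiff(tt[label == "ab", unique(block)], abc_blocks)
  hit <- tt[trio_conjfdr < 0.05]
  rate_abc <- mean(tt[block %in% abc_blocks]$trio_conjfdr < 0.05)
  rate_ab <- mean(tt[block %in% ab_blocks]$trio_conjfdr < 0.05)
  expect_gt(rate_abc, rate_ab)
})
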