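scored_table <- function(snp_id, chrom, pos, conjfdr, z_a = NULL,
                         z_b = NULL) {
  n <- length(snp_id)
  data.table::data.table(
    snp_id = snp_id, chrom = as.character(chrom), pos = pos,
    z_a = if (is.null(z_a)) rep(2, n) else z_a,
    z_b = if (is.null(z_b)) rep(2, n) else z_b,
    p_a = rep(1e-4, n), p_b = rep(1e-4, n), conjfdr = conjfdr)
}

test_that("a lone significant SNP forms a degenerate single-SNP locus", {
  sc <- scored_table("s1", 1, 5000, 0.01)
  loci <- define_loci(sc, identity_ld("s1"))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 5000)
  expect_equal(loci$end, 5000)
  expect_equal(loci$lead_snp, "s1")
  expect_equal(loci$n_ind_sig, 1L)
})

test_that("nothing significant yields an empty locus table, not an error", {
  sc <- scored_table(c("s1", "s2"), 1, c(1, 2), c(0.5, 0.9))
  expect_equal(nrow(define_loci(sc, identity_ld(c("s1", "s2")))), 0)
})

test_that("the 250 kb merge rule separates and joins envelopes", {
  sc2 <- scored_table(c("s1", "s2"), 1, c(1e6, 1e6 + 300000),
                      c(0.01, 0.02))
  expect_equal(nrow(define_loci(sc2, identity_ld(c("s1", "s2")))), 2)
  sc1 <- scored_table(c("s1", "s2"), 1, c(1e6, 1e6 + 200000),
                      c(0.01, 0.02))
  merged <- define_loci(sc1, identity_ld(c("s1", "s2")))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start, 1e6)
  expect_equal(merged$end, 1e6 + 200000)
  expect_equal(merged$lead_snp, "s1")
  expect_equal(merged$n_ind_sig, 2L)
})

test_that("candidates in LD above r2_indep join the envelope", {
  ids <- paste0("s", 1:5)
  l <- c(0.95, 0.947, 0.527, 0, 0)      # one-factor loadings: PSD by
  R <- diag(1 - l^2) + outer(l, l)      # construction
  diag(R) <- 1
  # r2(s1,s2) = 0.81 >= 0.6 (candidate); r2(s1,s3) = 0.25 < 0.6 (excluded)
  ld <- ld_structure(list(list(snp_id = ids, R = R)))
  sc <- scored_table(ids, 1, c(100, 200, 300, 400, 500) * 1000,
                     c(0.01, 0.08, 0.08, 0.5, 0.5))
  loci <- define_loci(sc, ld)
  expect_equal(nrow(loci), 1)
  expect_equal(sort(loci$cand_snps[[1]]), c("s1", "s2"))
  expect_equal(loci$end, 200000)
})

test_that("locus definition equals the brute-force FUMA rules", {
  for (s in 1:40) {
    set.seed(s)
    n <- 20
    ids <- paste0("s", 1:n)
    R <- cov2cor(crossprod(matrix(rnorm(2 * n * n), 2 * n, n)))
    ld <- ld_structure(list(list(snp_id = ids, R = R)))
    sc <- scored_table(ids, 1, sort(sample.int(2e6, n)),
                       round(runif(n, 0, 0.2), 3))
    got <- define_loci(sc, ld)
    want <- bf_define_loci(sc, ld)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
      next
    }
    expect_equal(nrow(got), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$start[i], want[[i]]$start)
      expect_equal(got$end[i], want[[i]]$end)
      expect_equal(got$lead_snp[i], want[[i]]$lead_snp)
      expect_equal(sort(got$ind_sig_snps[[i]]), want[[i]]$ind_sig)
      expect_equal(sort(got$cand_snps[[i]]), want[[i]]$cands)
    }
  }
})

test_that("output is invariant to row order and ties break by position", {
  ids <- paste0("s", 1:6)
  sc <- scored_table(ids, 1, c(10, 20, 30, 40, 50, 60) * 1e4,
                     c(0.02, 0.02, 0.3, 0.3, 0.01, 0.5))
  ld <- identity_ld(ids)
  a <- define_loci(sc, ld)
  b <- define_loci(sc[c(4, 2, 6, 1, 3, 5)], ld)
  expect_equal(as.data.frame(a[, .(chrom, start, end, lead_snp)]),
               as.data.frame(b[, .(chrom, start, end, lead_snp)]))
  # equal conjfdr at s1/s2: lead of their merged locus is the earlier one
  expect_equal(a[start == 1e5]$lead_snp, "s1")
})

test_that("every candidate SNP belongs to exactly one locus interval", {
  set.seed(77)
  gp <- generative_params(m = 5000, pi_a = 0, pi_b = 0, pi_12 = 5e-3,
                          rho12 = 0.9, seed = 77)
  sim <- simulate_gwas_pair(gp)
  scored <- conjfdr_analysis(sim$pair, sim$ld, n_prune = 5, seed = 1)
  loci <- define_loci(scored, sim$ld)
  if (nrow(loci) > 0) {
    cands <- unlist(loci$cand_snps)
    expect_equal(anyDuplicated(cands), 0)
    for (i in seq_len(nrow(loci))) {
      pos <- scored$pos[match(loci$cand_snps[[i]], scored$snp_id)]
      expect_true(all(pos >= loci$start[i] & pos <= loci$end[i]))
    }
  }
})

test_that("concordance percentages follow the sign rule", {
  mk <- function(z_a, z_b) {
    n <- length(z_a)
    loci <- data.table::data.table(
      chrom = "1", start = seq_len(n), end = seq_len(n),
      lead_snp = paste0("s", seq_len(n)), lead_conjfdr = 0.01,
      z_a = z_a, z_b = z_b, concordant = sign(z_a) * sign(z_b) > 0,
      n_ind_sig = 1L, n_cand = 1L)
    loci
  }
  expect_equal(effect_concordance(mk(c(2, 3), c(1, -1)))$pct_concordant, 50)
  expect_equal(effect_concordance(mk(c(2, -3), c(1, -1)))$pct_concordant,
               100)
  cc <- effect_concordance(mk(c(2, 0, NA), c(1, 1, 1)))
  expect_equal(cc$n_evaluable, 1)
  expect_equal(cc$n_na, 2)
  expect_equal(cc$pct_concordant, 100)
})

test_that("candidate majority vote can differ from the lead sign", {
  ids <- paste0("s", 1:3)
  sc <- scored_table(ids, 1, c(100, 200, 300), c(0.01, 0.02, 0.03),
                     z_a = c(3, 2.5, 2.4), z_b = c(-1, 2, 2))
  loci <- data.table::data.table(
    chrom = "1", start = 100, end = 300, lead_snp = "s1",
    lead_conjfdr = 0.01, z_a = 3, z_b = -1, concordant = FALSE,
    n_ind_sig = 1L, n_cand = 3L, ind_sig_snps = list("s1"),
    cand_snps = list(ids))
  lead <- effect_concordance(loci)
  vote <- effect_concordance(loci, method = "candidates", scored = sc)
  expect_equal(lead$pct_concordant, 0)
  expect_equal(vote$pct_concordant, 100)   # 2 of 3 candidates agree
  expect_error(effect_concordance(loci, method = "candidates"), "scored")
})
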