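write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t")
  path
}

test_that("a well-formed file reads back unchanged", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = c(1, 1, 2),
                   BP = c(100, 200, 300), A1 = c("A", "C", "G"),
                   A2 = c("G", "T", "A"), Z = c(1.5, -0.3, 2.2),
                   N = 50000, P = 2 * pnorm(-abs(c(1.5, -0.3, 2.2))))
  s <- read_sumstats(write_tsv(df))
  expect_equal(nrow(s), 3)
  expect_equal(s$snp_id, df$SNP)
  expect_equal(s$z, df$Z)
  expect_equal(s$p, df$P)
  expect_true(all(abs(s$p - 2 * pnorm(-abs(s$z))) <= 1e-4))
})

test_that("z is derived from beta/se and p from z when absent", {
  df <- data.frame(SNP = c("rs1", "rs2"), CHR = 1, BP = c(1, 2),
                   A1 = "A", A2 = "G", BETA = c(0.1, -0.2),
                   SE = c(0.05, 0.1), N = 1000)
  s <- read_sumstats(write_tsv(df))
  expect_equal(s$z, c(2, -2))
  expect_equal(s$p, rep(2 * pnorm(-2), 2))
})

test_that("p = 0 is clamped to the floor with a warning", {
  df <- data.frame(SNP = c("rs1", "rs2"), CHR = 1, BP = c(1, 2),
                   A1 = "A", A2 = "G", Z = c(1, 40), N = 1000,
                   P = c(0.5, 0))
  expect_warning(s <- read_sumstats(write_tsv(df)), "clamped")
  expect_equal(s$p[2], 1e-300)
  expect_lte(abs(s$z[2]), qnorm(1e-300 / 2, lower.tail = FALSE))
})

test_that("missing required columns raise a named error", {
  df <- data.frame(SNP = "rs1", CHR = 1, BP = 1, A2 = "G", Z = 1,
                   N = 10, P = 0.3)
  expect_error(read_sumstats(write_tsv(df)), "missing column A1")
})

test_that("rows failing validation are dropped, none surviving errors", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = 1, BP = c(1, -5, 2),
                   A1 = c("A", "A", "X"), A2 = "G", Z = 1, N = 10, P = 0.3)
  expect_message(s <- read_sumstats(write_tsv(df)), "2 row")
  expect_equal(s$snp_id, "rs1")
  bad <- data.frame(SNP = "rs1", CHR = 1, BP = 1, A1 = "A", A2 = "A",
                    Z = 1, N = 10, P = 0.3)
  expect_error(read_sumstats(write_tsv(bad)), "no rows survived")
})

make_ss <- function(snp_id, a1, a2, z, chrom = "1",
                    pos = seq_along(snp_id)) {
  sumstats(snp_id, chrom, pos, a1, a2, z, n = 1e4)
}

test_that("allele harmonization keeps, flips, complements and drops", {
  a <- make_ss(c("s1", "s2", "s3", "s4", "s5"),
               c("A", "A", "A", "A", "A"),
               c("G", "G", "G", "T", "G"), z = c(1, 1, 1, 1, 1))
  b <- make_ss(c("s1", "s2", "s3", "s4", "s5"),
               c("A", "G", "T", "A", "C"),
               c("G", "A", "C", "T", "A"), z = c(1.7, 1.7, 1.7, 1.7, 1.7))
  h <- suppressWarnings(harmonize_pair(a, b))
  # s1 same alleles, s2 swapped, s3 strand complement, s4 ambiguous A/T
  # dropped, s5 irreconcilable (C/A vs A/G) dropped
  expect_equal(h$snp_id, c("s1", "s2", "s3"))
  expect_equal(h$z_b, c(1.7, -1.7, 1.7))
  cnt <- attr(h, "drop_counts")
  expect_equal(unname(cnt["dropped_ambiguous"]), 1)
  expect_equal(unname(cnt["dropped_mismatch"]), 1)
  expect_equal(unname(cnt["kept"]), 3)
})

test_that("harmonization is idempotent and round-trips allele swaps", {
  set.seed(1)
  a <- make_ss(paste0("s", 1:50), "A", "G", rnorm(50))
  b <- make_ss(paste0("s", 1:50), "A", "G", rnorm(50))
  h1 <- suppressWarnings(harmonize_pair(a, b))
  ss <- pair_to_sumstats(h1)
  h2 <- suppressWarnings(harmonize_pair(ss$a, ss$b))
  expect_equal(as.data.frame(h1), as.data.frame(h2))
  # swap b's alleles and negate its z: harmonization must undo it exactly
  b_swapped <- data.table::copy(ss$b)
  b_swapped[, c("a1", "a2", "z") := .(a2, a1, -z)]
  h3 <- suppressWarnings(harmonize_pair(ss$a, b_swapped))
  expect_equal(h3$z_b, h1$z_b)
})

test_that("region exclusion is inclusive at both interval ends", {
  s <- make_ss(paste0("s", 1:4), "A", "G", z = rep(1, 4), chrom = "6",
               pos = c(25999999, 26000000, 34000000, 34000001))
  out <- exclude_regions(s, default_exclusion_mask())
  expect_equal(out$snp_id, c("s1", "s4"))
  expect_equal(nrow(exclude_regions(s, NULL)), 4)
  empty_mask <- data.table::data.table(chrom = character(0),
                                       start = numeric(0), end = numeric(0))
  expect_equal(nrow(exclude_regions(s, empty_mask)), 4)
})

test_that("BED masks convert from 0-based half-open coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr6\t26000000\t34000000", bed)
  mask <- read_region_mask(bed)
  expect_equal(mask$start, 26000001)
  expect_equal(mask$end, 34000000)
})

test_that("harmonized pairs survive a TSV write/read round trip", {
  set.seed(2)
  a <- make_ss(paste0("s", 1:20), "A", "G", rnorm(20))
  path <- tempfile(fileext = ".tsv")
  write_sumstats(a, path)
  s2 <- read_sumstats(path)
  expect_equal(as.data.frame(s2), as.data.frame(a))
})
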