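#' Block-diagonal LD structure
#'
#' Linkage disequilibrium between SNPs is represented as an ordered list of
#' disjoint blocks; within a block every pair of SNPs has an allelic
#' correlation `r`, between blocks `r = 0`. Each block carries its member
#' `snp_id`s and the block correlation matrix.
#'
#' @param blocks list of blocks; each a list with `snp_id` (character) and
#'   `R` (symmetric correlation matrix with unit diagonal).
#' @return An `ld_structure` object.
#' @export
ld_structure <- function(blocks) {
  for (b in blocks) {
    R <- b$R
    k <- length(b$snp_id)
    stopifnot(is.matrix(R), nrow(R) == k, ncol(R) == k)
    if (k == 1) {
      if (abs(R[1, 1] - 1) > 1e-8) stop("block diagonal must be 1")
      next
    }
    if (max(abs(R - t(R))) > 1e-8) stop("block correlation matrix not symmetric")
    if (max(abs(diag(R) - 1)) > 1e-8) stop("block diagonal must be 1")
    if (any(abs(R) > 1 + 1e-8)) stop("correlations outside [-1, 1]")
    off <- R[upper.tri(R)]
    # exchangeable blocks admit a closed-form smallest eigenvalue
    if (max(off) - min(off) < 1e-12) {
      if (1 - off[1] < -1e-8 || 1 + (k - 1) * off[1] < -1e-8)
        stop("block correlation matrix not positive semidefinite")
    } else {
      ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-8) stop("block correlation matrix not positive semidefinite")
    }
  }
  ids <- unlist(lapply(blocks, `[[`, "snp_id"))
  if (anyDuplicated(ids)) stop("blocks must be disjoint")
  structure(list(blocks = blocks), class = "ld_structure")
}

#' @export
print.ld_structure <- function(x, ...) {
  k <- vapply(x$blocks, function(b) length(b$snp_id), integer(1))
  cat("ld_structure:", length(x$blocks), "blocks,", sum(k), "SNPs,",
      "block sizes", min(k), "-", max(k), "\n")
  invisible(x)
}

# SNP id -> c(block index, position within block); NA rows for unknown SNPs.
ld_index <- function(ld) {
  ids <- unlist(lapply(ld$blocks, `[[`, "snp_id"))
  blk <- rep(seq_along(ld$blocks),
             vapply(ld$blocks, function(b) length(b$snp_id), integer(1)))
  within <- unlist(lapply(ld$blocks,
                          function(b) seq_along(b$snp_id)))
  data.table::data.table(snp_id = ids, block = blk, slot = within,
                         key = "snp_id")
}

#' Per-SNP LD scores
#'
#' The LD score of SNP j is the sum of squared allelic correlations with all
#' SNPs in its block, including itself: `l_j = sum_k r_jk^2 >= 1`. SNPs in no
#' block have score 1.
#'
#' @param ld an `ld_structure`.
#' @return data.table `snp_id, ld_score`.
#' @export
ld_scores <- function(ld) {
  data.table::data.table(
    snp_id = unlist(lapply(ld$blocks, `[[`, "snp_id"), use.names = FALSE),
    ld_score = unlist(lapply(ld$blocks, function(b) rowSums(b$R^2)),
                      use.names = FALSE))
}

#' Squared correlation between two SNPs under an LD structure
#'
#' Cross-block pairs have `r^2 = 0`.
#'
#' @param ld an `ld_structure`.
#' @param id1,id2 SNP id vectors (recycled).
#' @return Numeric vector of r-squared values.
#' @export
ld_r2 <- function(ld, id1, id2) {
  n <- max(length(id1), length(id2))
  id1 <- rep_len(id1, n)
  id2 <- rep_len(id2, n)
  idx <- ld_index(ld)
  i1 <- idx[data.table::data.table(snp_id = id1), on = "snp_id"]
  i2 <- idx[data.table::data.table(snp_id = id2), on = "snp_id"]
  r2 <- numeric(n)
  same <- !is.na(i1$block) & !is.na(i2$block) & i1$block == i2$block
  for (j in which(same)) {
    r2[j] <- ld$blocks[[i1$block[j]]]$R[i1$slot[j], i2$slot[j]]^2
  }
  r2
}

# Build a reusable greedy random pruner over a fixed SNP set. The returned
# function performs one pruning pass using the current RNG stream: visit the
# SNPs of each block in a fresh random order, keep a SNP iff its r^2 with
# every previously kept SNP of the block is < r2_max. SNPs outside every
# block, or alone in theirs, are always kept. Blocks where all pairwise r^2
# fall on one side of the threshold take O(1) fast paths.
make_pruner <- function(ld, snp_ids, r2_max) {
  idx <- ld_index(ld)
  present <- unique(snp_ids)
  hit <- idx[data.table::data.table(snp_id = present), on = "snp_id",
             nomatch = 0]
  data.table::setorder(hit, block, slot)   # invariant to input row order
  always <- setdiff(present, hit$snp_id)
  nb <- hit[, .N, by = block]
  always <- c(always, hit[hit$block %in% nb[N == 1]$block]$snp_id)
  multi_blocks <- nb[N > 1]$block
  groups <- lapply(multi_blocks, function(bi) {
    b <- ld$blocks[[bi]]
    slots <- hit[block == bi]$slot
    R2 <- b$R[slots, slots, drop = FALSE]^2
    off <- R2[upper.tri(R2)]
    mode <- if (all(off < r2_max)) "keep_all"
            else if (all(off >= r2_max)) "keep_one"
            else "greedy"
    list(ids = b$snp_id[slots], R2 = R2, mode = mode)
  })
  function() {
    kept <- lapply(groups, function(g) {
      k <- length(g$ids)
      switch(g$mode,
        keep_all = g$ids,
        keep_one = g$ids[sample.int(k, 1)],
        greedy = {
          ord <- sample.int(k)
          kept_slots <- integer(0)
          for (i in ord) {
            if (length(kept_slots) == 0 ||
                all(g$R2[i, kept_slots] < r2_max))
              kept_slots <- c(kept_slots, i)
          }
          g$ids[kept_slots]
        })
    })
    c(always, unlist(kept, use.names = FALSE))
  }
}

# One-shot greedy random pruning (see make_pruner).
prune_random <- function(ld, snp_ids, r2_max) {
  make_pruner(ld, snp_ids, r2_max)()
}

# Block-diagonal matrix-vector product R %*% v, with v in the LD object's
# SNP order. Identity-LD structures short-circuit.
ld_mult <- function(ld, v) {
  sizes <- vapply(ld$blocks, function(b) length(b$snp_id), integer(1))
  if (all(sizes == 1L)) return(v)
  out <- numeric(length(v))
  offset <- 0L
  for (b in ld$blocks) {
    k <- length(b$snp_id)
    idx <- offset + seq_len(k)
    out[idx] <- as.numeric(b$R %*% v[idx])
    offset <- offset + k
  }
  out
}

#' Write an LD structure as a triplet TSV
#'
#' One row per within-block pair (i <= j): `snp_i, snp_j, r`.
#'
#' @param ld an `ld_structure`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ld_triplets <- function(ld, path) {
  trip <- data.table::rbindlist(lapply(ld$blocks, function(b) {
    k <- length(b$snp_id)
    ij <- which(upper.tri(b$R, diag = TRUE), arr.ind = TRUE)
    data.table::data.table(snp_i = b$snp_id[ij[, 1]],
                           snp_j = b$snp_id[ij[, 2]],
                           r = b$R[ij])
  }))
  data.table::fwrite(trip, path, sep = "\t")
  invisible(path)
}

#' Read an LD structure from a triplet TSV
#'
#' Inverse of [write_ld_triplets()]. Connected components of the triplet
#' graph become blocks; missing pairs within a block default to r = 0.
#'
#' @param path TSV with columns `snp_i, snp_j, r`.
#' @return An `ld_structure`.
#' @export
read_ld_triplets <- function(path) {
  trip <- data.table::fread(path)
  ids <- unique(c(trip$snp_i, trip$snp_j))
  comp <- seq_along(ids)
  names(comp) <- ids
  # union-find over pairs
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (k in seq_len(nrow(trip))) {
    i <- find(match(trip$snp_i[k], ids))
    j <- find(match(trip$snp_j[k], ids))
    if (i != j) comp[max(i, j)] <- min(i, j)
  }
  roots <- vapply(seq_along(ids), find, integer(1))
  blocks <- lapply(split(seq_along(ids), roots), function(members) {
    bid <- ids[members]
    R <- diag(length(bid))
    sub <- trip[trip$snp_i %in% bid & trip$snp_j %in% bid]
    i <- match(sub$snp_i, bid); j <- match(sub$snp_j, bid)
    R[cbind(i, j)] <- sub$r
    R[cbind(j, i)] <- sub$r
    diag(R) <- 1
    list(snp_id = bid, R = R)
  })
  ld_structure(unname(blocks))
}
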