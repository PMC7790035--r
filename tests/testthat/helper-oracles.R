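# Independent oracle implementations and small fixture builders shared
# across test files. Oracles deliberately use plain-R brute force, not the
# package's code paths.

# Direct high-precision evaluation of the bivariate mixture NLL.
bf_mixture_nll <- function(z_a, z_b, w, sa, sb, cab) {
  total <- 0
  for (j in seq_along(z_a)) {
    dens <- 0
    for (k in seq_along(w)) {
      det <- sa[k] * sb[k] - cab[k]^2
      q <- (sb[k] * z_a[j]^2 - 2 * cab[k] * z_a[j] * z_b[j] +
              sa[k] * z_b[j]^2) / det
      dens <- dens + w[k] * exp(-q / 2) / (2 * pi * sqrt(det))
    }
    total <- total - log(dens)
  }
  total
}

# Verify that a pruned SNP set contains no pair violating the r2 threshold.
bf_prune_valid <- function(ld, kept, r2_max) {
  for (b in ld$blocks) {
    slots <- which(b$snp_id %in% kept)
    if (length(slots) < 2) next
    R2 <- b$R[slots, slots]^2
    if (any(R2[upper.tri(R2)] >= r2_max)) return(FALSE)
  }
  TRUE
}

# Pairwise r2 matrix for a small SNP set under a block LD structure.
bf_r2_matrix <- function(ld, ids) {
  n <- length(ids)
  R2 <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(R2) <- 1
  for (b in ld$blocks) {
    hit <- intersect(ids, b$snp_id)
    if (length(hit) < 2) next
    s <- match(hit, b$snp_id)
    R2[hit, hit] <- b$R[s, s]^2
  }
  R2
}

# Brute-force FUMA-style locus definition on a small scored table. Follows
# the published rules step by step with plain loops; independent of
# define_loci's implementation.
bf_define_loci <- function(scored, ld, sig_thresh = 0.05,
                           cand_thresh = 0.10, r2_indep = 0.6,
                           r2_lead = 0.1, merge_kb = 250) {
  sc <- as.data.frame(scored)
  R2 <- bf_r2_matrix(ld, sc$snp_id)
  ord <- order(sc$conjfdr, sc$chrom, sc$pos)
  sig <- ord[sc$conjfdr[ord] < sig_thresh]
  ind_sig <- c()
  for (i in sig) {
    if (all(R2[sc$snp_id[i], sc$snp_id[ind_sig]] < r2_indep))
      ind_sig <- c(ind_sig, i)
  }
  if (length(ind_sig) == 0) return(NULL)
  # candidate sets per independent significant SNP
  cand_rows <- which(sc$conjfdr < cand_thresh)
  env <- lapply(ind_sig, function(i) {
    cands <- sc$snp_id[i]
    for (j in cand_rows) {
      if (R2[sc$snp_id[j], sc$snp_id[i]] >= r2_indep)
        cands <- union(cands, sc$snp_id[j])
    }
    pos <- sc$pos[match(cands, sc$snp_id)]
    list(chrom = sc$chrom[i], start = min(pos), end = max(pos),
         ind = sc$snp_id[i], cands = cands)
  })
  # merge envelopes within merge_kb, exhaustively (fixed point)
  merged <- lapply(env, function(e) e)
  repeat {
    done <- TRUE
    for (i in seq_along(merged)) {
      if (is.null(merged[[i]])) next
      for (j in seq_along(merged)) {
        if (i == j || is.null(merged[[j]])) next
        a <- merged[[i]]; b <- merged[[j]]
        if (a$chrom == b$chrom &&
            max(a$start, b$start) - min(a$end, b$end) <= merge_kb * 1000) {
          merged[[i]] <- list(chrom = a$chrom,
                              start = min(a$start, b$start),
                              end = max(a$end, b$end),
                              ind = c(a$ind, b$ind),
                              cands = union(a$cands, b$cands))
          merged[[j]] <- NULL
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) break
  }
  merged <- Filter(Negate(is.null), merged)
  out <- lapply(merged, function(e) {
    rows <- match(e$ind, sc$snp_id)
    lead <- rows[order(sc$conjfdr[rows], sc$chrom[rows], sc$pos[rows])][1]
    cpos <- sc$pos[match(e$cands, sc$snp_id)]
    list(chrom = e$chrom, start = min(cpos), end = max(cpos),
         lead_snp = sc$snp_id[lead],
         ind_sig = sort(e$ind), cands = sort(e$cands))
  })
  out[order(vapply(out, `[[`, character(1), "chrom"),
            vapply(out, `[[`, numeric(1), "start"))]
}

# Construct a harmonized pair directly from vectors (for unit tests).
make_pair <- function(snp_id, chrom, pos, z_a, z_b, p_a = NULL, p_b = NULL,
                      n_a = 1e5, n_b = 1e5) {
  dt <- data.table::data.table(
    snp_id = snp_id, chrom = as.character(chrom), pos = pos,
    a1 = "A", a2 = "G", z_a = z_a, z_b = z_b, n_a = n_a, n_b = n_b,
    p_a = if (is.null(p_a)) 2 * pnorm(-abs(z_a)) else p_a,
    p_b = if (is.null(p_b)) 2 * pnorm(-abs(z_b)) else p_b)
  data.table::setattr(dt, "class",
                      unique(c("harmonized_pair", class(dt))))
  dt[]
}

# Identity LD over a set of SNP ids (1-SNP blocks).
identity_ld <- function(snp_ids) {
  ld_structure(lapply(snp_ids, function(id)
    list(snp_id = id, R = matrix(1, 1, 1))))
}

# Exchangeable-correlation block LD over consecutive groups of ids.
grouped_ld <- function(snp_ids, block_size, rho) {
  blocks <- split(snp_ids, ceiling(seq_along(snp_ids) / block_size))
  ld_structure(unname(lapply(blocks, function(ids) {
    R <- matrix(rho, length(ids), length(ids)); diag(R) <- 1
    list(snp_id = ids, R = R)
  })))
}
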