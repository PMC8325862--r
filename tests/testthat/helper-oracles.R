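# Independent oracles, deliberately written as plain direct-space / brute
# force computations so they share no code path with the package.

# Direct-space genotype scores (probability scale), vectorized over counts.
oracle_genotype_scores <- function(ww_w, ww_c, wc_w, wc_c, b, p) {
  pmf <- function(nc, n, theta) ifelse(n == 0, 1, dbinom(nc, n, theta))
  nw <- ww_w + ww_c; nc <- wc_w + wc_c
  Lww_WW <- pmf(ww_c, nw, b);      Lwc_WW <- pmf(wc_c, nc, b)
  Lww_WC <- pmf(ww_c, nw, 0.5);    Lwc_WC <- pmf(wc_c, nc, 0.5)
  Lww_CC <- pmf(ww_c, nw, 1 - b);  Lwc_CC <- pmf(wc_c, nc, 1 - b)
  ref <- p$p_ref * (0.5 * p$p_none * Lww_WW * Lwc_WC +
                    p$p_awc * Lww_WC * Lwc_WC +
                    0.5 * p$p_del * Lww_WW * (Lwc_WW + Lwc_CC))
  het01 <- (p$p_het / 2) * (p$p_none * Lww_WC * Lwc_WW +
                            p$p_awc * Lww_WC * Lwc_WC +
                            0.5 * p$p_del * (Lww_WW + Lww_CC) * Lwc_WW)
  het10 <- (p$p_het / 2) * (p$p_none * Lww_WC * Lwc_CC +
                            p$p_awc * Lww_WC * Lwc_WC +
                            0.5 * p$p_del * (Lww_WW + Lww_CC) * Lwc_CC)
  hom <- p$p_hom * (0.5 * p$p_none * Lww_CC * Lwc_WC +
                    p$p_awc * Lww_WC * Lwc_WC +
                    0.5 * p$p_del * Lww_CC * (Lwc_WW + Lwc_CC))
  cbind(REF = ref, `HET(0|1)` = het01, `HET(1|0)` = het10, HOM = hom)
}

# Brute-force Mendelian check: enumerate parental gametes.
oracle_concordant <- function(father, mother, child) {
  alleles <- function(g) switch(g, REF = c(0, 0), HET = c(0, 1), HOM = c(1, 1))
  target <- sort(alleles(child))
  for (fa in alleles(father)) {
    for (ma in alleles(mother)) {
      if (identical(sort(c(fa, ma)), target)) return(TRUE)
    }
  }
  FALSE
}

# Brute-force ordered self-intersection count at reciprocal overlap f.
oracle_self_intersections <- function(iv, f = 0.8) {
  n <- nrow(iv)
  count <- 0L
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (iv$chrom[a] != iv$chrom[b]) next
      ov <- min(iv$end[a], iv$end[b]) - max(iv$start[a], iv$start[b])
      la <- iv$end[a] - iv$start[a]
      lb <- iv$end[b] - iv$start[b]
      if (ov >= f * la && ov >= f * lb) count <- count + 1L
    }
  }
  count
}

# Exhaustive phasing oracle: per-library net votes for "allele 1 on Watson"
# per SNV; the best +/-1 assignment maximizes total agreement
# sum_snv | sum_lib o_l * s_l(snv) |. Returns the argmax (and its mirror).
oracle_phase_assignment <- function(lib_scores) {
  libs <- names(lib_scores)
  positions <- unique(unlist(lapply(lib_scores, names)))
  mat <- sapply(lib_scores, function(s) {
    v <- setNames(rep(0, length(positions)), positions)
    v[names(s)] <- s
    v
  })
  best_score <- -Inf
  best <- NULL
  for (mask in 0:(2^length(libs) - 1)) {
    o <- ifelse(bitwAnd(mask, 2^(seq_along(libs) - 1)) > 0, -1, 1)
    score <- sum(abs(mat %*% o))
    if (score > best_score) {
      best_score <- score
      best <- setNames(o, libs)
    }
  }
  best
}

# Net "allele 1 on Watson" votes per SNV for one library's reads.
lib_snv_scores <- function(reads) {
  informative <- reads[!is.na(reads$snv_pos), , drop = FALSE]
  if (nrow(informative) == 0) return(numeric(0))
  w_allele <- ifelse(informative$strand == "-", informative$allele,
                     1L - informative$allele)
  tapply(ifelse(w_allele == 1L, 1, -1), informative$snv_pos, sum)
}
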