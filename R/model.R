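# The Bayesian core.
#
# Within a putative inversion, the Watson/Crick read counts of each composite
# follow a binomial whose Crick-success probability depends on the strand
# state: b for WW, 1-b for CC, 0.5 for WC and CW, where b is the composite
# background. Genotype scores mix these strand-state likelihoods over three
# error states (no error / always-WC / missing-deletion), weighted by the
# genotype and error-state priors:
#
#   S_REF  = P_REF  [ 1/2 P_none L(ww,WW) L(wc,WC) + P_awc L(ww,WC) L(wc,WC)
#                     + 1/2 P_del L(ww,WW) (L(wc,WW) + L(wc,CC)) ]
#   S_H01  = P_HET/2 [ P_none L(ww,WC) L(wc,WW) + P_awc L(ww,WC) L(wc,WC)
#                     + 1/2 P_del (L(ww,WW) + L(ww,CC)) L(wc,WW) ]
#   S_H10  = as S_H01 with L(wc,WW) -> L(wc,CC)
#   S_HOM  = P_HOM  [ 1/2 P_none L(ww,CC) L(wc,WC) + P_awc L(ww,WC) L(wc,WC)
#                     + 1/2 P_del L(ww,CC) (L(wc,WW) + L(wc,CC)) ]
#
# Everything is computed in log space with log-sum-exp over the mixture
# components; posteriors are the softmax of the four scores and a call is
# confident when the maximum posterior reaches the threshold (default 95%).

#' Binomial strand-state log-likelihood
#'
#' Log-probability of observing `n_c` Crick reads among `n_w + n_c` reads in
#' one composite under a given strand state, with Crick-success probability
#' `b` for WW, `1 - b` for CC, and 0.5 for WC/CW. Returns 0 (likelihood 1)
#' for zero reads. WC and CW are numerically identical: counts alone cannot
#' separate them.
#'
#' @param n_w,n_c Watson and Crick read counts (non-negative integers).
#' @param state One of `"WW"`, `"WC"`, `"CW"`, `"CC"`.
#' @param b Background in `[0, 0.5)`.
#' @return Log-likelihood (scalar).
#' @export
strand_state_loglik <- function(n_w, n_c, state, b) {
  if (n_w < 0 || n_c < 0) stop("read counts must be non-negative")
  if (b < 0 || b >= 0.5) stop("background must lie in [0, 0.5)")
  state <- match.arg(state, STRAND_STATES)
  n <- n_w + n_c
  if (n == 0) return(0)
  switch(state,
         WW = dbinom(n_c, n, b, log = TRUE),
         WC = dbinom(pmin(n_w, n_c), n, 0.5, log = TRUE),
         CW = dbinom(pmin(n_w, n_c), n, 0.5, log = TRUE),
         CC = dbinom(n_w, n, b, log = TRUE))
}

# Vectorized state log-likelihood table: rows = observations, columns
# WW / WC / CC (CW == WC). CC is evaluated as Watson successes at rate b
# and WC on the minority count -- mathematically identical to the theta
# convention, but it makes the Watson/Crick swap symmetry exact in
# floating point.
state_loglik_table <- function(n_w, n_c, b) {
  n <- n_w + n_c
  out <- cbind(
    WW = dbinom(n_c, n, b, log = TRUE),
    WC = dbinom(pmin(n_w, n_c), n, 0.5, log = TRUE),
    CC = dbinom(n_w, n, b, log = TRUE)
  )
  out[n == 0, ] <- 0
  out
}

# Vectorized genotype log scores; counts are equal-length vectors.
genotype_logliks_matrix <- function(ww_w, ww_c, wc_w, wc_c, b, priors) {
  stopifnot(inherits(priors, "invr_priors"))
  if (any(c(ww_w, ww_c, wc_w, wc_c) < 0)) stop("read counts must be non-negative")
  if (b < 0 || b >= 0.5) stop("background must lie in [0, 0.5)")
  lww <- state_loglik_table(ww_w, ww_c, b)
  lwc <- state_loglik_table(wc_w, wc_c, b)
  lp <- log(c(none = priors$p_none, awc = priors$p_awc, del = priors$p_del))
  wc_dir <- logsumexp_rows(cbind(lwc[, "WW"], lwc[, "CC"]))
  ww_dir <- logsumexp_rows(cbind(lww[, "WW"], lww[, "CC"]))

  ref <- logsumexp_rows(cbind(
    log(0.5) + lp["none"] + lww[, "WW"] + lwc[, "WC"],
    lp["awc"] + lww[, "WC"] + lwc[, "WC"],
    log(0.5) + lp["del"] + lww[, "WW"] + wc_dir
  )) + log(priors$p_ref)
  het01 <- logsumexp_rows(cbind(
    lp["none"] + lww[, "WC"] + lwc[, "WW"],
    lp["awc"] + lww[, "WC"] + lwc[, "WC"],
    log(0.5) + lp["del"] + ww_dir + lwc[, "WW"]
  )) + log(priors$p_het / 2)
  het10 <- logsumexp_rows(cbind(
    lp["none"] + lww[, "WC"] + lwc[, "CC"],
    lp["awc"] + lww[, "WC"] + lwc[, "WC"],
    log(0.5) + lp["del"] + ww_dir + lwc[, "CC"]
  )) + log(priors$p_het / 2)
  hom <- logsumexp_rows(cbind(
    log(0.5) + lp["none"] + lww[, "CC"] + lwc[, "WC"],
    lp["awc"] + lww[, "WC"] + lwc[, "WC"],
    log(0.5) + lp["del"] + lww[, "CC"] + wc_dir
  )) + log(priors$p_hom)

  out <- cbind(ref, het01, het10, hom)
  colnames(out) <- GENOTYPES
  out
}

#' Genotype log scores for one interval
#'
#' Mixture log score of each genotype given the Watson/Crick counts of the
#' two composites within a putative inversion (see the model sketch in the
#' package help page). The heterozygote prior mass is split equally between
#' the two phases.
#'
#' @param counts_ww,counts_wc Length-2 vectors `c(n_w, n_c)` for the WW-type
#'   and WC-type composite.
#' @param b Background (shared by both composites).
#' @param priors An [priors()] object.
#' @return Named numeric vector of log scores for
#'   `REF, HET(0|1), HET(1|0), HOM`.
#' @export
genotype_logliks <- function(counts_ww, counts_wc, b, priors = default_priors()) {
  stopifnot(length(counts_ww) == 2, length(counts_wc) == 2)
  m <- genotype_logliks_matrix(counts_ww[1], counts_ww[2],
                               counts_wc[1], counts_wc[2], b, priors)
  scores <- m[1, ]
  if (all(!is.finite(scores))) {
    stop("all genotype scores are -Inf; check priors and background")
  }
  scores
}

#' Posterior genotype probabilities and call
#'
#' Softmax of the four genotype log scores; the call is the argmax genotype
#' when its posterior reaches `threshold`, otherwise `AMBIGUOUS`.
#'
#' @param logliks Named vector from [genotype_logliks()].
#' @param threshold Confidence threshold (default 0.95).
#' @return List with `posterior` (named, sums to 1), `call`, `confident`.
#' @export
genotype_posterior <- function(logliks, threshold = 0.95) {
  stopifnot(length(logliks) == 4, any(is.finite(logliks)))
  z <- logsumexp(logliks)
  post <- exp(logliks - z)
  names(post) <- GENOTYPES
  best <- which.max(post)
  confident <- post[best] >= threshold
  list(posterior = post,
       call = if (confident) GENOTYPES[best] else "AMBIGUOUS",
       confident = unname(confident))
}

#' Genotype a set of putative inversion intervals
#'
#' Counts Watson/Crick reads of each composite whose start position falls
#' inside each interval (after MAPQ and blacklist filtering), scores the four
#' genotypes, and reports posteriors and calls. Intervals on chromosomes
#' absent from the composites, or extending beyond them, are skipped with a
#' warning. Intervals larger than the sizes composites render reliably
#' (8 Mb for the HET signature, 4 Mb for HOM) are flagged but still
#' genotyped. On user-declared haploid chromosomes (e.g. male X/Y),
#' confident HET calls are downgraded to AMBIGUOUS with a note.
#'
#' @param intervals Data frame `chrom`, `start`, `end` (0-based half-open).
#' @param ww,wc The two `composite_reads` objects.
#' @param b Background; if `NULL`, estimated from the WW composite with
#'   [estimate_background()].
#' @param priors An [priors()] object.
#' @param min_mapq Minimum read mapping quality.
#' @param blacklist Optional regions whose reads are discarded.
#' @param posterior_threshold Confidence threshold.
#' @param haploid_chroms Character vector of haploid chromosome names.
#' @param provenance Label recorded for every call (e.g. `"user"`,
#'   `"de_novo"`, `"catalogue"`).
#' @return Data frame of calls: coordinates, `genotype`
#'   (REF/HET/HOM/AMBIGUOUS), `phase` (`0|1`, `1|0`, or `.`), `posterior`
#'   (of the called genotype, or the maximum for ambiguous calls), the four
#'   per-genotype posteriors, per-composite counts, `size_flag`, `note`,
#'   `provenance`.
#' @export
genotype_intervals <- function(intervals, ww, wc, b = NULL,
                               priors = default_priors(), min_mapq = 10,
                               blacklist = NULL, posterior_threshold = 0.95,
                               haploid_chroms = character(0),
                               provenance = "user") {
  stopifnot(inherits(ww, "composite_reads"), inherits(wc, "composite_reads"))
  if (is.null(b)) b <- estimate_background(ww, blacklist = blacklist,
                                           min_mapq = min_mapq)$b
  if (inherits(b, "background_estimate")) b <- b$b
  lens <- ww$chrom_lengths
  ok <- intervals$chrom %in% names(lens) &
    intervals$start >= 0 & intervals$end > intervals$start &
    intervals$end <= unname(lens[intervals$chrom])
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    warning(sum(!ok), " interval(s) fall off the genome and were skipped")
    intervals <- intervals[ok, , drop = FALSE]
  }
  n <- nrow(intervals)
  if (n == 0) {
    stop("no genotypable intervals")
  }

  count_comp <- function(comp) {
    reads <- comp$reads[comp$reads$mapq >= min_mapq, , drop = FALSE]
    if (!is.null(blacklist) && nrow(blacklist) > 0) {
      reads <- reads[!points_in_intervals(reads, blacklist), , drop = FALSE]
    }
    hits <- GenomicRanges::findOverlaps(read_points_gr(reads),
                                        intervals_to_gr(intervals))
    w_count <- rep(0L, n); c_count <- rep(0L, n)
    if (length(hits) > 0) {
      watson <- is_watson(reads$strand[S4Vectors::queryHits(hits)])
      iv <- S4Vectors::subjectHits(hits)
      tw <- rowsum(cbind(w = as.integer(watson), c = as.integer(!watson)), iv)
      idx <- as.integer(rownames(tw))
      w_count[idx] <- tw[, "w"]; c_count[idx] <- tw[, "c"]
    }
    list(w = w_count, c = c_count)
  }
  cww <- count_comp(ww)
  cwc <- count_comp(wc)

  scores <- genotype_logliks_matrix(cww$w, cww$c, cwc$w, cwc$c, b, priors)
  z <- logsumexp_rows(scores)
  post <- exp(scores - z)
  best <- max.col(post, ties.method = "first")
  best_post <- post[cbind(seq_len(n), best)]
  confident <- best_post >= posterior_threshold
  raw_geno <- GENOTYPES[best]

  genotype <- ifelse(confident,
                     c("REF", "HET", "HET", "HOM")[best], "AMBIGUOUS")
  phase <- ifelse(confident & raw_geno == "HET(0|1)", "0|1",
           ifelse(confident & raw_geno == "HET(1|0)", "1|0", "."))
  note <- rep("", n)

  haploid_het <- intervals$chrom %in% haploid_chroms & genotype == "HET"
  if (any(haploid_het)) {
    genotype[haploid_het] <- "AMBIGUOUS"
    phase[haploid_het] <- "."
    note[haploid_het] <- "confident_HET_on_haploid_chrom"
  }
  size <- intervals$end - intervals$start
  size_flag <- size > 8e6 | (size > 4e6 & genotype == "HOM")
  if (any(size_flag)) {
    warning(sum(size_flag), " interval(s) exceed the size composites render",
            " reliably (8 Mb HET / 4 Mb HOM signatures); calls are flagged")
  }

  data.frame(
    chrom = intervals$chrom, start = intervals$start, end = intervals$end,
    genotype = genotype, posterior = best_post, phase = phase,
    p_ref = post[, 1], p_het01 = post[, 2], p_het10 = post[, 3], p_hom = post[, 4],
    ww_w = cww$w, ww_c = cww$c, wc_w = cwc$w, wc_c = cwc$c,
    size_flag = size_flag, note = note, provenance = provenance,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
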