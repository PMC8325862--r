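# Prior construction.
#
# Genotype priors can come from published per-individual genotype
# frequencies, or from the self-overlap structure of an inversion catalogue:
# with l catalogue intervals, i ordered self-intersections at 80% reciprocal
# overlap, and n expected true inversions, the expected frequency of a
# biological inversion at a random catalogue interval is n*i/(2*l^2) per
# heterozygous/homozygous class, l^2/i being an estimate of the number of
# unique intervals once overlapping duplicates are clustered.

#' Construct a prior set
#'
#' @param p_ref,p_het,p_hom Genotype priors; must sum to 1. `p_het` is the
#'   total heterozygote mass; at genotyping time each phase (0|1, 1|0)
#'   receives `p_het / 2`.
#' @param p_none,p_awc,p_del Error-state priors: no error, always-WC
#'   (reference-assembly collapse), missing/deletion. Must sum to 1.
#'   Defaults are the conservative 0.5 / 0.25 / 0.25.
#' @param provenance One of `"user"`, `"frequency"`, `"catalogue"`,
#'   `"de_novo"`.
#' @param n,i,l For catalogue priors: expected inversions, self-intersection
#'   count, catalogue size.
#' @return Object of class `invr_priors`.
#' @export
priors <- function(p_ref = 0.9, p_het = 0.05, p_hom = 0.05,
                   p_none = 0.5, p_awc = 0.25, p_del = 0.25,
                   provenance = "user", n = NA_real_, i = NA_real_, l = NA_real_) {
  g <- c(p_ref, p_het, p_hom)
  e <- c(p_none, p_awc, p_del)
  if (any(g < 0) || any(g > 1) || abs(sum(g) - 1) > 1e-9) {
    stop("genotype priors must lie in [0,1] and sum to 1 (got sum = ", sum(g), ")")
  }
  if (any(e < 0) || any(e > 1) || abs(sum(e) - 1) > 1e-9) {
    stop("error-state priors must lie in [0,1] and sum to 1")
  }
  structure(list(p_ref = p_ref, p_het = p_het, p_hom = p_hom,
                 p_none = p_none, p_awc = p_awc, p_del = p_del,
                 provenance = provenance, n = n, i = i, l = l),
            class = "invr_priors")
}

#' @rdname priors
#' @export
default_priors <- function() priors()

#' @export
print.invr_priors <- function(x, ...) {
  cat(sprintf("priors (%s): REF %.4f | HET %.4f | HOM %.4f; error states %.2f/%.2f/%.2f\n",
              x$provenance, x$p_ref, x$p_het, x$p_hom, x$p_none, x$p_awc, x$p_del))
  invisible(x)
}

#' Genotype priors from reported genotype frequencies
#'
#' Each genotype's prior is its reported count divided by the number of
#' non-ambiguous calls for that individual: `P_g = n_g / (total -
#' n_ambiguous)`. The heterozygote mass is split equally between the two
#' phases at genotyping time.
#'
#' @param n_ref,n_het,n_hom,n_ambiguous Reported per-genotype call counts.
#' @param total Total calls; must equal the sum of the four counts.
#' @param ... Error-state priors passed to [priors()].
#' @return An `invr_priors` object with provenance `"frequency"`.
#' @export
priors_from_genotype_counts <- function(n_ref, n_het, n_hom, n_ambiguous = 0,
                                        total = n_ref + n_het + n_hom + n_ambiguous,
                                        ...) {
  if (n_ref + n_het + n_hom + n_ambiguous != total) {
    stop("genotype counts must sum to 'total'")
  }
  denom <- total - n_ambiguous
  if (denom <= 0) stop("all calls are ambiguous; no frequencies to use")
  priors(p_ref = n_ref / denom, p_het = n_het / denom, p_hom = n_hom / denom,
         provenance = "frequency", ...)
}

#' Ordered self-intersections of an interval set
#'
#' Counts ordered pairs `(a, b)` -- including `a = b` -- whose overlap covers
#' at least `reciprocal_fraction` of both intervals, matching the hit count
#' of `bedtools intersect -f 0.8 -r -a x -b x`. Self-hits are included, so
#' the count is at least the number of intervals.
#'
#' @param intervals Data frame `chrom`, `start`, `end` (0-based half-open).
#' @param reciprocal_fraction Required reciprocal overlap fraction.
#' @return Integer count `i`.
#' @export
self_intersections <- function(intervals, reciprocal_fraction = 0.8) {
  if (nrow(intervals) == 0) return(0L)
  gr <- intervals_to_gr(intervals)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gr[q], gr[s]))
  len <- intervals$end - intervals$start
  sum(ov >= reciprocal_fraction * len[q] & ov >= reciprocal_fraction * len[s])
}

#' Estimate the number of unique intervals in a catalogue
#'
#' Returns `l^2 / i`, where `l` is the catalogue size and `i` its ordered
#' self-intersection count at the given reciprocal-overlap threshold. Equals
#' `l` when no two intervals overlap; collapses duplicated intervals toward
#' a single cluster.
#'
#' @inheritParams self_intersections
#' @return A real number `<= l`.
#' @export
unique_interval_estimate <- function(intervals, reciprocal_fraction = 0.8) {
  l <- nrow(intervals)
  if (l < 1) stop("need at least one interval")
  i <- self_intersections(intervals, reciprocal_fraction)
  l^2 / i
}

#' Genotype priors from an inversion catalogue
#'
#' `P_HET = P_HOM = n * i / (2 * l^2)` and `P_REF = 1 - P_HET - P_HOM`,
#' where `n` is the number of inversions expected to be real, and `i`, `l`
#' describe the catalogue ([self_intersections()]). Use `n = 100` for a
#' published catalogue and `n = 80` for de novo strand-switch intervals
#' (smaller inversions are expected to be missed there).
#'
#' @param n Expected number of true inversions among the intervals.
#' @param intervals Catalogue intervals (`chrom`, `start`, `end`).
#' @param reciprocal_fraction Reciprocal-overlap threshold for `i`.
#' @param provenance `"catalogue"` or `"de_novo"`.
#' @param ... Error-state priors passed to [priors()].
#' @return An `invr_priors` object carrying `n`, `i`, `l`.
#' @export
priors_from_catalogue <- function(n = 100, intervals, reciprocal_fraction = 0.8,
                                  provenance = "catalogue", ...) {
  stopifnot(n >= 0)
  l <- nrow(intervals)
  if (l < 1) stop("catalogue must contain at least one interval")
  i <- self_intersections(intervals, reciprocal_fraction)
  p_het <- n * i / (2 * l^2)
  p_hom <- p_het
  if (p_het + p_hom >= 1) {
    stop("degenerate catalogue: P_HET + P_HOM = ", p_het + p_hom,
         " >= 1; reduce n or supply a larger catalogue")
  }
  priors(p_ref = 1 - p_het - p_hom, p_het = p_het, p_hom = p_hom,
         provenance = provenance, n = n, i = i, l = l, ...)
}
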