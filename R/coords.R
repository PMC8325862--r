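# Putative-interval supply and refinement.
#
# A simplified read-windowed segmentation supplies de novo candidate
# intervals: sliding windows of a fixed number of reads are classified by
# Watson fraction, runs that differ from the chromosome's modal state are
# emitted, and boundaries are refined with deltaW -- the absolute difference
# in Watson-read counts between adjacent read windows, summed over a set of
# window sizes, which peaks at strand-state switch points. The same deltaW
# profile drives breakpoint adjustment of user-supplied calls, with
# re-genotyping and a retention rule.

# Summed deltaW profile at each read (positions sorted). For window size w,
# deltaW at read k is |#W in reads (k-w..k-1]| - |#W in [k..k+w-1]|, defined
# where both windows fit; profiles are summed across window sizes.
delta_w_profile <- function(watson, window_sizes = c(40, 120, 360)) {
  n <- length(watson)
  prof <- numeric(n)
  cw <- cumsum(as.numeric(watson))
  for (w in window_sizes) {
    if (n < 2 * w) next
    k <- (w + 1):(n - w + 1)
    left <- cw[k - 1] - c(0, cw)[k - w]
    right <- cw[k + w - 1] - cw[k - 1]
    prof[k] <- prof[k] + abs(right - left)
  }
  prof
}

smooth3 <- function(x) {
  if (length(x) < 3) return(x)
  s <- stats::filter(x, rep(1 / 3, 3), sides = 2)
  s[1] <- x[1]; s[length(x)] <- x[length(x)]
  as.numeric(s)
}

window_state <- function(wfrac, w_threshold = 0.8, c_threshold = 0.2) {
  ifelse(wfrac >= w_threshold, "WW", ifelse(wfrac <= c_threshold, "CC", "WC"))
}

#' Detect de novo strand switches in a composite
#'
#' For each parameterization (a window size in reads and a minimum read
#' support), non-overlapping windows of `windowsize` consecutive reads are
#' classified by Watson fraction (WW at or above 0.8, CC at or below 0.2,
#' else WC), maximal runs whose state differs from the chromosome's modal
#' state and that contain at least `minreads` reads are emitted, and their
#' boundaries are placed at the flanking deltaW maxima. Intervals from all
#' parameterizations are unioned. Chromosomes with fewer than `windowsize`
#' reads are skipped with a warning.
#'
#' The default parameterizations (window sizes 40/120/360 reads with minimum
#' support 15/50/50) target inversions of increasing size.
#'
#' @param composite A `composite_reads` object.
#' @param windowsize,minreads Equal-length vectors of paired parameters.
#' @param w_threshold,c_threshold Watson-fraction cutoffs.
#' @return Data frame `chrom`, `start`, `end`, `state` (observed state of
#'   the interval in this composite), `n_reads`, `w_fraction`.
#' @export
detect_strand_switches <- function(composite,
                                   windowsize = c(40, 120, 360),
                                   minreads = c(15, 50, 50),
                                   w_threshold = 0.8, c_threshold = 0.2) {
  stopifnot(inherits(composite, "composite_reads"),
            length(windowsize) == length(minreads))
  reads <- composite$reads
  if (nrow(reads) == 0) stop("empty composite")
  pieces <- list()
  for (ch in unique(reads$chrom)) {
    r <- reads[reads$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    watson <- is_watson(r$strand)
    n <- nrow(r)
    dw <- smooth3(delta_w_profile(watson))
    for (p in seq_along(windowsize)) {
      w <- windowsize[p]; m <- minreads[p]
      if (n < w) {
        warning("chromosome ", ch, " has fewer than ", w, " reads; skipped")
        next
      }
      nw <- floor(n / w)
      win <- rep(seq_len(nw), each = w)[seq_len(nw * w)]
      wf <- as.vector(tapply(watson[seq_len(nw * w)], win, mean))
      st <- window_state(wf, w_threshold, c_threshold)
      base <- names(which.max(table(st)))
      r_len <- rle(st != base)
      hi <- cumsum(r_len$lengths); lo <- hi - r_len$lengths + 1
      for (j in which(r_len$values)) {
        i0 <- (lo[j] - 1) * w + 1   # first read of the run
        i1 <- hi[j] * w             # last read of the run
        # Refine each boundary to the deltaW maximum within one window.
        sl <- max(1, i0 - w):min(n, i0 + w - 1)
        sr <- max(1, i1 - w + 1):min(n, i1 + w)
        b0 <- sl[which.max(dw[sl])]
        sr <- sr[sr > b0]  # the end boundary must lie right of the start
        b1 <- if (length(sr) > 0) sr[which.max(dw[sr])] else NA
        if (is.na(b1)) { b0 <- i0; b1 <- i1 }
        # Support = reads inconsistent with the chromosome base state
        # (deltaW cannot localize events narrower than the window, so the
        # interval read count alone would overstate the evidence).
        seg_w <- sum(watson[b0:b1])
        seg_c <- (b1 - b0 + 1) - seg_w
        support <- switch(base, WW = seg_c, CC = seg_w, abs(seg_w - seg_c))
        if (support < m) next
        pieces[[length(pieces) + 1]] <- data.frame(
          chrom = ch, start = r$start[b0], end = r$start[b1] + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(pieces) == 0) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      state = character(0), n_reads = integer(0),
                      w_fraction = numeric(0)))
  }
  cand <- do.call(rbind, pieces)
  merged <- GenomicRanges::reduce(intervals_to_gr(cand))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    stringsAsFactors = FALSE
  )
  # Observed state of each merged interval.
  hits <- GenomicRanges::findOverlaps(read_points_gr(reads), intervals_to_gr(out))
  watson <- is_watson(reads$strand[S4Vectors::queryHits(hits)])
  iv <- S4Vectors::subjectHits(hits)
  nn <- rep(0L, nrow(out)); wsum <- rep(0, nrow(out))
  if (length(hits) > 0) {
    tw <- rowsum(cbind(n = 1, w = as.numeric(watson)), iv)
    idx <- as.integer(rownames(tw))
    nn[idx] <- tw[, "n"]; wsum[idx] <- tw[, "w"]
  }
  out$w_fraction <- ifelse(nn > 0, wsum / nn, NA_real_)
  out$state <- window_state(out$w_fraction, w_threshold, c_threshold)
  out$n_reads <- nn
  out[, c("chrom", "start", "end", "state", "n_reads", "w_fraction")]
}

full_genotype <- function(calls) {
  ifelse(calls$genotype == "HET", paste0("HET(", calls$phase, ")"),
         calls$genotype)
}

#' Merge overlapping same-genotype calls
#'
#' Confident non-REF calls that overlap and share genotype and phase are
#' replaced by their union span, which is then re-genotyped; the merged call
#' is kept only if the new genotype is confident and identical, otherwise
#' the original calls are retained. Disjoint calls and overlapping calls of
#' different genotype are left untouched.
#'
#' @param calls Call table from [genotype_intervals()].
#' @param ww,wc Composites used for re-genotyping.
#' @param b Background.
#' @param priors An [priors()] object.
#' @param ... Passed to [genotype_intervals()] for re-genotyping.
#' @return A call table.
#' @export
merge_same_genotype <- function(calls, ww, wc, b, priors = default_priors(), ...) {
  mergeable <- calls$genotype %in% c("HET", "HOM")
  keep <- calls[!mergeable, , drop = FALSE]
  cand <- calls[mergeable, , drop = FALSE]
  if (nrow(cand) == 0) return(calls)
  out <- list()
  for (g in unique(full_genotype(cand))) {
    sub <- cand[full_genotype(cand) == g, , drop = FALSE]
    gr <- intervals_to_gr(sub)
    cl <- GenomicRanges::reduce(gr, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(cl)$revmap
    for (k in seq_along(cl)) {
      members <- revmap[[k]]
      if (length(members) == 1) {
        out[[length(out) + 1]] <- sub[members, , drop = FALSE]
        next
      }
      span <- data.frame(chrom = sub$chrom[members[1]],
                         start = min(sub$start[members]),
                         end = max(sub$end[members]))
      regen <- genotype_intervals(span, ww, wc, b = b, priors = priors, ...)
      if (regen$genotype[1] != "AMBIGUOUS" && full_genotype(regen)[1] == g) {
        regen$provenance <- paste0(sub$provenance[members[1]], "+merged")
        out[[length(out) + 1]] <- regen
      } else {
        out[[length(out) + 1]] <- sub[members, , drop = FALSE]
      }
    }
  }
  res <- rbind(keep, do.call(rbind, out))
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Jointly choose the (start, end) pair maximizing summed deltaW, start
# strictly left of end, each within its search radius; the original
# endpoints participate with zero deltaW, so an endpoint without signal
# stays put. Ties go to the pair nearest the original endpoints.
best_endpoint_pair <- function(composites, chrom, start, end, radius,
                               window_sizes = c(40, 120, 360)) {
  cs <- delta_w_candidates(composites, chrom, start - radius, start + radius,
                           window_sizes)
  ce <- delta_w_candidates(composites, chrom, end - radius, end + radius,
                           window_sizes)
  cs <- rbind(cs, data.frame(pos = start, dw = 0))
  ce <- rbind(ce, data.frame(pos = end, dw = 0))
  ce <- ce[order(ce$pos), , drop = FALSE]
  suf_max <- rev(cummax(rev(ce$dw)))
  best <- NULL
  best_score <- -Inf
  best_dist <- Inf
  ord <- order(-cs$dw, abs(cs$pos - start))
  for (i in ord) {
    j <- findInterval(cs$pos[i], ce$pos) + 1  # first end candidate right of s
    if (j > nrow(ce)) next
    score <- cs$dw[i] + suf_max[j]
    if (score < best_score) next
    hits <- which(ce$pos > cs$pos[i] & ce$dw == suf_max[j])
    e_pos <- ce$pos[hits[which.min(abs(ce$pos[hits] - end))]]
    dist <- abs(cs$pos[i] - start) + abs(e_pos - end)
    if (score > best_score || dist < best_dist) {
      best_score <- score
      best_dist <- dist
      best <- c(cs$pos[i], e_pos)
    }
  }
  best
}

# Candidate (position, smoothed summed deltaW) pairs near a locus, pooled
# over both composites.
delta_w_candidates <- function(composites, chrom, lo, hi,
                               window_sizes = c(40, 120, 360)) {
  pieces <- lapply(composites, function(comp) {
    r <- comp$reads[comp$reads$chrom == chrom, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    dw <- smooth3(delta_w_profile(is_watson(r$strand), window_sizes))
    sel <- r$start >= lo & r$start <= hi
    if (!any(sel)) return(NULL)
    data.frame(pos = r$start[sel], dw = dw[sel])
  })
  do.call(rbind, pieces)
}

#' Adjust call breakpoints to deltaW peaks
#'
#' Each endpoint of each call is moved to a peak of the smoothed summed
#' deltaW profile among composite reads within a search radius (the
#' interval length, capped at `max_radius`). The two endpoints are chosen
#' jointly -- the pair of positions, start strictly left of end, with the
#' highest combined deltaW; ties are broken toward the original endpoints,
#' and an endpoint with no deltaW signal in its radius stays put. The
#' adjusted interval is re-genotyped and kept only if the new call is
#' confident and (for previously confident calls) matches the original
#' genotype and phase; previously ambiguous calls keep the adjustment
#' whenever the new call is confident. The operation is idempotent: a call
#' already at the peaks is returned unchanged.
#'
#' The radius is half the interval length (capped), so the two search
#' windows do not overlap and each endpoint can only lock onto its own
#' strand switch: a single broad deltaW plateau cannot capture both
#' endpoints.
#'
#' @inheritParams merge_same_genotype
#' @param max_radius Cap on the search radius in bp.
#' @param window_sizes deltaW window sizes in reads.
#' @return A call table with adjusted coordinates where retained.
#' @export
adjust_breakpoints <- function(calls, ww, wc, b, priors = default_priors(),
                               max_radius = 1e6, window_sizes = c(40, 120, 360),
                               ...) {
  composites <- list(ww, wc)
  res <- calls
  for (k in seq_len(nrow(calls))) {
    call <- calls[k, , drop = FALSE]
    radius <- min((call$end - call$start) / 2, max_radius)
    new_ends <- best_endpoint_pair(composites, call$chrom,
                                   call$start, call$end, radius, window_sizes)
    if (is.null(new_ends)) next
    if (new_ends[1] == call$start && new_ends[2] == call$end) next
    span <- data.frame(chrom = call$chrom, start = new_ends[1], end = new_ends[2])
    regen <- tryCatch(
      genotype_intervals(span, ww, wc, b = b, priors = priors, ...),
      error = function(e) NULL)
    if (is.null(regen)) next
    retain <- if (call$genotype == "AMBIGUOUS") {
      regen$genotype[1] != "AMBIGUOUS"
    } else {
      regen$genotype[1] != "AMBIGUOUS" &&
        full_genotype(regen)[1] == full_genotype(call)
    }
    if (retain) {
      regen$provenance <- paste0(call$provenance, "+adjusted")
      res[k, ] <- regen[1, , drop = FALSE]
    }
  }
  res
}
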