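# Background estimation: the proportion of non-directional reads in a
# composite, taken as the mode of a kernel density estimate over per-bin
# minority-orientation fractions. Using the mode (rather than the mean)
# keeps rare inversions and poorly-mapped regions from inflating the
# estimate.

#' Estimate the composite background
#'
#' For a WW-type composite: reads with mapping quality below `min_mapq` or
#' intersecting the blacklist are removed, the genome is cut into
#' `bin_size` bins, and each bin with at least `min_reads` reads (and not
#' intersecting the blacklist) contributes its minority-orientation read
#' fraction. The background `b` is the argmax of a Gaussian kernel density
#' (Scott's plug-in bandwidth, 512-point grid on `[0, 0.5]`) over those
#' fractions.
#'
#' For a WC-type composite the same routine runs on folded fractions
#' `|W-fraction - 0.5|` with `b = 0.5 - mode`; this is reported for
#' diagnostics only -- the genotype model uses a single background, by
#' default the WW-composite estimate.
#'
#' @param composite A `composite_reads` object.
#' @param bin_size Bin width in bp (default 1 Mb).
#' @param blacklist Optional data frame `chrom`, `start`, `end` of regions
#'   to exclude.
#' @param min_mapq Minimum read mapping quality.
#' @param min_reads Minimum reads per bin.
#' @param n_grid Density evaluation grid size.
#' @return Object of class `background_estimate`: list with `b`,
#'   `n_bins_used`, `fractions` (per-bin values retained for diagnostics)
#'   and `type`.
#' @export
estimate_background <- function(composite, bin_size = 1e6, blacklist = NULL,
                                min_mapq = 10, min_reads = 50, n_grid = 512) {
  stopifnot(inherits(composite, "composite_reads"))
  reads <- composite$reads
  if (nrow(reads) == 0) stop("empty composite: cannot estimate background")
  reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    reads <- reads[!points_in_intervals(reads, blacklist), , drop = FALSE]
  }
  if (nrow(reads) == 0) stop("no reads pass the MAPQ/blacklist filters")

  bin <- floor(reads$start / bin_size)
  key <- paste(reads$chrom, bin, sep = "\r")
  counts <- rowsum(cbind(n = 1, w = as.numeric(is_watson(reads$strand))), key)
  bins <- data.frame(
    chrom = sub("\r.*", "", rownames(counts)),
    bin = as.numeric(sub(".*\r", "", rownames(counts))),
    n = counts[, "n"], w = counts[, "w"], stringsAsFactors = FALSE
  )
  bins <- bins[bins$n >= min_reads, , drop = FALSE]
  if (!is.null(blacklist) && nrow(blacklist) > 0 && nrow(bins) > 0) {
    bgr <- intervals_to_gr(blacklist)
    bin_gr <- GenomicRanges::GRanges(
      bins$chrom, IRanges::IRanges(bins$bin * bin_size + 1, (bins$bin + 1) * bin_size))
    hit <- GenomicRanges::countOverlaps(bin_gr, bgr) > 0
    bins <- bins[!hit, , drop = FALSE]
  }
  if (nrow(bins) == 0) stop("no bins with >= ", min_reads, " reads after filters")

  wf <- bins$w / bins$n
  x <- if (composite$type == "wc") abs(wf - 0.5) else pmin(wf, 1 - wf)
  mode_x <- density_mode(x, n_grid)
  b <- if (composite$type == "wc") 0.5 - mode_x else mode_x
  if (composite$type != "wc" && b >= 0.5) {
    stop("estimated background >= 0.5: composite is not directional enough to use")
  }
  structure(list(b = unname(b), n_bins_used = nrow(bins), fractions = unname(x),
                 type = composite$type),
            class = "background_estimate")
}

# Mode of a Gaussian KDE (Scott's rule) on [0, 0.5]; degenerate samples
# (a single bin, or zero spread) return the median directly.
density_mode <- function(x, n_grid = 512) {
  if (length(x) < 2 || stats::sd(x) == 0) return(stats::median(x))
  bw <- tryCatch(stats::bw.nrd(x), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) return(stats::median(x))
  d <- density(x, bw = bw, n = n_grid, from = 0, to = 0.5)
  d$x[which.max(d$y)]
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("background estimate (%s composite): b = %.4f from %d bins\n",
              toupper(x$type), x$b, x$n_bins_used))
  invisible(x)
}
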