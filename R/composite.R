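# Composite read-set construction.
#
# A composite pools reads from many single-cell libraries after re-orienting
# them so that a common reference frame emerges. The WW-type composite keeps
# WW regions and strand-flips CC regions, so reference-orientation sequence
# reads almost entirely Watson. The WC-type composite keeps WC regions and
# strand-flips CW regions after phasing each library against heterozygous
# SNVs, so haplotype 1 is on Watson and haplotype 2 on Crick; a heterozygous
# inversion then shows a genuine strand switch, whereas a reference-assembly
# collapse does not.

#' Classify per-library strand states in genomic bins
#'
#' Bins each library's reads and classifies every bin by its Watson-read
#' fraction: `WW` if the fraction is at least `w_threshold`, `CC` if at most
#' `c_threshold`, otherwise `WC` (Watson-Crick, orientation undetermined).
#' Bins with fewer than `min_reads_per_bin` reads get state `unknown` and are
#' excluded downstream. Adjacent same-state bins are merged, so the returned
#' regions tile each chromosome per library.
#'
#' @param reads Read table (`chrom`, `start`, `end`, `library`, `mapq`,
#'   `strand`).
#' @param bin_size Bin width in bp. 1 Mb suits WW/CC classification; 20 Mb
#'   suits WC-region discovery for phasing.
#' @param chrom_lengths Named vector; defaults to the maximum read end per
#'   chromosome.
#' @param w_threshold,c_threshold Watson-fraction cutoffs for WW and CC.
#' @param min_reads_per_bin Minimum reads for a bin to be classified.
#' @return Data frame `library`, `chrom`, `start`, `end`, `state`,
#'   `w_fraction`, `n_reads`, with the per-bin table and binning parameters
#'   attached as attributes.
#' @export
classify_region_states <- function(reads, bin_size = 1e6, chrom_lengths = NULL,
                                   w_threshold = 0.8, c_threshold = 0.2,
                                   min_reads_per_bin = 20) {
  validate_reads(reads)
  if (nrow(reads) == 0) stop("at least one read per library is required")
  chrom_lengths <- chrom_lengths %||% chrom_lengths_from_reads(reads)
  libs <- sort(unique(reads$library))

  grid <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_size)
    expand.grid(library = libs, chrom = ch, bin = seq_len(nb) - 1L,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  bin <- floor(reads$start / bin_size)
  key <- paste(reads$library, reads$chrom, bin, sep = "\r")
  counts <- rowsum(cbind(n = 1, w = as.numeric(is_watson(reads$strand))), key)
  gkey <- paste(grid$library, grid$chrom, grid$bin, sep = "\r")
  m <- match(gkey, rownames(counts))
  grid$n_reads <- ifelse(is.na(m), 0, counts[m, "n"])
  grid$w <- ifelse(is.na(m), 0, counts[m, "w"])
  grid$w_fraction <- ifelse(grid$n_reads > 0, grid$w / grid$n_reads, NA_real_)
  grid$state <- ifelse(grid$n_reads < min_reads_per_bin, "unknown",
                ifelse(grid$w_fraction >= w_threshold, "WW",
                ifelse(grid$w_fraction <= c_threshold, "CC", "WC")))
  grid <- grid[order(grid$library, grid$chrom, grid$bin), , drop = FALSE]

  # Merge runs of adjacent same-state bins into regions.
  regions <- do.call(rbind, by(grid, list(grid$library, grid$chrom), function(g) {
    r <- rle(g$state)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1
    data.frame(
      library = g$library[1], chrom = g$chrom[1],
      start = g$bin[lo] * bin_size,
      end = pmin((g$bin[hi] + 1) * bin_size, chrom_lengths[[g$chrom[1]]]),
      state = r$values,
      w_fraction = vapply(seq_along(lo), function(i) {
        n <- sum(g$n_reads[lo[i]:hi[i]])
        if (n == 0) NA_real_ else sum(g$w[lo[i]:hi[i]]) / n
      }, 0),
      n_reads = vapply(seq_along(lo), function(i) sum(g$n_reads[lo[i]:hi[i]]), 0),
      stringsAsFactors = FALSE
    )
  }))
  rownames(regions) <- NULL
  attr(regions, "bins") <- grid
  attr(regions, "bin_size") <- bin_size
  attr(regions, "chrom_lengths") <- chrom_lengths
  regions
}

# State of the bin containing each read's start, for the library it belongs to.
read_bin_states <- function(reads, region_states) {
  bins <- attr(region_states, "bins")
  bin_size <- attr(region_states, "bin_size")
  if (is.null(bins) || is.null(bin_size)) {
    stop("region_states must come from classify_region_states()")
  }
  key <- paste(reads$library, reads$chrom, floor(reads$start / bin_size), sep = "\r")
  setNames(bins$state, paste(bins$library, bins$chrom, bins$bin, sep = "\r"))[key]
}

new_composite <- function(type, reads, chrom_lengths, n_flipped) {
  reads <- reads[order(reads$chrom, reads$start), , drop = FALSE]
  rownames(reads) <- NULL
  structure(list(type = type, reads = reads,
                 chrom_lengths = chrom_lengths, n_flipped = n_flipped),
            class = "composite_reads")
}

#' @export
print.composite_reads <- function(x, ...) {
  cat(sprintf("%s-type composite: %d reads (%d flipped) on %d chromosome(s)\n",
              toupper(x$type), nrow(x$reads), x$n_flipped,
              length(unique(x$reads$chrom))))
  invisible(x)
}

#' Build the WW-type composite
#'
#' Keeps reads from WW regions as-is, strand-flips reads from CC regions, and
#' drops WC/unknown regions. In the result, sequence in the reference
#' orientation reads as mostly Watson; a heterozygous inversion appears as a
#' 50/50 (WC-like) segment and a homozygous inversion as mostly Crick.
#'
#' @param reads Read table.
#' @param region_states Output of [classify_region_states()] (typically at
#'   1 Mb bins).
#' @return A `composite_reads` object of type `"ww"`.
#' @export
build_ww_composite <- function(reads, region_states) {
  validate_reads(reads)
  state <- read_bin_states(reads, region_states)
  keep <- !is.na(state) & state %in% c("WW", "CC")
  out <- reads[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no directional (WW/CC) regions found; cannot build a WW composite")
  }
  flip <- state[keep] == "CC"
  out$strand[flip] <- flip_strand(out$strand[flip])
  new_composite("ww", out, attr(region_states, "chrom_lengths"), sum(flip))
}

#' Phase WC-state libraries against heterozygous SNVs
#'
#' Assigns each WC-state library x chromosome an orientation label: `WC`
#' (haplotype 1 on the Watson strand) or `CW` (haplotype 1 on Crick). Every
#' read in a WC region that covers a het SNV votes: a Watson read carrying
#' allele `a` says the Watson haplotype carries `a`; a Crick read says it
#' carries the other allele (the SNV is heterozygous).
#'
#' With a phased SNV table (GT contains `|`), orientations are anchored to
#' VCF haplotype 1 directly and are comparable across chromosomes. With an
#' unphased table, a consensus is built greedily per chromosome -- the
#' library with the most informative reads seeds it, the rest join in
#' decreasing order of evidence, and assignments are iterated to convergence
#' -- so labels are defined only up to one global swap per chromosome.
#'
#' @param reads Read table carrying `snv_pos` / `allele` columns (0-based SNV
#'   position covered by the read and the observed allele, 0 = ref, 1 = alt).
#' @param region_states Output of [classify_region_states()] (typically at
#'   20 Mb bins).
#' @param snvs Het-SNV table (`chrom`, `pos`, `gt`), e.g. from
#'   [read_snv_vcf()].
#' @return Data frame `library`, `chrom`, `orientation` (WC / CW / unknown),
#'   `n_informative`.
#' @export
phase_wc_regions <- function(reads, region_states, snvs) {
  validate_reads(reads)
  if (!all(c("snv_pos", "allele") %in% names(reads))) {
    stop("reads must carry 'snv_pos' and 'allele' columns for phasing")
  }
  wc_cells <- unique(region_states[region_states$state == "WC",
                                   c("library", "chrom")])
  if (nrow(wc_cells) == 0) stop("no WC-state regions to phase")

  state <- read_bin_states(reads, region_states)
  obs <- reads[!is.na(state) & state == "WC" & !is.na(reads$snv_pos), , drop = FALSE]
  skey <- paste(snvs$chrom, snvs$pos, sep = "\r")
  m <- match(paste(obs$chrom, obs$snv_pos, sep = "\r"), skey)
  obs <- obs[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  # Allele implied on the Watson strand by each informative read.
  obs$w_allele <- ifelse(is_watson(obs$strand), obs$allele, 1L - obs$allele)

  phased <- length(m) > 0 && any(grepl("|", snvs$gt[m], fixed = TRUE))
  out <- wc_cells
  out$orientation <- "unknown"
  out$n_informative <- 0L

  for (i in seq_len(nrow(out))) {
    sub <- obs[obs$library == out$library[i] & obs$chrom == out$chrom[i], , drop = FALSE]
    out$n_informative[i] <- nrow(sub)
  }

  if (phased) {
    hap1_allele <- ifelse(snvs$gt == "0|1", 0L, ifelse(snvs$gt == "1|0", 1L, NA_integer_))
    obs$hap1_on_w <- obs$w_allele == hap1_allele[m]
    for (i in seq_len(nrow(out))) {
      sub <- obs[obs$library == out$library[i] & obs$chrom == out$chrom[i], , drop = FALSE]
      sub <- sub[!is.na(sub$hap1_on_w), , drop = FALSE]
      if (nrow(sub) == 0) next
      frac <- mean(sub$hap1_on_w)
      if (frac > 0.5) out$orientation[i] <- "WC"
      if (frac < 0.5) out$orientation[i] <- "CW"
    }
    rownames(out) <- NULL
    return(out)
  }

  # Unphased: greedy consensus per chromosome, largest evidence first.
  for (ch in unique(out$chrom)) {
    cells <- which(out$chrom == ch)
    cells <- cells[order(-out$n_informative[cells])]
    sub_ch <- obs[obs$chrom == ch, , drop = FALSE]
    if (nrow(sub_ch) == 0) next
    # Per library x SNV net vote for "allele 1 on Watson" (+1/-1 per read).
    lib_scores <- lapply(out$library[cells], function(lb) {
      s <- sub_ch[sub_ch$library == lb, , drop = FALSE]
      if (nrow(s) == 0) return(numeric(0))
      tapply(ifelse(s$w_allele == 1L, 1, -1), s$snv_pos, sum)
    })
    names(lib_scores) <- out$library[cells]
    consensus <- numeric(0)  # named by SNV pos; sign = consensus hap1 allele on W
    sign_of <- setNames(rep(NA_real_, length(cells)), out$library[cells])
    for (lb in out$library[cells]) {
      sc <- lib_scores[[lb]]
      if (length(sc) == 0) next
      if (length(consensus) == 0) {
        sign_of[lb] <- 1
      } else {
        shared <- intersect(names(sc), names(consensus))
        agr <- if (length(shared) > 0) sum(sc[shared] * sign(consensus[shared])) else 0
        sign_of[lb] <- if (agr >= 0) 1 else -1
      }
      add <- sign_of[lb] * sc
      all_pos <- union(names(consensus), names(add))
      consensus <- setNames(
        ifelse(is.na(consensus[all_pos]), 0, consensus[all_pos]) +
          ifelse(is.na(add[all_pos]), 0, add[all_pos]),
        all_pos)
    }
    # Iterate assignments against the consensus until stable.
    for (iter in 1:10) {
      changed <- FALSE
      for (lb in out$library[cells]) {
        sc <- lib_scores[[lb]]
        if (length(sc) == 0) next
        shared <- intersect(names(sc), names(consensus))
        if (length(shared) == 0) next
        agr <- sum(sc[shared] * sign(consensus[shared]))
        new_sign <- if (agr > 0) 1 else if (agr < 0) -1 else sign_of[lb]
        if (!identical(new_sign, sign_of[lb])) {
          consensus[names(sc)] <- consensus[names(sc)] +
            (new_sign - sign_of[lb]) * sc[names(sc)]
          sign_of[lb] <- new_sign
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (k in seq_along(cells)) {
      lb <- out$library[cells[k]]
      if (!is.na(sign_of[lb]) && length(lib_scores[[lb]]) > 0) {
        out$orientation[cells[k]] <- if (sign_of[lb] > 0) "WC" else "CW"
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Build the WC-type composite
#'
#' Keeps reads from WC-assigned library x chromosome combinations, flips
#' reads from CW-assigned ones, and drops WW/CC/unknown regions. In the
#' result, reference-orientation sequence reads ~50/50 Watson/Crick with
#' haplotype 1 on Watson; a HET(0|1) inversion reads mostly Watson, a
#' HET(1|0) inversion mostly Crick, and a HOM inversion stays ~50/50.
#'
#' @param reads Read table.
#' @param region_states Output of [classify_region_states()].
#' @param orientations Output of [phase_wc_regions()].
#' @return A `composite_reads` object of type `"wc"`.
#' @export
build_wc_composite <- function(reads, region_states, orientations) {
  validate_reads(reads)
  ok <- orientations[orientations$orientation %in% c("WC", "CW"), , drop = FALSE]
  if (nrow(ok) == 0) stop("no phased WC-state libraries; cannot build a WC composite")
  state <- read_bin_states(reads, region_states)
  okey <- paste(ok$library, ok$chrom, sep = "\r")
  rkey <- paste(reads$library, reads$chrom, sep = "\r")
  ori <- setNames(ok$orientation, okey)[rkey]
  keep <- !is.na(state) & state == "WC" & !is.na(ori)
  out <- reads[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no reads in phased WC regions")
  flip <- ori[keep] == "CW"
  out$strand[flip] <- flip_strand(out$strand[flip])
  new_composite("wc", out, attr(region_states, "chrom_lengths"), sum(flip))
}

#' Build both composites in one call
#'
#' Convenience wrapper: classifies strand states at `ww_bin_size` for the WW
#' composite and at `wc_bin_size` for WC-region discovery, phases WC-state
#' libraries against `snvs`, and returns both composites.
#'
#' @inheritParams classify_region_states
#' @param snvs Het-SNV table for phasing.
#' @param ww_bin_size,wc_bin_size Bin widths for the two classifications.
#' @param ... Passed on to [classify_region_states()].
#' @return List with `ww`, `wc`, `ww_states`, `wc_states`, `orientations`.
#' @export
build_composites <- function(reads, snvs, chrom_lengths = NULL,
                             ww_bin_size = 1e6, wc_bin_size = 2e7, ...) {
  ww_states <- classify_region_states(reads, bin_size = ww_bin_size,
                                      chrom_lengths = chrom_lengths, ...)
  wc_states <- classify_region_states(reads, bin_size = wc_bin_size,
                                      chrom_lengths = chrom_lengths, ...)
  orientations <- phase_wc_regions(reads, wc_states, snvs)
  list(ww = build_ww_composite(reads, ww_states),
       wc = build_wc_composite(reads, wc_states, orientations),
       ww_states = ww_states, wc_states = wc_states,
       orientations = orientations)
}
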