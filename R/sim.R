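# Seeded Strand-seq simulator.
#
# Emulates the data model the genotyper assumes: each library (cell) inherits
# one template strand per homolog and chromosome (WW / WC / CW / CC), reads
# are directional points drawn uniformly along each chromosome, an inversion
# carried by a haplotype flips the orientation of that haplotype's reads
# inside the inverted interval, and an i.i.d. background rate flips reads at
# random. Reference-collapse regions emit Bernoulli(0.5) orientations in
# every cell; deletion regions silence one haplotype. Sequencing error, GC
# bias, variable coverage and BrdU chemistry are deliberately not modelled.

#' Simulation configuration
#'
#' Assembles and validates the configuration for [simulate_dataset()].
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_libraries Number of single-cell libraries.
#' @param reads_per_library Reads drawn per library (before deletions).
#' @param background Fraction in `[0, 0.5)` of reads whose orientation is
#'   flipped independently at random (mis-oriented reads).
#' @param inversions `NULL` or a data frame with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `genotype` in
#'   `c("REF", "HET(0|1)", "HET(1|0)", "HOM")`. Genotype `g = a|b` lists the
#'   haplotype-1 allele first; allele 1 means inverted, so `HET(0|1)` carries
#'   the inversion on haplotype 2. Overlapping inversions with conflicting
#'   genotypes are rejected.
#' @param collapse_regions `NULL` or a data frame `chrom`, `start`, `end` of
#'   regions that present as WC in every library (reference-assembly
#'   collapse mimics).
#' @param deletion_regions `NULL` or a data frame `chrom`, `start`, `end`,
#'   `haplotype` (1 or 2); no reads are emitted from that haplotype there.
#' @param wc_fraction Expected fraction of library x chromosome combinations
#'   inheriting a Watson-Crick state (split equally between WC and CW).
#' @param snv_density Expected heterozygous SNVs per bp (phased, for the WC
#'   composite). Human-realistic densities are of order 1e-3.
#' @param read_length Read length in bp; reads are treated as points at
#'   their start for all counting, so this only affects SNV coverage.
#' @param mapq Mapping quality assigned to every simulated read.
#' @param seed Integer seed; identical configurations and seeds yield
#'   identical output.
#' @param inheritance Optional data frame `library`, `chrom`, `state`
#'   (WW/WC/CW/CC) overriding the random template-strand draw; used for
#'   controlled experiments.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths,
                       n_libraries = 20,
                       reads_per_library = 10000,
                       background = 0.05,
                       inversions = NULL,
                       collapse_regions = NULL,
                       deletion_regions = NULL,
                       wc_fraction = 0.5,
                       snv_density = 8e-4,
                       read_length = 100,
                       mapq = 60,
                       seed = 1,
                       inheritance = NULL) {
  stopifnot(is.numeric(chrom_lengths), length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  if (background < 0 || background >= 0.5) {
    stop("background must lie in [0, 0.5)")
  }
  stopifnot(wc_fraction >= 0, wc_fraction <= 1,
            n_libraries >= 1, reads_per_library >= 1)
  if (!is.null(inversions) && nrow(inversions) > 0) {
    if (!all(inversions$genotype %in% GENOTYPES)) {
      stop("inversion genotypes must be one of: ", paste(GENOTYPES, collapse = ", "))
    }
    check_chrom_lengths(inversions, chrom_lengths, "inversion")
    gr <- intervals_to_gr(inversions)
    hits <- GenomicRanges::findOverlaps(gr, gr)
    hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
    gq <- inversions$genotype[S4Vectors::queryHits(hits)]
    gs <- inversions$genotype[S4Vectors::subjectHits(hits)]
    if (any(gq != gs)) {
      stop("overlapping truth inversions with conflicting genotypes; ",
           "separate them or give them the same genotype")
    }
  }
  if (!is.null(collapse_regions) && nrow(collapse_regions) > 0) {
    check_chrom_lengths(collapse_regions, chrom_lengths, "collapse region")
  }
  if (!is.null(deletion_regions) && nrow(deletion_regions) > 0) {
    check_chrom_lengths(deletion_regions, chrom_lengths, "deletion region")
    stopifnot(all(deletion_regions$haplotype %in% c(1L, 2L)))
  }
  if (!is.null(inheritance)) {
    stopifnot(all(c("library", "chrom", "state") %in% names(inheritance)),
              all(inheritance$state %in% STRAND_STATES))
  }
  structure(list(
    chrom_lengths = chrom_lengths, n_libraries = as.integer(n_libraries),
    reads_per_library = as.integer(reads_per_library), background = background,
    inversions = inversions, collapse_regions = collapse_regions,
    deletion_regions = deletion_regions, wc_fraction = wc_fraction,
    snv_density = snv_density, read_length = as.integer(read_length),
    mapq = as.integer(mapq), seed = as.integer(seed), inheritance = inheritance
  ), class = "sim_config")
}

# Which haplotypes does a genotype invert?
inverted_haplotypes <- function(genotype) {
  switch(genotype,
    "REF" = integer(0),
    "HET(0|1)" = 2L,
    "HET(1|0)" = 1L,
    "HOM" = c(1L, 2L),
    stop("unknown genotype: ", genotype)
  )
}

#' Simulate a Strand-seq dataset
#'
#' Draws per-library template-strand inheritance, directional reads, phased
#' heterozygous SNVs, and returns them together with the ground truth. A
#' read's orientation is its haplotype's template strand, flipped if that
#' haplotype carries an inversion spanning the read start, then flipped again
#' independently with probability `background`. Reads starting in a collapse
#' region are oriented Bernoulli(0.5) regardless of inheritance.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `reads` (data frame: `chrom`, `start`, `end`,
#'   `library`, `mapq`, `strand` with '-' = Watson, plus truth columns `hap`,
#'   and SNV-coverage columns `snv_pos`/`allele` used for phasing), `snvs`
#'   (data frame `chrom`, `pos` (0-based), `ref`, `alt`, `gt`), and `truth`
#'   (list: `inversions`, `inheritance`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lens <- config$chrom_lengths
  chroms <- names(lens)
  libs <- sprintf("lib%02d", seq_len(config$n_libraries))

  # Template-strand inheritance per library x chromosome.
  if (is.null(config$inheritance)) {
    wc <- config$wc_fraction
    inh <- expand.grid(library = libs, chrom = chroms,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    inh$state <- sample(STRAND_STATES, nrow(inh), replace = TRUE,
                        prob = c((1 - wc) / 2, wc / 2, wc / 2, (1 - wc) / 2))
  } else {
    inh <- config$inheritance[, c("library", "chrom", "state")]
  }

  n <- config$n_libraries * config$reads_per_library
  reads <- data.frame(
    chrom = sample(chroms, n, replace = TRUE, prob = lens / sum(lens)),
    library = rep(libs, each = config$reads_per_library),
    stringsAsFactors = FALSE
  )
  max_start <- pmax(unname(lens[reads$chrom]) - config$read_length, 1)
  reads$start <- floor(runif(n) * max_start)
  reads$end <- reads$start + config$read_length
  reads$hap <- sample(c(1L, 2L), n, replace = TRUE)
  reads$mapq <- config$mapq

  # Deletions: silence one haplotype.
  del <- config$deletion_regions
  if (!is.null(del) && nrow(del) > 0) {
    drop <- rep(FALSE, nrow(reads))
    for (h in c(1L, 2L)) {
      dh <- del[del$haplotype == h, , drop = FALSE]
      if (nrow(dh) > 0) drop <- drop | (reads$hap == h & points_in_intervals(reads, dh))
    }
    reads <- reads[!drop, , drop = FALSE]
  }

  # Orientation from inheritance: state "a b" puts haplotype 1 on strand a.
  key <- paste(reads$library, reads$chrom, sep = "\r")
  state <- setNames(inh$state, paste(inh$library, inh$chrom, sep = "\r"))[key]
  hap1_watson <- state %in% c("WW", "WC")
  hap2_watson <- state %in% c("WW", "CW")
  watson <- ifelse(reads$hap == 1L, hap1_watson, hap2_watson)

  # Inversions flip the carrying haplotype's reads.
  inv <- config$inversions
  if (!is.null(inv) && nrow(inv) > 0) {
    for (h in c(1L, 2L)) {
      carrying <- inv[vapply(inv$genotype, function(g) h %in% inverted_haplotypes(g), TRUE), ,
                      drop = FALSE]
      if (nrow(carrying) > 0) {
        idx <- reads$hap == h & points_in_intervals(reads, carrying)
        watson[idx] <- !watson[idx]
      }
    }
  }

  # Collapse regions read ~50/50 in every cell.
  col <- config$collapse_regions
  if (!is.null(col) && nrow(col) > 0) {
    idx <- which(points_in_intervals(reads, col))
    watson[idx] <- runif(length(idx)) < 0.5
  }

  # i.i.d. background mis-orientation.
  if (config$background > 0) {
    flip <- runif(nrow(reads)) < config$background
    watson <- xor(watson, flip)
  }
  reads$strand <- ifelse(watson, "-", "+")

  # Phased heterozygous SNVs.
  snvs <- do.call(rbind, lapply(chroms, function(ch) {
    k <- rpois(1, lens[[ch]] * config$snv_density)
    k <- min(k, lens[[ch]] - 1)
    if (k == 0) return(NULL)
    pos <- sort(sample.int(lens[[ch]] - 1L, k))
    ref <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    data.frame(chrom = ch, pos = pos, ref = ref, alt = unname(alt),
               gt = sample(c("0|1", "1|0"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(snvs)) {
    snvs <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                       alt = character(0), gt = character(0))
  }

  # Annotate each read with the first het SNV it covers and the allele its
  # haplotype carries there (what a pileup would observe).
  reads$snv_pos <- NA_integer_
  reads$allele <- NA_integer_
  if (nrow(snvs) > 0 && nrow(reads) > 0) {
    rgr <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end))
    sgr <- GenomicRanges::GRanges(snvs$chrom, IRanges::IRanges(snvs$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(rgr, sgr, select = "first")
    cov <- !is.na(hits)
    reads$snv_pos[cov] <- snvs$pos[hits[cov]]
    hap1_allele <- ifelse(snvs$gt == "0|1", 0L, 1L)
    a1 <- hap1_allele[hits[cov]]
    reads$allele[cov] <- ifelse(reads$hap[cov] == 1L, a1, 1L - a1)
  }

  reads <- reads[order(reads$library, reads$chrom, reads$start), , drop = FALSE]
  rownames(reads) <- NULL
  reads$id <- seq_len(nrow(reads))
  reads <- reads[, c("chrom", "start", "end", "library", "mapq", "strand",
                     "hap", "snv_pos", "allele", "id")]

  truth_inv <- if (is.null(inv)) {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               genotype = character(0))
  } else {
    inv[, c("chrom", "start", "end", "genotype")]
  }
  list(reads = reads, snvs = snvs,
       truth = list(inversions = truth_inv, inheritance = inh),
       config = config)
}

#' Write / read a ground-truth inversion table
#'
#' BED6+ with the genotype in column 7; phase is encoded in the genotype
#' label itself (`HET(0|1)` vs `HET(1|0)`). Round-trips losslessly.
#'
#' @param truth Either the `truth` element of [simulate_dataset()] output or
#'   a data frame with `chrom`, `start`, `end`, `genotype`.
#' @param path Output file.
#' @export
write_truth <- function(truth, path) {
  inv <- if (is.data.frame(truth)) truth else truth$inversions
  if (nrow(inv) > 0 && !all(inv$genotype %in% GENOTYPES)) {
    stop("truth genotypes must be one of: ", paste(GENOTYPES, collapse = ", "))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand\tgenotype", con)
  if (nrow(inv) > 0) {
    out <- data.frame(inv$chrom, inv$start, inv$end,
                      sprintf("inv%04d", seq_len(nrow(inv))), 0L, "+",
                      inv$genotype)
    write_tsv_plain(out, con)
  }
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- tryCatch(
    read.table(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) NULL
  )
  if (is.null(tab)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), genotype = character(0)))
  }
  out <- data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
                    genotype = tab[[7]], stringsAsFactors = FALSE)
  if (!all(out$genotype %in% GENOTYPES)) {
    stop("truth file contains genotypes outside the 4-state alphabet")
  }
  out
}
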