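# Composite construction: strand-state classification, WW composite,
# phasing, WC composite.

# Hand-built read table: one read per row at evenly spaced positions.
manual_reads <- function(n_w, n_c, chrom = "chr1", library = "libA",
                         start0 = 0, span = 1e6, alleles_w = NULL,
                         alleles_c = NULL, snv_pos = NULL) {
  n <- n_w + n_c
  reads <- data.frame(
    chrom = chrom,
    start = floor(seq(start0, start0 + span - 200, length.out = n)),
    library = library, mapq = 60L,
    strand = c(rep("-", n_w), rep("+", n_c)),
    stringsAsFactors = FALSE
  )
  reads$end <- reads$start + 100L
  reads$snv_pos <- if (is.null(snv_pos)) NA_integer_ else snv_pos
  reads$allele <- NA_integer_
  if (!is.null(alleles_w)) reads$allele[reads$strand == "-"] <- alleles_w
  if (!is.null(alleles_c)) reads$allele[reads$strand == "+"] <- alleles_c
  reads[, c("chrom", "start", "end", "library", "mapq", "strand",
            "snv_pos", "allele")]
}

test_that("bins are classified by Watson fraction with a read floor", {
  reads <- rbind(manual_reads(98, 2),
                 manual_reads(52, 48, library = "libB"),
                 manual_reads(5, 5, library = "libC"))
  st <- classify_region_states(reads, bin_size = 1e6,
                               chrom_lengths = c(chr1 = 1e6))
  expect_equal(st$state[st$library == "libA"], "WW")
  expect_equal(st$state[st$library == "libB"], "WC")
  expect_equal(st$state[st$library == "libC"], "unknown")
  # 2/100 Watson is a CC bin.
  st2 <- classify_region_states(manual_reads(2, 98), bin_size = 1e6,
                                chrom_lengths = c(chr1 = 1e6))
  expect_equal(st2$state, "CC")
})

test_that("region states tile each chromosome per library", {
  fx <- fixture_small()
  st <- fx$comps$ww_states
  for (lb in unique(st$library)) {
    for (ch in names(fx$cfg$chrom_lengths)) {
      r <- st[st$library == lb & st$chrom == ch, ]
      r <- r[order(r$start), ]
      expect_equal(r$start[1], 0)
      expect_equal(r$end[nrow(r)], unname(fx$cfg$chrom_lengths[ch]))
      if (nrow(r) > 1) expect_equal(r$start[-1], r$end[-nrow(r)])
    }
  }
})

test_that("a simulated WC library is classified WC in 20 Mb bins", {
  inh <- data.frame(library = "lib01", chrom = "chr1", state = "WC")
  sim <- simulate_dataset(sim_config(chrom_lengths = c(chr1 = 2e8),
                                     n_libraries = 1,
                                     reads_per_library = 20000,
                                     background = 0.05, inheritance = inh,
                                     seed = 31))
  st <- classify_region_states(sim$reads, bin_size = 2e7,
                               chrom_lengths = c(chr1 = 2e8))
  expect_gte(mean(st$state == "WC"), 0.95)
})

test_that("the WW composite keeps WW regions and flips CC regions", {
  cc <- manual_reads(2, 98)
  st <- classify_region_states(cc, bin_size = 1e6,
                               chrom_lengths = c(chr1 = 1e6))
  comp <- build_ww_composite(cc, st)
  expect_equal(comp$type, "ww")
  expect_equal(mean(comp$reads$strand == "-"), 0.98)
  expect_equal(comp$n_flipped, 100)

  wc <- manual_reads(50, 50)
  st_wc <- classify_region_states(wc, bin_size = 1e6,
                                  chrom_lengths = c(chr1 = 1e6))
  expect_error(build_ww_composite(wc, st_wc), "WW composite")
})

test_that("simulated WW composite is directional outside inversions", {
  fx <- fixture_small()
  reads <- fx$comps$ww$reads
  outside <- !(reads$chrom == "chr1" & reads$start >= 10e6 & reads$start < 50.3e6)
  expect_gt(mean(reads$strand[outside] == "-"), 1 - 0.05 - 0.02)
})

test_that("libraries with identical allele-strand patterns get the same label", {
  snvs <- data.frame(chrom = "chr1", pos = seq(1000, 999000, by = 2000),
                     ref = "A", alt = "G", gt = "0/1",
                     stringsAsFactors = FALSE)
  mk <- function(lib, w_allele) {
    r <- manual_reads(50, 50, library = lib)
    r$snv_pos <- snvs$pos[seq_len(nrow(r))]
    r$allele <- ifelse(r$strand == "-", w_allele, 1L - w_allele)
    r
  }
  reads <- rbind(mk("libA", 1L), mk("libB", 1L), mk("libC", 0L))
  st <- classify_region_states(reads, bin_size = 1e6,
                               chrom_lengths = c(chr1 = 1e6))
  ori <- phase_wc_regions(reads, st, snvs)
  expect_equal(ori$orientation[ori$library == "libA"],
               ori$orientation[ori$library == "libB"])
  expect_false(ori$orientation[ori$library == "libC"] ==
                 ori$orientation[ori$library == "libA"])
  # Library with no informative reads is left unknown.
  reads2 <- rbind(reads, manual_reads(50, 50, library = "libD"))
  st2 <- classify_region_states(reads2, bin_size = 1e6,
                                chrom_lengths = c(chr1 = 1e6))
  ori2 <- phase_wc_regions(reads2, st2, snvs)
  expect_equal(ori2$orientation[ori2$library == "libD"], "unknown")
})

test_that("unphased consensus phasing matches the exhaustive oracle", {
  cells <- expand.grid(library = sprintf("lib%02d", 1:10), chrom = "chr1",
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(1)
  cells$state <- sample(c("WC", "CW"), 10, replace = TRUE)
  sim <- simulate_dataset(sim_config(chrom_lengths = c(chr1 = 2e7),
                                     n_libraries = 10,
                                     reads_per_library = 3000,
                                     background = 0.05, snv_density = 5e-4,
                                     inheritance = cells, seed = 33))
  snvs_unphased <- sim$snvs
  snvs_unphased$gt <- "0/1"
  st <- classify_region_states(sim$reads, bin_size = 2e7,
                               chrom_lengths = c(chr1 = 2e7))
  ori <- phase_wc_regions(sim$reads, st, snvs_unphased)

  scores <- lapply(sprintf("lib%02d", 1:10), function(lb) {
    lib_snv_scores(sim$reads[sim$reads$library == lb, ])
  })
  names(scores) <- sprintf("lib%02d", 1:10)
  best <- oracle_phase_assignment(scores)
  got <- ifelse(ori$orientation[match(names(best), ori$library)] == "WC", 1, -1)
  expect_true(all(got == best) || all(got == -best))
  # And the oracle itself recovers the simulated inheritance up to a swap.
  truth <- ifelse(cells$state == "WC", 1, -1)
  expect_true(all(got == truth) || all(got == -truth))
})

test_that("the WC composite shows the heterozygote strand switch", {
  fx <- fixture_small()
  wc <- fx$comps$wc$reads
  het01 <- wc$chrom == "chr1" & wc$start >= 10e6 & wc$start < 10.3e6
  het10 <- wc$chrom == "chr1" & wc$start >= 20e6 & wc$start < 20.1e6
  hom <- wc$chrom == "chr1" & wc$start >= 30e6 & wc$start < 30.1e6
  ref <- wc$chrom == "chr1" & wc$start >= 50e6 & wc$start < 50.3e6
  expect_gt(mean(wc$strand[het01] == "-"), 0.9)   # HET(0|1): all-Watson
  expect_lt(mean(wc$strand[het10] == "-"), 0.1)   # HET(1|0): all-Crick
  expect_lt(abs(mean(wc$strand[hom] == "-") - 0.5), 0.12)
  expect_lt(abs(mean(wc$strand[ref] == "-") - 0.5), 0.05)
})

test_that("flipping every orientation label swaps heterozygote phases only", {
  fx <- fixture_small()
  ori <- fx$comps$orientations
  flipped <- ori
  flipped$orientation <- ifelse(ori$orientation == "WC", "CW",
                         ifelse(ori$orientation == "CW", "WC",
                                ori$orientation))
  wc2 <- build_wc_composite(fx$sim$reads, fx$comps$wc_states, flipped)
  expect_equal(sort(wc2$reads$id), sort(fx$comps$wc$reads$id))
  m <- match(fx$comps$wc$reads$id, wc2$reads$id)
  expect_true(all(wc2$reads$strand[m] != fx$comps$wc$reads$strand))

  calls1 <- genotype_intervals(fx$inv, fx$comps$ww, fx$comps$wc, b = fx$bg$b)
  calls2 <- genotype_intervals(fx$inv, fx$comps$ww, wc2, b = fx$bg$b)
  expect_equal(calls2$p_het01, calls1$p_het10, tolerance = 1e-12)
  expect_equal(calls2$p_het10, calls1$p_het01, tolerance = 1e-12)
  expect_equal(calls2$p_ref, calls1$p_ref, tolerance = 1e-12)
  expect_equal(calls2$p_hom, calls1$p_hom, tolerance = 1e-12)
})

test_that("no read lands in both composites", {
  fx <- fixture_small()
  expect_length(intersect(fx$comps$ww$reads$id, fx$comps$wc$reads$id), 0)
})

test_that("building a WC composite without phased libraries fails", {
  reads <- manual_reads(50, 50)
  st <- classify_region_states(reads, bin_size = 1e6,
                               chrom_lengths = c(chr1 = 1e6))
  ori <- data.frame(library = "libA", chrom = "chr1", orientation = "unknown",
                    n_informative = 0L)
  expect_error(build_wc_composite(reads, st, ori), "phased")
})
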