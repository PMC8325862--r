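# Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Regularly spaced inversion grid: one inversion per genotype in rotation,
# placed in the second half of every `spacing`-wide slot so that no
# inversion crosses a classification-bin boundary.
inversion_grid <- function(chroms, n_per_chrom, size = 1e5, spacing = 2e6,
                           genotypes = c("REF", "HET(0|1)", "HET(1|0)", "HOM")) {
  do.call(rbind, lapply(chroms, function(ch) {
    k <- seq_len(n_per_chrom) - 1
    data.frame(chrom = ch,
               start = k * spacing + spacing / 2,
               end = k * spacing + spacing / 2 + size,
               genotype = rep_len(genotypes, n_per_chrom),
               stringsAsFactors = FALSE)
  }))
}

# Small dataset shared by composite/background/model/coords tests:
# two 60 Mb chromosomes, 20 libraries, one inversion per genotype class.
fixture_small <- function() cached("small", {
  inv <- data.frame(
    chrom = "chr1",
    start = c(10e6, 30e6, 50e6, 20e6),
    end = c(10.3e6, 30.1e6, 50.3e6, 20.1e6),
    genotype = c("HET(0|1)", "HOM", "REF", "HET(1|0)"),
    stringsAsFactors = FALSE
  )
  cfg <- sim_config(chrom_lengths = c(chr1 = 6e7, chr2 = 6e7),
                    n_libraries = 20, reads_per_library = 12000,
                    background = 0.05, inversions = inv, seed = 42)
  sim <- simulate_dataset(cfg)
  comps <- build_composites(sim$reads, sim$snvs,
                            chrom_lengths = cfg$chrom_lengths)
  bg <- estimate_background(comps$ww)
  list(cfg = cfg, sim = sim, comps = comps, bg = bg, inv = inv)
})

# Recovery-scale dataset: 300 truth intervals (REF/HET/HOM), 20 libraries,
# background 0.05, read density giving >= 50 reads per composite per
# inversion.
fixture_recovery <- function(seed = 7) cached(paste0("recovery", seed), {
  chroms <- c(chr1 = 2.04e8, chr2 = 2.04e8, chr3 = 2.04e8)
  inv <- inversion_grid(names(chroms), n_per_chrom = 100, size = 1e5,
                        genotypes = c("REF", "HET(0|1)", "HOM",
                                      "REF", "HET(1|0)", "HOM",
                                      "REF", "HET(0|1)", "HOM",
                                      "REF", "HET(1|0)", "HOM"))
  cfg <- sim_config(chrom_lengths = chroms, n_libraries = 20,
                    reads_per_library = 122400, background = 0.05,
                    inversions = inv, seed = seed)
  sim <- simulate_dataset(cfg)
  comps <- build_composites(sim$reads, sim$snvs,
                            chrom_lengths = cfg$chrom_lengths)
  bg <- estimate_background(comps$ww)
  list(cfg = cfg, sim = sim, comps = comps, bg = bg, inv = inv)
})

# Reconstruct phased genotype labels from a call table.
call_labels <- function(calls) {
  ifelse(calls$genotype == "HET", paste0("HET(", calls$phase, ")"),
         calls$genotype)
}

# Apply a global phase swap to genotype labels.
swap_phase <- function(labels) {
  out <- labels
  out[labels == "HET(0|1)"] <- "HET(1|0)"
  out[labels == "HET(1|0)"] <- "HET(0|1)"
  out
}
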