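# Bayesian core: strand-state likelihoods, genotype mixtures, posteriors,
# interval genotyping.

spec_priors <- function() priors(p_ref = 0.85, p_het = 0.1, p_hom = 0.05)

test_that("strand-state log-likelihoods follow the binomial with theta by state", {
  expect_equal(strand_state_loglik(0, 0, "WW", 0.1), 0)
  expect_equal(strand_state_loglik(5, 5, "WC", 0.1),
               log(choose(10, 5) * 0.5^10))
  expect_equal(strand_state_loglik(10, 0, "WW", 0.1), 10 * log(0.9))
  expect_equal(strand_state_loglik(0, 10, "CC", 0.1), 10 * log(0.9))
  # Counts cannot separate WC from CW.
  expect_equal(strand_state_loglik(3, 7, "WC", 0.2),
               strand_state_loglik(3, 7, "CW", 0.2))
  expect_error(strand_state_loglik(-1, 5, "WW", 0.1), "non-negative")
  expect_error(strand_state_loglik(1, 5, "WW", 0.6), "background")
})

test_that("genotype scores reproduce the direct-space oracle on key signatures", {
  p <- spec_priors()
  # Homozygous signature: WW composite all-Crick, WC composite balanced.
  s_hom <- genotype_logliks(c(0, 60), c(30, 30), b = 0.05, priors = p)
  expect_equal(names(which.max(s_hom)), "HOM")
  # Heterozygous 0|1 signature: WW balanced, WC all-Watson.
  s_het <- genotype_logliks(c(30, 30), c(60, 0), b = 0.05, priors = p)
  expect_equal(names(which.max(s_het)), "HET(0|1)")
  for (s in list(list(c(0, 60), c(30, 30)), list(c(30, 30), c(60, 0)))) {
    got <- genotype_logliks(s[[1]], s[[2]], b = 0.05, priors = p)
    want <- log(oracle_genotype_scores(s[[1]][1], s[[1]][2],
                                       s[[2]][1], s[[2]][2], 0.05, p))
    expect_equal(unname(got), unname(drop(want)), tolerance = 1e-12)
  }
})

test_that("zero counts collapse the scores to the mixture weights", {
  p <- spec_priors()
  got <- genotype_logliks(c(0, 0), c(0, 0), b = 0.05, priors = p)
  want <- log(drop(oracle_genotype_scores(0, 0, 0, 0, 0.05, p)))
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("posteriors normalize and the 95% rule gates the call", {
  post <- genotype_posterior(log(c(0.97, 0.01, 0.01, 0.01)))
  expect_equal(unname(post$posterior[1]), 0.97)
  expect_equal(post$call, "REF")
  expect_true(post$confident)

  flat <- genotype_posterior(rep(log(0.25), 4))
  expect_equal(unname(flat$posterior), rep(0.25, 4))
  expect_equal(flat$call, "AMBIGUOUS")

  expect_equal(sum(genotype_posterior(c(-3, -700, -2, -1))$posterior), 1,
               tolerance = 1e-9)
})

test_that("the collapse signature is ambiguous: posteriors echo the priors", {
  p <- spec_priors()
  s <- genotype_logliks(c(30, 30), c(30, 30), b = 0.05, priors = p)
  post <- genotype_posterior(s)
  expect_equal(post$call, "AMBIGUOUS")
  # The always-WC component dominates every genotype equally, so the
  # posteriors reduce to the (phase-split) genotype priors.
  expect_equal(unname(post$posterior), c(0.85, 0.05, 0.05, 0.05),
               tolerance = 0.01)
})

test_that("log-space scores match the direct-space oracle on a count grid", {
  p <- default_priors()
  grid <- expand.grid(ww_w = seq(0, 12, by = 3), ww_c = seq(0, 12, by = 3),
                      wc_w = seq(0, 12, by = 3), wc_c = seq(0, 12, by = 3))
  want <- oracle_genotype_scores(grid$ww_w, grid$ww_c, grid$wc_w, grid$wc_c,
                                 0.1, p)
  for (i in seq_len(nrow(grid))) {
    got <- genotype_logliks(c(grid$ww_w[i], grid$ww_c[i]),
                            c(grid$wc_w[i], grid$wc_c[i]), b = 0.1, priors = p)
    expect_equal(exp(unname(got)), unname(want[i, ]), tolerance = 1e-9)
  }
})

test_that("swapping WC-composite counts exchanges the heterozygote phases exactly", {
  p <- default_priors()
  set.seed(2)
  for (i in 1:50) {
    ww <- rpois(2, 20); wc <- rpois(2, 20)
    a <- genotype_posterior(genotype_logliks(ww, wc, b = 0.07, priors = p))
    s <- genotype_posterior(genotype_logliks(ww, rev(wc), b = 0.07, priors = p))
    expect_identical(unname(a$posterior[c("HET(0|1)", "HET(1|0)")]),
                     unname(s$posterior[c("HET(1|0)", "HET(0|1)")]))
    expect_identical(unname(a$posterior["REF"]), unname(s$posterior["REF"]))
    expect_identical(unname(a$posterior["HOM"]), unname(s$posterior["HOM"]))
  }
})

test_that("a concordant read never decreases its genotype's posterior", {
  p <- default_priors()
  post_of <- function(g, ww, wc) {
    genotype_posterior(genotype_logliks(ww, wc, b = 0.05, priors = p))$posterior[[g]]
  }
  grid <- expand.grid(w = seq(0, 20, by = 5), c = seq(0, 20, by = 5))
  for (i in seq_len(nrow(grid))) {
    ww <- c(grid$w[i], grid$c[i]); wc <- c(grid$c[i], grid$w[i])
    # REF expects Watson in the WW composite; HOM expects Crick there;
    # each HET phase expects its strand in the WC composite.
    expect_gte(post_of("REF", ww + c(1, 0), wc), post_of("REF", ww, wc))
    expect_gte(post_of("HOM", ww + c(0, 1), wc), post_of("HOM", ww, wc))
    expect_gte(post_of("HET(0|1)", ww, wc + c(1, 0)), post_of("HET(0|1)", ww, wc))
    expect_gte(post_of("HET(1|0)", ww, wc + c(0, 1)), post_of("HET(1|0)", ww, wc))
  }
})

test_that("simulated truth intervals are recovered by genotype_intervals", {
  fx <- fixture_small()
  calls <- genotype_intervals(fx$inv, fx$comps$ww, fx$comps$wc, b = fx$bg$b)
  labels <- call_labels(calls)
  # The 300 Kb HET and REF intervals genotype cleanly; the HOM interval is
  # large enough to drop out of 1 Mb WW classification bins, so the model
  # falls back on the deletion error state and stays shy of the threshold.
  expect_equal(labels[fx$inv$genotype == "HET(0|1)"], "HET(0|1)")
  expect_equal(labels[fx$inv$genotype == "HET(1|0)"], "HET(1|0)")
  expect_equal(labels[fx$inv$genotype == "REF"], "REF")
})

test_that("empty and off-genome intervals are handled", {
  fx <- fixture_small()
  iv <- data.frame(chrom = c("chr2", "chr9", "chr1"),
                   start = c(4e6, 1e6, 5.9e7),
                   end = c(4e6 + 1, 2e6, 7e7))
  expect_warning(calls <- genotype_intervals(iv, fx$comps$ww, fx$comps$wc,
                                             b = fx$bg$b),
                 "off the genome")
  expect_equal(nrow(calls), 1)  # the two off-genome intervals are skipped
  expect_equal(calls$genotype, "AMBIGUOUS")  # 1 bp: essentially no reads
  expect_error(suppressWarnings(
    genotype_intervals(iv[2:3, ], fx$comps$ww, fx$comps$wc, b = fx$bg$b)),
    "no genotypable")
})

test_that("confident HET on a declared haploid chromosome is downgraded", {
  fx <- fixture_small()
  iv <- fx$inv[fx$inv$genotype == "HET(0|1)", c("chrom", "start", "end")]
  calls <- genotype_intervals(iv, fx$comps$ww, fx$comps$wc, b = fx$bg$b,
                              haploid_chroms = "chr1")
  expect_equal(calls$genotype, "AMBIGUOUS")
  expect_equal(calls$note, "confident_HET_on_haploid_chrom")
})

test_that("oversized intervals are flagged but still genotyped", {
  fx <- fixture_small()
  iv <- data.frame(chrom = "chr2", start = 0, end = 9e6)
  expect_warning(calls <- genotype_intervals(iv, fx$comps$ww, fx$comps$wc,
                                             b = fx$bg$b),
                 "8 Mb")
  expect_true(calls$size_flag)
  expect_true(calls$genotype %in% c("REF", "HET", "HOM", "AMBIGUOUS"))
})
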