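# Optional external data

Two acceptance-level tests verify the package against published
supplementary tables that are not distributed with the package. To run
them, place the files here before installing:

* `public_inversion_catalogue.bed` — the published catalogue of 8787
  inversion/TIR intervals (BED: chrom, start, end). Used to check that
  the `l^2/i` unique-interval estimate at 80% reciprocal self-overlap is
  approximately 3701.
* `published_trio_genotypes.tsv` — tab-separated per-inversion,
  per-individual genotype table for the three published trios, with
  columns `inversion`, `individual`, `genotype` (REF/HET/HOM/AMBIGUOUS),
  optionally `chrom`, plus pedigree columns `father`, `mother`, `child`.
  Used to check the reported Mendelian discordance of 6.3% (42/667).

Without these files the corresponding tests fail with an explanatory
message; everything else in the package is self-contained.
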