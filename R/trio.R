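# Trio Mendelian-concordance accounting.
#
# A "trio genotype" is a complete set of three non-ambiguous genotypes
# (father, mother, child) at one inversion. It is discordant when no
# assignment of parental gametes explains the child: writing REF = {0,0},
# HET = {0,1}, HOM = {1,1}, the child needs one allele from each parent.

geno_class <- function(g) {
  g <- as.character(g)
  out <- ifelse(g %in% c("HET(0|1)", "HET(1|0)", "0|1", "1|0", "HET"), "HET",
         ifelse(g == "REF", "REF",
         ifelse(g == "HOM", "HOM",
         ifelse(g %in% c("AMBIGUOUS", "", ".", NA), "AMBIGUOUS", NA))))
  out[is.na(g)] <- "AMBIGUOUS"
  if (any(is.na(out))) stop("unrecognized genotype label(s): ",
                            paste(unique(g[is.na(out)]), collapse = ", "))
  out
}

#' Mendelian concordance of one trio genotype
#'
#' `TRUE` iff the child's two alleles can be drawn one from each parent:
#' a REF child requires that neither parent is HOM, a HOM child that
#' neither parent is REF, and a HET child that the parents are not both REF
#' and not both HOM. All three genotypes must be non-ambiguous.
#'
#' @param father,mother,child Genotype labels (`REF`, `HET`, `HOM`; phased
#'   HET labels are accepted and collapsed to `HET`). Vectorized.
#' @return Logical vector.
#' @export
is_concordant <- function(father, mother, child) {
  f <- geno_class(father); m <- geno_class(mother); ch <- geno_class(child)
  if (any(c(f, m, ch) == "AMBIGUOUS")) {
    stop("trio is incomplete (ambiguous genotype); filter before checking")
  }
  ifelse(ch == "REF", f != "HOM" & m != "HOM",
  ifelse(ch == "HOM", f != "REF" & m != "REF",
         !(f == "REF" & m == "REF") & !(f == "HOM" & m == "HOM")))
}

#' Mendelian discordance rate over a genotype table
#'
#' Counts complete trio genotypes (all three members non-ambiguous at an
#' inversion) and the discordant subset. Sex chromosomes are excluded by
#' default when the table carries a `chrom` column, since hemizygous calls
#' do not follow autosomal transmission.
#'
#' @param genotypes Data frame with columns `inversion` (identifier),
#'   `individual`, `genotype`, and optionally `chrom`.
#' @param pedigree Data frame with columns `father`, `mother`, `child`
#'   (individual identifiers; one row per trio).
#' @param exclude_chroms Chromosome names dropped before counting.
#' @return List `n_discordant`, `n_complete`, `fraction` (`NaN` with a
#'   warning when there are no complete trio genotypes), and `discordant`
#'   (table of the offending trios).
#' @export
discordance_rate <- function(genotypes, pedigree,
                             exclude_chroms = c("chrX", "chrY", "X", "Y")) {
  stopifnot(all(c("inversion", "individual", "genotype") %in% names(genotypes)),
            all(c("father", "mother", "child") %in% names(pedigree)))
  members <- unique(unlist(pedigree[, c("father", "mother", "child")]))
  missing <- setdiff(members, unique(genotypes$individual))
  if (length(missing) > 0) {
    stop("pedigree member(s) absent from the genotype table: ",
         paste(missing, collapse = ", "))
  }
  if ("chrom" %in% names(genotypes)) {
    genotypes <- genotypes[!(genotypes$chrom %in% exclude_chroms), , drop = FALSE]
  }
  n_complete <- 0L
  disc <- list()
  for (t in seq_len(nrow(pedigree))) {
    trio <- pedigree[t, ]
    for (id in unique(genotypes$inversion)) {
      g <- genotypes[genotypes$inversion == id, , drop = FALSE]
      pick <- function(who) {
        v <- g$genotype[g$individual == who]
        if (length(v) == 0) NA_character_ else v[1]
      }
      f <- pick(trio$father); m <- pick(trio$mother); ch <- pick(trio$child)
      if (any(is.na(c(f, m, ch))) ||
          any(geno_class(c(f, m, ch)) == "AMBIGUOUS")) next
      n_complete <- n_complete + 1L
      if (!is_concordant(f, m, ch)) {
        disc[[length(disc) + 1]] <- data.frame(
          inversion = id, trio = t, father = f, mother = m, child = ch,
          stringsAsFactors = FALSE)
      }
    }
  }
  n_disc <- length(disc)
  if (n_complete == 0) {
    warning("no complete trio genotypes; discordance fraction is undefined")
  }
  list(n_discordant = n_disc, n_complete = n_complete,
       fraction = if (n_complete > 0) n_disc / n_complete else NaN,
       discordant = if (n_disc > 0) do.call(rbind, disc) else NULL)
}

#' Phase-aware transmission check
#'
#' Optional stricter check for phased child genotypes under the convention
#' that the child's first-listed haplotype is paternal: the father must
#' carry the child's first allele and the mother the second. Never accepts
#' a trio the unphased [is_concordant()] rejects.
#'
#' @param father,mother Parent genotype labels (unphased classes suffice).
#' @param child_phase Child phased genotype, `"0|1"`, `"1|0"`, `"0|0"` or
#'   `"1|1"`.
#' @return Logical.
#' @export
is_concordant_phased <- function(father, mother, child_phase) {
  al <- as.integer(strsplit(child_phase, "|", fixed = TRUE)[[1]])
  stopifnot(length(al) == 2, all(al %in% 0:1))
  carries <- function(g, a) {
    cls <- geno_class(g)
    (a == 0 && cls != "HOM") || (a == 1 && cls != "REF")
  }
  carries(father, al[1]) && carries(mother, al[2])
}
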