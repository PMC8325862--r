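# File formats, run configuration and logging.
#
# Coordinates are 0-based half-open in BED files and 1-based in VCF and
# browser URLs. Strand '+' = Crick, '-' = Watson.

#' Write / read Strand-seq reads as BED
#'
#' BED6 with the library in the name column and MAPQ as the score, plus two
#' optional columns (`snv_pos`, `allele`) carrying SNV-coverage annotations
#' used for phasing. Round-trips losslessly apart from simulator-only truth
#' columns.
#'
#' @param reads Read table.
#' @param path File path.
#' @export
write_reads_bed <- function(reads, path) {
  validate_reads(reads)
  out <- data.frame(reads$chrom, reads$start, reads$end, reads$library,
                    reads$mapq, reads$strand)
  if (all(c("snv_pos", "allele") %in% names(reads))) {
    out$snv_pos <- ifelse(is.na(reads$snv_pos), ".", reads$snv_pos)
    out$allele <- ifelse(is.na(reads$allele), ".", reads$allele)
  }
  write_tsv_plain(out, path)
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_reads_bed <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  reads <- data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
                      library = tab[[4]], mapq = tab[[5]], strand = tab[[6]],
                      stringsAsFactors = FALSE)
  if (ncol(tab) >= 8) {
    reads$snv_pos <- suppressWarnings(as.integer(ifelse(tab[[7]] == ".", NA, tab[[7]])))
    reads$allele <- suppressWarnings(as.integer(ifelse(tab[[8]] == ".", NA, tab[[8]])))
  }
  validate_reads(reads)
  reads$id <- seq_len(nrow(reads))
  reads
}

#' Write / read a plain interval BED
#'
#' First three columns `chrom`, `start`, `end`; extra columns are preserved.
#'
#' @param intervals Data frame; `path` file path.
#' @export
write_bed <- function(intervals, path) {
  write_tsv_plain(intervals, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4 && all(tab[[4]] %in% GENOTYPES)) names(tab)[4] <- "genotype"
  tab
}

call_columns <- c("chrom", "start", "end", "genotype", "posterior", "phase",
                  "p_ref", "p_het01", "p_het10", "p_hom",
                  "ww_w", "ww_c", "wc_w", "wc_c", "size_flag", "note",
                  "provenance")

#' Write / read a call table as BED9+
#'
#' Tab-separated with a single `#`-prefixed header naming the columns of
#' [genotype_intervals()] output; `write_calls_bed(read_calls_bed(p), p)`
#' round-trips.
#'
#' @param calls Call table.
#' @param path File path.
#' @export
write_calls_bed <- function(calls, path) {
  stopifnot(all(call_columns %in% names(calls)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(call_columns, collapse = "\t")), con)
  out <- calls[, call_columns, drop = FALSE]
  out$note[out$note == ""] <- "."
  write_tsv_plain(out, con)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
read_calls_bed <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "integer",
                                   "character", "numeric", "character",
                                   "numeric", "numeric", "numeric", "numeric",
                                   "integer", "integer", "integer", "integer",
                                   "logical", "character", "character"))
  names(tab) <- call_columns
  tab$note[tab$note == "."] <- ""
  tab
}

#' Write calls as a minimal inversion VCF
#'
#' One `<INV>` record per call, 1-based POS, `END` and `SVTYPE=INV` in INFO,
#' and a single sample with `GT` (phased where available: `0|1`, `1|0`,
#' `1/1` for HOM, `0/0` for REF, `./.` for ambiguous) and `PP`, the
#' posterior probability of the called genotype.
#'
#' @param calls Call table.
#' @param path File path.
#' @param sample Sample name for the genotype column.
#' @export
write_calls_vcf <- function(calls, path, sample = "SAMPLE") {
  gt <- ifelse(calls$genotype == "REF", "0/0",
        ifelse(calls$genotype == "HOM", "1/1",
        ifelse(calls$genotype == "HET" & calls$phase %in% PHASES, calls$phase,
        ifelse(calls$genotype == "HET", "0/1", "./."))))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=strandinv",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PP,Number=1,Type=Float,Description=\"Posterior probability of the call\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"),
    sprintf("%s\t%d\t%s\tN\t<INV>\t.\t.\tEND=%d;SVTYPE=INV\tGT:PP\t%s:%.6g",
            calls$chrom, calls$start + 1L,
            sprintf("inv%04d", seq_len(nrow(calls))),
            calls$end, gt, calls$posterior)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal inversion VCF back into a call skeleton
#'
#' @param path File path.
#' @return Data frame `chrom`, `start`, `end`, `genotype`, `phase`,
#'   `posterior`.
#' @export
read_calls_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_end <- as.integer(sub(".*END=([0-9]+).*", "\\1", vcfR::getINFO(v)))
  gt <- as.character(vcfR::extract.gt(v, element = "GT"))
  pp <- as.numeric(vcfR::extract.gt(v, element = "PP"))
  genotype <- ifelse(gt == "0/0", "REF",
              ifelse(gt == "1/1", "HOM",
              ifelse(gt %in% c("0|1", "1|0", "0/1"), "HET", "AMBIGUOUS")))
  data.frame(chrom = fix$CHROM, start = as.integer(fix$POS) - 1L,
             end = info_end, genotype = genotype,
             phase = ifelse(gt %in% PHASES, gt, "."),
             posterior = pp, stringsAsFactors = FALSE)
}

#' Write / read phased heterozygous SNVs as a minimal VCF
#'
#' `GT` is phased (`0|1` / `1|0`) with the phase defining the haplotype-1
#' allele; positions are 1-based in the file and 0-based in the table.
#'
#' @param snvs SNV table (`chrom`, `pos`, `ref`, `alt`, `gt`).
#' @param path File path.
#' @param sample Sample name.
#' @export
write_snv_vcf <- function(snvs, path, sample = "SAMPLE") {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=strandinv",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  if (nrow(snvs) > 0) {
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t%s",
                              snvs$chrom, snvs$pos + 1L, snvs$ref, snvs$alt,
                              snvs$gt))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_snv_vcf
#' @export
read_snv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- as.character(vcfR::extract.gt(v, element = "GT"))
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
             ref = fix$REF, alt = fix$ALT, gt = gt, stringsAsFactors = FALSE)
}

#' UCSC Genome Browser links for a call table
#'
#' One URL per call, 1-based inclusive, padded by one interval length on
#' each side (clamped at position 1) so the flanking strand states are
#' visible.
#'
#' @param calls Call table (needs `chrom`, `start`, `end`).
#' @param genome_build Browser db label, e.g. `"hg38"`.
#' @return Data frame `chrom`, `start`, `end`, `position`, `url`.
#' @export
ucsc_links <- function(calls, genome_build = "hg38") {
  if (nrow(calls) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), position = character(0),
                      url = character(0)))
  }
  len <- calls$end - calls$start
  from <- pmax(1, calls$start - len + 1)
  to <- calls$end + len
  position <- sprintf("%s:%d-%d", calls$chrom, from, to)
  data.frame(
    chrom = calls$chrom, start = calls$start, end = calls$end,
    position = position,
    url = sprintf(
      "https://genome.ucsc.edu/cgi-bin/hgTracks?db=%s&position=%s",
      genome_build, position),
    stringsAsFactors = FALSE
  )
}

#' Write / read a composite read set
#'
#' The read BED plus `#`-prefixed header lines recording the composite type
#' and chromosome lengths, so the object round-trips.
#'
#' @param composite A `composite_reads` object.
#' @param path File path.
#' @export
write_composite <- function(composite, path) {
  stopifnot(inherits(composite, "composite_reads"))
  con <- file(path, "w")
  writeLines(c(
    paste0("#type=", composite$type),
    paste0("#chrom_lengths=", paste(sprintf("%s:%d",
      names(composite$chrom_lengths), as.integer(composite$chrom_lengths)),
      collapse = ",")),
    paste0("#n_flipped=", composite$n_flipped)
  ), con)
  close(con)
  r <- composite$reads
  out <- data.frame(r$chrom, r$start, r$end, r$library, r$mapq, r$strand)
  write_tsv_plain(out, path, append = TRUE)
  invisible(path)
}

#' @rdname write_composite
#' @export
read_composite <- function(path) {
  hdr <- readLines(path, n = 3)
  type <- sub("^#type=", "", hdr[1])
  cl_parts <- strsplit(sub("^#chrom_lengths=", "", hdr[2]), ",")[[1]]
  cl <- setNames(as.numeric(sub(".*:", "", cl_parts)), sub(":.*", "", cl_parts))
  n_flipped <- as.integer(sub("^#n_flipped=", "", hdr[3]))
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  reads <- data.frame(chrom = tab[[1]], start = tab[[2]], end = tab[[3]],
                      library = tab[[4]], mapq = tab[[5]], strand = tab[[6]],
                      stringsAsFactors = FALSE)
  new_composite(type, reads, cl, n_flipped)
}

#' Run configuration serialization
#'
#' A flat list of paths, priors, thresholds and window sizes, round-tripped
#' through YAML.
#'
#' @param config Named list.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

# Machine-readable run log: package version, configuration, background and
# priors, without which results are irreproducible.
write_run_log <- function(path, ..., config = NULL) {
  entries <- list(...)
  log <- c(list(
    tool = "strandinv",
    version = as.character(utils::packageVersion("strandinv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), entries)
  if (!is.null(config)) log$config <- config
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
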