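# Internal helpers shared across modules.

GENOTYPES <- c("REF", "HET(0|1)", "HET(1|0)", "HOM")
PHASES <- c("0|1", "1|0")
STRAND_STATES <- c("WW", "WC", "CW", "CC")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sorting before summation makes the result invariant to permutations of
# x, so symmetries of the model (e.g. the heterozygote phase swap) hold
# exactly in floating point.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(sort(exp(x - m))))
}

# Rowwise log-sum-exp over the columns of a matrix, guarding -Inf rows.
logsumexp_rows <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(-Inf)))
  out <- rep(-Inf, nrow(m))
  ok <- is.finite(mx)
  if (any(ok)) {
    s <- rowSums(exp(m[ok, , drop = FALSE] - mx[ok]))
    out[ok] <- mx[ok] + log(s)
  }
  out
}

# write.table with scientific notation disabled: genomic coordinates must
# never be serialized as 1e+07.
write_tsv_plain <- function(df, file, append = FALSE) {
  old <- options(scipen = 15)
  on.exit(options(old))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, append = append)
}

read_columns <- c("chrom", "start", "end", "library", "mapq", "strand")

validate_reads <- function(reads) {
  stopifnot(is.data.frame(reads))
  missing <- setdiff(read_columns, names(reads))
  if (length(missing) > 0) {
    stop("read table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(reads) > 0 && !all(reads$strand %in% c("+", "-"))) {
    stop("read strand must be '+' (Crick) or '-' (Watson)")
  }
  invisible(reads)
}

is_watson <- function(strand) strand == "-"

flip_strand <- function(strand) ifelse(strand == "-", "+", "-")

# 0-based half-open interval table -> GRanges (1-based closed).
intervals_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = pmax(df$end, df$start + 1L))
  )
}

# Read start points as width-1 GRanges.
read_points_gr <- function(reads) {
  GenomicRanges::GRanges(
    seqnames = as.character(reads$chrom),
    ranges = IRanges::IRanges(start = reads$start + 1L, width = 1L)
  )
}

# Which reads have their start position inside any of the intervals?
points_in_intervals <- function(reads, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0 || nrow(reads) == 0) {
    return(rep(FALSE, nrow(reads)))
  }
  hits <- GenomicRanges::findOverlaps(read_points_gr(reads), intervals_to_gr(intervals))
  out <- rep(FALSE, nrow(reads))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

chrom_lengths_from_reads <- function(reads) {
  tapply(reads$end, reads$chrom, max)
}

check_chrom_lengths <- function(intervals, chrom_lengths, what = "interval") {
  bad <- !(intervals$chrom %in% names(chrom_lengths)) |
    intervals$end > unname(chrom_lengths[intervals$chrom]) |
    intervals$start < 0 | intervals$end <= intervals$start
  if (any(bad)) {
    stop(sum(bad), " ", what, "(s) fall outside the declared chromosome lengths")
  }
  invisible(TRUE)
}
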