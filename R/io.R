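# Plain-text genomic file helpers. All coordinates 0-based half-open
# (BED convention).

#' Read / write BED intervals
#'
#' Minimal BED readers/writers: columns chrom, start, end, then
#' optionally name (BED4) and score/strand (BED6). No header.
#'
#' @param file Path.
#' @return `read_bed` returns a data.frame with `chrom`, `start`,
#'   `end` and, when present, `id`, `score`, `strand`.
#' @export
read_bed <- function(file) {
  df <- read.table(file, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "id", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' @rdname read_bed
#' @param df data.frame with `chrom`, `start`, `end` and optional
#'   further BED columns in order.
#' @export
write_bed <- function(df, file) {
  keep <- intersect(c("chrom", "start", "end", "id", "name", "score",
                      "strand"), names(df))
  write.table(df[, keep], file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a genome FASTA as a named character vector
#'
#' Wraps `Biostrings::readDNAStringSet`; sequences are returned in
#' lower case, names truncated at the first whitespace.
#'
#' @param file FASTA path (multi-line records supported).
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  out <- tolower(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read per-tissue BED files into the merge input format
#'
#' @param files Named character vector: tissue name -> BED path.
#' @return Named list of interval data.frames for
#'   [merge_across_tissues()].
#' @export
read_tissue_beds <- function(files) {
  stopifnot(!is.null(names(files)))
  lapply(files, read_bed)
}

#' Read an activity TSV (id, comma-separated tissues)
#'
#' @param file Path to a TSV written by [write_synthetic()].
#' @return data.frame with `id` and list column `tissues`.
#' @export
read_activity <- function(file) {
  df <- read.table(file, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  df$tissues <- strsplit(df$tissues, ",", fixed = TRUE)
  df
}
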