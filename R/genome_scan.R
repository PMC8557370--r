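# Sliding-window prediction tracks combining an enhancer-vs-random
# classifier with a tissue-discriminating classifier.

#' Sliding-window enhancer prediction track
#'
#' Slides a window along a region, featurizes each window, and combines
#' two classifiers: `model_enh` (enhancer vs random genomic regions)
#' gives p1, `model_ab` (tissue A vs tissue B enhancers) gives p2. The
#' A-track is the combination of p1 and p2 and the B-track the
#' combination of p1 and the complement probability 1 - p2. The default
#' combination is the product, under which
#' `track_a + track_b = p1` at every window.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom Chromosome to scan.
#' @param model_enh,model_ab `klr_model`s sharing one code-word space.
#' @param space The [codeword_space()] both models were trained on.
#' @param start,end Region bounds (0-based half-open); defaults to the
#'   whole chromosome.
#' @param window Window width in bp (default 2000).
#' @param step Step in bp (default 200, the segmentation bin).
#' @param combine `"product"` (default), `"min"`, or `"gated"`
#'   (second classifier reported only where p1 > 0.5, else 0).
#' @param mode Featurization mode for windows; occurrence features
#'   (default) blunt the width mismatch between scan windows and
#'   training elements.
#' @return An object of class `scan_track`: data.frame with `chrom`,
#'   `start`, `end`, `p1`, `p2`, `track_a`, `track_b`.
#' @export
scan_genome <- function(genome, chrom, model_enh, model_ab, space,
                        start = 0L, end = NULL, window = 2000L,
                        step = 200L,
                        combine = c("product", "min", "gated"),
                        mode = c("occurrence", "counts")) {
  combine <- match.arg(combine); mode <- match.arg(mode)
  stopifnot(chrom %in% names(genome),
            model_enh$m == space$m, model_ab$m == space$m)
  if (is.null(end)) end <- nchar(genome[[chrom]])
  if (end - start < window)
    stop("scan window is wider than the requested region")
  ws <- seq.int(start, end - window, by = step)
  seqs <- substring(genome[[chrom]], ws + 1L, ws + window)
  x <- featurize(seqs, space, mode = mode)
  p1 <- predict(model_enh, x)
  p2 <- predict(model_ab, x)
  comb <- switch(combine,
    product = list(a = p1 * p2, b = p1 * (1 - p2)),
    min = list(a = pmin(p1, p2), b = pmin(p1, 1 - p2)),
    gated = list(a = ifelse(p1 > 0.5, p2, 0),
                 b = ifelse(p1 > 0.5, 1 - p2, 0)))
  structure(data.frame(chrom = chrom, start = ws, end = ws + window,
                       p1 = p1, p2 = p2,
                       track_a = comb$a, track_b = comb$b),
            class = c("scan_track", "data.frame"),
            window = window, step = step, combine = combine)
}

#' Remove training elements overlapping a locus
#'
#' Drops every element overlapping the given region by >= 1 bp, so a
#' locus used for sliding-window demonstration can be excluded from
#' classifier training.
#'
#' @param table An [element_table()] (or any data.frame with `chrom`,
#'   `start`, `end`).
#' @param chrom,start,end Region to exclude (0-based half-open).
#' @return The table without overlapping elements.
#' @export
exclude_region <- function(table, chrom, start, end) {
  hit <- table$chrom == chrom & table$start < end & table$end > start
  out <- table[!hit, , drop = FALSE]
  attr(out, "element_width") <- attr(table, "element_width")
  attr(out, "bin_size") <- attr(table, "bin_size")
  out
}

#' Write a scan track column as bedGraph
#'
#' @param track A `scan_track`.
#' @param column Which value column to export (e.g. "track_a").
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_scan_bedgraph <- function(track, column, file) {
  stopifnot(column %in% names(track))
  writeLines(sprintf("%s\t%d\t%d\t%g", track$chrom, track$start,
                     track$end, track[[column]]), file)
  invisible(file)
}
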