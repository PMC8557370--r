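# ATAC-seq coverage with Tn5 shifts and aggregate footprint profiles.

#' Shifted 2-bp cut-site coverage from strand-labeled reads
#'
#' Treats each read as single-end, reduces it to the 2 bp starting at
#' its 5' end, and applies the Tn5 shift: forward-strand positions +4,
#' reverse-strand positions -5. The shifted 5' position is the inferred
#' transposition cut site; the 2-bp footprint covers that position and
#' the next base. Positions shifted off a chromosome end are clipped
#' (dropped individually).
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open; strand "+" or "-").
#' @param chrom_lengths Named integer vector of chromosome lengths (or a
#'   named character genome, whose `nchar` is used).
#' @return An object of class `coverage_track`: a named list of integer
#'   per-bp count vectors (index 1 = position 0).
#' @export
atac_coverage <- function(reads, chrom_lengths) {
  if (is.character(chrom_lengths))
    chrom_lengths <- setNames(nchar(chrom_lengths), names(chrom_lengths))
  if (is.null(reads$strand) || any(!reads$strand %in% c("+", "-")))
    stop("reads must carry strand '+' or '-'")
  fw <- reads$strand == "+"
  p5 <- ifelse(fw, reads$start + 4L, reads$end - 1L - 5L)
  track <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    cov <- integer(len)
    sel <- reads$chrom == cn
    for (off in 0:1) {
      pos <- p5[sel] + off
      pos <- pos[pos >= 0L & pos < len]
      if (length(pos)) {
        tb <- tabulate(pos + 1L, nbins = len)
        cov <- cov + tb
      }
    }
    cov
  })
  names(track) <- names(chrom_lengths)
  structure(track, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosomes, total mass %d\n",
              length(x), sum(vapply(x, sum, 0))))
  invisible(x)
}

# leftmost match start (0-based, within seq) of either orientation of a
# code word; NA if absent. `word` may be a canonical label "p|q" or a
# plain pattern.
first_occurrence <- function(seqs, word) {
  pats <- unique(strsplit(tolower(word), "|", fixed = TRUE)[[1L]])
  subj <- Biostrings::DNAStringSet(toupper(seqs))
  best <- rep(NA_integer_, length(seqs))
  for (p in pats) {
    hits <- Biostrings::vmatchPattern(toupper(p), subj, fixed = FALSE)
    st <- vapply(hits, function(h)
      if (length(h)) min(Biostrings::start(h)) else NA_integer_, 0L)
    best <- pmin(best, st - 1L, na.rm = TRUE)
  }
  best
}

all_occurrences <- function(seq, word) {
  pats <- unique(strsplit(tolower(word), "|", fixed = TRUE)[[1L]])
  subj <- Biostrings::DNAString(toupper(seq))
  st <- integer(0)
  for (p in pats) {
    h <- Biostrings::matchPattern(toupper(p), subj, fixed = FALSE)
    st <- c(st, Biostrings::start(h) - 1L)
  }
  sort(unique(st))
}

word_length <- function(word) {
  nchar(strsplit(tolower(word), "|", fixed = TRUE)[[1L]][1L])
}

#' Aggregate footprint profile around aligned anchors
#'
#' Aligns the coverage track around anchor points and returns the mean
#' coverage and a dispersion band per offset. Modes: `"codeword"`
#' anchors at the center of the first (leftmost, either orientation)
#' occurrence of the code word in each element containing it (elements
#' without the word are omitted); `"element-center"` anchors the same
#' element set at the element centers (control); `"mito"` anchors at
#' every occurrence of the word in the mitochondrial sequence (`chrM`).
#' Anchors whose window extends beyond the chromosome are dropped.
#'
#' @param track A `coverage_track` from [atac_coverage()].
#' @param elements An [element_table()] or `dataset_spec` (ignored in
#'   mito mode).
#' @param word Code-word label ("p|q") or plain gapped pattern.
#' @param genome Named character vector of chromosome sequences.
#' @param W Profile half-width in bp (default 500).
#' @param mode `"codeword"`, `"element-center"` or `"mito"`.
#' @param band `"sem"` for 2 standard errors of the per-offset mean
#'   (default) or `"sd"` for 2 standard deviations across anchors.
#' @param mito_chrom Name of the mitochondrial sequence (default
#'   "chrM").
#' @return An object of class `footprint_profile`: data.frame with
#'   `offset`, `mean`, `band`, plus `n_anchors` and the anchor table in
#'   attributes. `n_anchors = 0` yields an empty profile.
#' @export
footprint_profile <- function(track, elements, word, genome, W = 500L,
                              mode = c("codeword", "element-center",
                                       "mito"),
                              band = c("sem", "sd"), mito_chrom = "chrM") {
  mode <- match.arg(mode); band <- match.arg(band)
  wl <- word_length(word)
  stopifnot(W >= wl)
  half_off <- (wl - 1L) %/% 2L
  if (mode == "mito") {
    if (!mito_chrom %in% names(genome) || !mito_chrom %in% names(track))
      stop("mitochondrial sequence '", mito_chrom, "' not found")
    occ <- all_occurrences(genome[[mito_chrom]], word)
    anchors <- data.frame(chrom = rep(mito_chrom, length(occ)),
                          pos = occ + half_off, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(elements)
    seqs <- element_sequences(df, genome)
    st <- first_occurrence(seqs, word)
    keep <- !is.na(st)
    df <- df[keep, , drop = FALSE]
    anchors <- data.frame(
      chrom = df$chrom,
      pos = if (mode == "codeword") df$start + st[keep] + half_off
            else (df$start + df$end) %/% 2L,
      stringsAsFactors = FALSE)
  }
  # drop anchors whose window leaves the chromosome
  lens <- vapply(track, length, 0L)[anchors$chrom]
  ok <- anchors$pos - W >= 0L & anchors$pos + W < lens
  anchors <- anchors[which(ok), , drop = FALSE]
  n <- nrow(anchors)
  offs <- -W:W
  if (n == 0L) {
    prof <- data.frame(offset = offs, mean = NA_real_, band = NA_real_)
    return(structure(prof, class = c("footprint_profile", "data.frame"),
                     n_anchors = 0L, mode = mode, word = word,
                     anchors = anchors))
  }
  mat <- matrix(0, nrow = n, ncol = length(offs))
  for (a in seq_len(n)) {
    cov <- track[[anchors$chrom[a]]]
    mat[a, ] <- cov[(anchors$pos[a] - W):(anchors$pos[a] + W) + 1L]
  }
  mu <- colMeans(mat)
  sdv <- apply(mat, 2L, sd)
  b <- if (band == "sem") 2 * sdv / sqrt(n) else 2 * sdv
  prof <- data.frame(offset = offs, mean = mu, band = b)
  structure(prof, class = c("footprint_profile", "data.frame"),
            n_anchors = n, mode = mode, word = word, anchors = anchors)
}

#' @export
print.footprint_profile <- function(x, ...) {
  cat(sprintf("footprint_profile (%s, '%s'): %d anchors, W = %d\n",
              attr(x, "mode"), attr(x, "word"), attr(x, "n_anchors"),
              max(x$offset)))
  invisible(x)
}

#' Base frequencies of aligned code-word neighborhoods
#'
#' Computes per-offset base frequencies of the sequences aligned at the
#' given anchors (e.g. from a footprint profile), the data behind
#' neighborhood logos. Ambiguous bases are excluded from the
#' denominator, so each column over \{a,c,g,t\} sums to 1.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param anchors data.frame with `chrom`, `pos` (e.g.
#'   `attr(profile, "anchors")`).
#' @param W Half-width in bp.
#' @return 4 x (2W+1) matrix of frequencies, rows a, c, g, t, columns
#'   named by offset.
#' @export
neighborhood_frequency <- function(genome, anchors, W) {
  offs <- -W:W
  counts <- matrix(0, nrow = 4, ncol = length(offs),
                   dimnames = list(c("a", "c", "g", "t"), offs))
  for (a in seq_len(nrow(anchors))) {
    s <- substring(tolower(genome[[anchors$chrom[a]]]),
                   anchors$pos[a] - W + 1L, anchors$pos[a] + W + 1L)
    ch <- strsplit(s, "")[[1L]]
    for (b in c("a", "c", "g", "t"))
      counts[b, ] <- counts[b, ] + (ch == b)
  }
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  sweep(counts, 2L, tot, "/")
}

#' Export a coverage track as bedGraph
#'
#' @param track A `coverage_track`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_coverage_bedgraph <- function(track, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (cn in names(track)) {
    cov <- track[[cn]]
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", cn, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(file)
}
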