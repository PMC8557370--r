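#' Regulatory element table
#'
#' A data.frame of regulatory elements with 0-based half-open
#' coordinates (`chrom`, `start`, `end`, `id`) and a list column
#' `tissues` holding each element's activity set.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `id`.
#' @param tissues List of character vectors (one activity set per row).
#' @param bin_size Segmentation bin size in bp (default 200).
#' @param element_width Uniform element width after resizing (default
#'   1000).
#' @return An object of class `element_table` (a data.frame).
#' @export
element_table <- function(df, tissues, bin_size = 200L,
                          element_width = 1000L) {
  stopifnot(all(c("chrom", "start", "end", "id") %in% names(df)),
            nrow(df) == length(tissues),
            all(lengths(tissues) >= 1L))
  df <- df[, c("chrom", "start", "end", "id")]
  df$tissues <- tissues
  structure(df, class = c("element_table", "data.frame"),
            bin_size = as.integer(bin_size),
            element_width = as.integer(element_width))
}

#' @export
print.element_table <- function(x, ...) {
  cat(sprintf("element_table: %d elements, %d tissues, width %s\n",
              nrow(x), length(unique(unlist(x$tissues))),
              attr(x, "element_width")))
  NextMethod()
}

table_has <- function(table, tissue) {
  vapply(table$tissues, function(a) tissue %in% a, TRUE)
}

#' Merge per-tissue element intervals into a multi-tissue table
#'
#' Joins all intervals that overlap by at least one bin (transitive
#' closure); for bin-aligned segmentations an overlap of >= 1 bp implies
#' a shared full bin, and the same >= 1 bp rule is used as the fallback
#' for arbitrary inputs. Each merged element's activity set is the union
#' of contributing tissues. Merged elements are then resized to
#' `element_width` bp centered on the merged span's center (centers of
#' odd-width spans round down).
#'
#' @param tissue_intervals Named list (one entry per tissue) of
#'   data.frames with `chrom`, `start`, `end` (0-based half-open).
#' @param bin_size Bin size in bp (default 200).
#' @param element_width Output element width in bp (default 1000).
#' @return An [element_table()] sorted by chromosome and start.
#' @export
merge_across_tissues <- function(tissue_intervals, bin_size = 200L,
                                 element_width = 1000L) {
  stopifnot(is.list(tissue_intervals), !is.null(names(tissue_intervals)))
  all_df <- do.call(rbind, lapply(names(tissue_intervals), function(t) {
    d <- tissue_intervals[[t]]
    data.frame(chrom = d$chrom, start = d$start, end = d$end, tissue = t,
               stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(
    all_df$chrom, IRanges::IRanges(all_df$start + 1L, all_df$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(merged, gr, minoverlap = 1L)
  tis <- lapply(
    split(all_df$tissue[S4Vectors::subjectHits(hits)],
          factor(S4Vectors::queryHits(hits), levels = seq_along(merged))),
    function(v) sort(unique(v)))
  st0 <- GenomicRanges::start(merged) - 1L
  en0 <- GenomicRanges::end(merged)
  center <- (st0 + en0) %/% 2L
  half <- as.integer(element_width) %/% 2L
  new_start <- center - half
  new_end <- new_start + as.integer(element_width)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                   start = new_start, end = new_end,
                   id = NA_character_, stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$start)
  df <- df[ord, ]
  df$id <- sprintf("e%05d", seq_len(nrow(df)))
  rownames(df) <- NULL
  element_table(df, tissues = tis[ord], bin_size = bin_size,
                element_width = element_width)
}

new_dataset_spec <- function(name, pos, neg, removed = NULL) {
  spec <- rbind(
    if (nrow(pos)) cbind(pos, label = 1) else NULL,
    if (nrow(neg)) cbind(neg, label = 0) else NULL)
  rownames(spec) <- NULL
  structure(spec, class = c("dataset_spec", "data.frame"),
            name = name,
            removed_ids = if (is.null(removed)) character(0) else removed)
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat(sprintf("dataset_spec '%s': %d positives, %d negatives (%d removed)\n",
              attr(x, "name"), sum(x$label == 1), sum(x$label == 0),
              length(attr(x, "removed_ids"))))
  invisible(x)
}

spec_cols <- function(table) {
  as.data.frame(table)[, c("id", "chrom", "start", "end")]
}

#' One-vs-rest (leaves) data set for a target tissue
#'
#' Positives are elements active in the target tissue only; negatives
#' are elements active in at least one other tissue and not in the
#' target. Elements active in both the target and any other tissue are
#' removed entirely, since their sequence features need not be specific
#' to either side.
#'
#' @param table An [element_table()].
#' @param target Tissue name.
#' @return A `dataset_spec` (data.frame with `id`, `chrom`, `start`,
#'   `end`, `label`; removed element ids in `attr(, "removed_ids")`).
#' @export
leaves_collection <- function(table, target) {
  tissues <- unique(unlist(table$tissues))
  if (!target %in% tissues) stop("target tissue not present in the table")
  if (length(tissues) < 2L) stop("need at least two tissues")
  in_target <- table_has(table, target)
  n_other <- lengths(table$tissues) - as.integer(in_target)
  pos <- in_target & n_other == 0L
  neg <- !in_target
  removed <- in_target & n_other > 0L
  cols <- spec_cols(table)
  new_dataset_spec(paste0("leaves:", target),
                   cols[pos, , drop = FALSE], cols[neg, , drop = FALSE],
                   table$id[removed])
}

#' Tissue similarity by shared elements
#'
#' Entry (A, B) counts the merged elements active in both A and B; the
#' diagonal holds per-tissue totals.
#'
#' @param table An [element_table()].
#' @return Symmetric integer matrix with tissue dimnames.
#' @export
tissue_similarity <- function(table) {
  tissues <- sort(unique(unlist(table$tissues)))
  memb <- vapply(tissues, function(t) table_has(table, t),
                 logical(nrow(table)))
  s <- crossprod(memb)
  storage.mode(s) <- "integer"
  dimnames(s) <- list(tissues, tissues)
  s
}

#' Hierarchical clustering of tissues
#'
#' Agglomerates tissues with [stats::hclust()] on the distance
#' d(A, B) = 1 - s(A, B) / min(s(A, A), s(B, B)) derived from the
#' shared-element similarity. Tissues are ordered lexicographically
#' first, which makes the result invariant to input order (deterministic
#' tie-breaking).
#'
#' @param similarity Symmetric similarity matrix from
#'   [tissue_similarity()].
#' @param method Linkage passed to [stats::hclust()] (default
#'   "complete").
#' @return An `hclust` tree.
#' @export
cluster_tissues <- function(similarity, method = "complete") {
  if (nrow(similarity) < 2L) stop("need at least two tissues to cluster")
  ord <- order(rownames(similarity))
  s <- similarity[ord, ord]
  dmin <- outer(diag(s), diag(s), pmin)
  d <- 1 - s / dmin
  stats::hclust(stats::as.dist(d), method = method)
}

# leaf label sets of every internal node of an hclust tree
hclust_clusters <- function(tree) {
  n <- length(tree$labels)
  cl <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    mem <- unlist(lapply(tree$merge[i, ], function(j) {
      if (j < 0) tree$labels[-j] else cl[[j]]
    }))
    cl[[i]] <- sort(mem)
  }
  cl
}

#' Data sets from tissue bipartitions of the clustering tree
#'
#' Removing an edge of the tissue tree bipartitions the tissues; each
#' non-root internal node of the rooted tree contributes the bipartition
#' (its leaf set, the complement), with duplicate bipartitions (the two
#' edges at the root) collapsed. The smaller tissue set is taken as
#' positive. Per data set, positives are elements active in at least one
#' positive tissue and no negative tissue; negatives mirror this;
#' elements active on both sides are removed.
#'
#' @param tree An `hclust` tree over >= 3 tissues (see
#'   [cluster_tissues()]).
#' @param table An [element_table()].
#' @return Named list of entries, each with `bipartition`
#'   (list(positive, negative)) and `spec` (a `dataset_spec`).
#' @export
clustered_collection <- function(tree, table) {
  tissues <- sort(tree$labels)
  if (length(tissues) < 3L) stop("need at least three tissues")
  cl <- hclust_clusters(tree)
  cl <- cl[-length(cl)]  # drop the root
  # orient: smaller side positive (lexicographic first tissue on ties)
  parts <- lapply(cl, function(side) {
    other <- setdiff(tissues, side)
    if (length(side) < length(other) ||
        (length(side) == length(other) && side[1] < other[1]))
      list(positive = side, negative = other)
    else
      list(positive = other, negative = side)
  })
  keys <- vapply(parts, function(p) paste(p$positive, collapse = ","), "")
  parts <- parts[!duplicated(keys)]
  names(parts) <- vapply(parts, function(p)
    paste(p$positive, collapse = "+"), "")
  lapply(parts, function(p) {
    n_pos <- vapply(table$tissues, function(a)
      sum(a %in% p$positive), 0L)
    n_neg <- vapply(table$tissues, function(a)
      sum(a %in% p$negative), 0L)
    pos <- n_pos > 0L & n_neg == 0L
    neg <- n_neg > 0L & n_pos == 0L
    removed <- n_pos > 0L & n_neg > 0L
    cols <- spec_cols(table)
    list(bipartition = p,
         spec = new_dataset_spec(
           paste(p$positive, collapse = "+"),
           cols[pos, , drop = FALSE], cols[neg, , drop = FALSE],
           table$id[removed]))
  })
}

#' Enhancer-versus-random data set
#'
#' Positives are all elements of the table; negatives are an equal
#' number of uniform random genomic regions of the same width (no
#' genomic region excluded).
#'
#' @param table An [element_table()].
#' @param genome Named character vector of chromosome sequences.
#' @param seed Integer seed for the random regions.
#' @return A `dataset_spec`.
#' @export
enhancer_vs_random <- function(table, genome, seed = 1L) {
  w <- attr(table, "element_width")
  rnd <- generate_random_regions(genome, nrow(table), w, seed = seed)
  new_dataset_spec("enhancer_vs_random", spec_cols(table),
                   rnd[, c("id", "chrom", "start", "end")])
}

#' Chromosome-split control data set
#'
#' Labels every element by chromosome membership: elements on the
#' positive chromosome list are positive, all remaining elements
#' negative; nothing is removed. With no chromosome-linked sequence
#' signal, classifier performance on this set should be near the
#' prevalence baseline.
#'
#' @param table An [element_table()].
#' @param positive_chroms Chromosomes forming the positive class
#'   (default chr3, chr5, chr7, chr11, chr13, chr17, chr19).
#' @return A `dataset_spec`.
#' @export
chromosome_control <- function(table,
                               positive_chroms = paste0(
                                 "chr", c(3, 5, 7, 11, 13, 17, 19))) {
  pos <- table$chrom %in% positive_chroms
  cols <- spec_cols(table)
  new_dataset_spec("chromosome_control",
                   cols[pos, , drop = FALSE], cols[!pos, , drop = FALSE])
}

#' Observed-to-expected CpG ratio
#'
#' N_CG * L / (N_C * N_G) for a sequence of length L, with CG
#' dinucleotides counted by an overlapping scan. Returns `NA` when the
#' sequence contains no C or no G (undefined ratio).
#'
#' @param sequence Character vector of DNA sequences.
#' @return Numeric vector of CpG ratios.
#' @examples
#' cpg_ratio("cgcg") # 2
#' cpg_ratio("acgt") # 4
#' @export
cpg_ratio <- function(sequence) {
  sequence <- tolower(sequence)
  vapply(sequence, function(s) {
    L <- nchar(s)
    if (L < 2L) return(NA_real_)
    ch <- strsplit(s, "")[[1L]]
    nc <- sum(ch == "c"); ng <- sum(ch == "g")
    if (nc == 0L || ng == 0L) return(NA_real_)
    ncg <- sum(ch[-L] == "c" & ch[-1L] == "g")
    ncg * L / (nc * ng)
  }, 0, USE.NAMES = FALSE)
}

#' Extract element sequences from a genome
#'
#' @param spec_or_table A `dataset_spec` or [element_table()] (needs
#'   `chrom`, `start`, `end`).
#' @param genome Named character vector of chromosome sequences.
#' @return Character vector of sequences (forward strand), named by id.
#' @export
element_sequences <- function(spec_or_table, genome) {
  df <- as.data.frame(spec_or_table)
  bad <- !df$chrom %in% names(genome)
  if (any(bad)) stop("chromosomes absent from genome: ",
                     paste(unique(df$chrom[bad]), collapse = ", "))
  setNames(substring(genome[df$chrom], df$start + 1L, df$end), df$id)
}

#' Build a labeled feature dataset from a dataset spec
#'
#' Extracts element sequences, featurizes them against a code-word
#' space, and bundles features, labels and coordinates into a
#' [klr_dataset()].
#'
#' @param spec A `dataset_spec`.
#' @param genome Named character vector of chromosome sequences.
#' @param space A [codeword_space()].
#' @param mode `"counts"` or `"occurrence"`.
#' @return A [klr_dataset()].
#' @export
build_dataset <- function(spec, genome, space,
                          mode = c("counts", "occurrence")) {
  mode <- match.arg(mode)
  seqs <- element_sequences(spec, genome)
  x <- featurize(seqs, space, mode = mode)
  klr_dataset(x, spec$label, feature_labels = space$labels, mode = mode,
              chrom = spec$chrom, start = spec$start, ids = spec$id)
}
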