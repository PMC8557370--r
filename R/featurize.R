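#' Map DNA sequences to sparse code-word feature vectors
#'
#' Scans every window of each sequence against a [codeword_space()]. A
#' window matches a gapped pattern when all non-gap positions agree;
#' every window of length k contributes one match for each of its
#' 2^(k-2) gappifications, credited to the pattern's canonical code
#' word. A window matching a pattern in both orientations (a palindromic
#' instance) is counted once; a non-palindromic code word accumulates
#' matches of both members of its pair, which makes counts exactly
#' invariant under reverse complementation of the sequence. Windows
#' containing characters outside \{a,c,g,t\} contribute nothing.
#'
#' @param sequences Character vector of DNA sequences (or a
#'   `Biostrings::DNAStringSet`), case-insensitive.
#' @param space A [codeword_space()].
#' @param mode `"counts"` for match counts, `"occurrence"` for binarized
#'   presence/absence.
#' @return A sparse `Matrix::dgCMatrix` of dimension
#'   `length(sequences) x space$m`, with `space$labels` as column names
#'   omitted (kept separate for memory); rows follow the input order.
#' @examples
#' sp <- codeword_space(4, 4)
#' featurize("acgt", sp)
#' @export
featurize <- function(sequences, space, mode = c("counts", "occurrence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(space, "codeword_space"))
  if (methods::is(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  sequences <- as.character(sequences)
  tri <- cw_featurize_cpp(sequences, space$k_min, space$k_max,
                          space$lookups, space$m, mode == "occurrence")
  Matrix::sparseMatrix(i = tri$i + 1L, j = tri$j + 1L, x = tri$x,
                       dims = c(length(sequences), space$m))
}

#' Count code-word features of a single sequence
#'
#' Convenience wrapper around [featurize()] returning the nonzero
#' entries as a named numeric vector (names are canonical labels).
#'
#' @inheritParams featurize
#' @param sequence A single DNA sequence.
#' @return Named numeric vector of nonzero code-word counts.
#' @export
count_features <- function(sequence, space) {
  stopifnot(length(sequence) == 1L)
  x <- featurize(sequence, space, mode = "counts")
  j <- which(x[1L, ] != 0)
  setNames(as.numeric(x[1L, j]), space$labels[j])
}

#' Binarize a count feature vector or matrix
#'
#' Maps every nonzero count to 1 ("occurrence" features).
#'
#' @param x Numeric vector or sparse matrix of nonnegative counts.
#' @return Object of the same shape with nonzero entries set to 1.
#' @export
binarize <- function(x) {
  if (methods::is(x, "sparseMatrix")) {
    x <- methods::as(x, "CsparseMatrix")
    x@x <- rep(1, length(x@x))
    return(x)
  }
  x[x != 0] <- 1
  x
}

#' Fit per-column unit-variance scales on training data
#'
#' Returns the per-column sample standard deviation (n-1 denominator)
#' used to normalize count features to unit variance. Data are scaled by
#' division only, never centered, so sparsity is preserved. Zero-variance
#' columns get scale 1 (left unscaled).
#'
#' @param x Sparse or dense numeric matrix (training rows only).
#' @return Numeric vector of column scales (length `ncol(x)`).
#' @export
fit_scales <- function(x) {
  n <- nrow(x)
  if (n < 2L) return(rep(1, ncol(x)))
  cs <- Matrix::colSums(x)
  cs2 <- Matrix::colSums(x^2)
  v <- (cs2 - cs^2 / n) / (n - 1)
  v[v < 0] <- 0  # numerical guard
  s <- sqrt(v)
  s[s == 0] <- 1
  as.numeric(s)
}

#' Apply per-column scales
#'
#' Divides each column by its scale. Inverse operation is applying
#' `1/scales`.
#'
#' @param x Numeric matrix (sparse or dense).
#' @param scales Numeric vector from [fit_scales()].
#' @return Scaled matrix of the same class family.
#' @export
apply_scales <- function(x, scales) {
  stopifnot(length(scales) == ncol(x))
  x %*% Matrix::Diagonal(x = 1 / scales)
}

#' Write / read a sparse feature matrix as text triplets
#'
#' Serializes a feature matrix in a plain-text triplet format
#' (row, column, value; 1-based) with a companion label index
#' (column, label).
#'
#' @param x Sparse feature matrix.
#' @param space The [codeword_space()] the columns refer to.
#' @param file Path of the triplet file; the label index is written to
#'   `paste0(file, ".labels")`.
#' @return `file`, invisibly.
#' @export
write_feature_matrix <- function(x, space, file) {
  tr <- methods::as(methods::as(x, "CsparseMatrix"), "TsparseMatrix")
  df <- data.frame(row = tr@i + 1L, col = tr@j + 1L, value = tr@x)
  df <- df[order(df$row, df$col), ]
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- data.frame(col = seq_len(space$m), label = space$labels)
  write.table(idx, paste0(file, ".labels"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_feature_matrix
#' @param dims Dimensions of the matrix to restore.
#' @export
read_feature_matrix <- function(file, dims) {
  df <- read.table(file, header = TRUE, sep = "\t")
  Matrix::sparseMatrix(i = df$row, j = df$col, x = df$value, dims = dims)
}
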