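#' Merge cross-validation models into stable coefficients
#'
#' For each feature, takes the coefficient with the minimum absolute
#' value across the fold models (sign carried from that fold). A feature
#' is therefore nonzero only if it is nonzero in every fold; features
#' with inconsistent signs across folds are set to zero (conservative
#' reading of "stable across all training sets"). Extraction is
#' restricted to occurrence-feature models, whose coefficients compare
#' directly across folds; pass `require_occurrence = FALSE` to override.
#'
#' @param models List of `klr_model` objects over the same feature
#'   space (e.g. `lapply(cv$folds, function(f) f$model)`).
#' @param require_occurrence Enforce occurrence-mode models (default
#'   TRUE).
#' @return An object of class `merged_coefficients`: a named numeric
#'   vector of merged coefficients (nonzero entries only) with the fold
#'   count in `attr(, "n_models")`.
#' @examples
#' # folds with coefficients 0.5, 0.3, 0.4 for one feature merge to 0.3
#' @export
merge_cv_models <- function(models, require_occurrence = TRUE) {
  stopifnot(length(models) >= 1L)
  m <- models[[1L]]$m
  labs <- models[[1L]]$feature_labels
  for (mdl in models) {
    if (mdl$m != m || !identical(mdl$feature_labels, labs))
      stop("models do not share a feature space")
    if (require_occurrence && mdl$mode != "occurrence")
      stop("code-word extraction uses occurrence-feature models; ",
           "set require_occurrence = FALSE to override")
  }
  # features nonzero in every model
  idx <- Reduce(intersect, lapply(models, `[[`, "beta_index"))
  if (!length(idx))
    return(structure(setNames(numeric(0), character(0)),
                     class = "merged_coefficients",
                     n_models = length(models)))
  coefs <- vapply(models, function(mdl) {
    v <- numeric(length(idx))
    v <- mdl$beta_value[match(idx, mdl$beta_index)]
    v
  }, numeric(length(idx)))
  coefs <- matrix(coefs, nrow = length(idx))
  sign_ok <- apply(coefs, 1L, function(v) all(v > 0) || all(v < 0))
  pick <- apply(coefs, 1L, function(v) v[which.min(abs(v))])
  merged <- ifelse(sign_ok, pick, 0)
  keep <- merged != 0
  structure(setNames(merged[keep],
                     if (is.null(labs)) as.character(idx[keep])
                     else labs[idx[keep]]),
            class = "merged_coefficients", n_models = length(models))
}

#' @export
print.merged_coefficients <- function(x, ...) {
  cat(sprintf("merged_coefficients: %d stable features from %d models\n",
              length(x), attr(x, "n_models")))
  invisible(x)
}

#' Top tissue-specific code words
#'
#' Ranks positively weighted merged features by coefficient (descending,
#' ties broken lexicographically by label). Only positive coefficients
#' are reported: they mark code words whose presence favors the positive
#' (single-tissue) set.
#'
#' @param merged A `merged_coefficients` object (or named numeric
#'   vector).
#' @param count Maximum number of code words to return.
#' @return data.frame with `rank`, `code_word`, `coefficient`.
#' @export
top_code_words <- function(merged, count = 10L) {
  pos <- merged[merged > 0]
  if (!length(pos))
    return(data.frame(rank = integer(0), code_word = character(0),
                      coefficient = numeric(0)))
  ord <- order(-unname(pos), names(pos), method = "radix")
  pos <- pos[ord]
  n <- min(count, length(pos))
  data.frame(rank = seq_len(n), code_word = names(pos)[seq_len(n)],
             coefficient = unname(pos)[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Write ranked code words to TSV
#'
#' @param words data.frame from [top_code_words()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_code_words <- function(words, file) {
  write.table(words, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
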