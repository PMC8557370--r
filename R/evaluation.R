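#' ROC and precision-recall evaluation of classifier scores
#'
#' Sweeps all score thresholds (ties grouped), returning ROC points with
#' trapezoidal ROC-AUC, precision-recall points with step-interpolated
#' PR-AUC (precision steps, no trapezoid, avoiding optimistic
#' interpolation bias), and the positive-prevalence baseline.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (0/1), both classes present.
#' @return List with `roc` (data.frame fpr, tpr), `pr` (data.frame
#'   recall, precision), `roc_auc`, `pr_auc`, `baseline`.
#' @examples
#' evaluate_scores(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$roc_auc # 0.75
#' @export
evaluate_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("both classes must be present to evaluate scores")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  tpr <- c(0, tp / np); fpr <- c(0, fp / nn)
  roc_auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  prec <- tp / (tp + fp); rec <- tp / np
  pr_auc <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = rec, precision = prec),
       roc_auc = roc_auc, pr_auc = pr_auc,
       baseline = np / (np + nn))
}

stratified_folds <- function(y, folds, seed) {
  with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
}

chromosome_folds <- function(chrom, start, folds) {
  if (is.null(chrom)) stop("dataset has no chromosome metadata")
  groups <- unique(chrom[order(chrom, start)])
  if (length(groups) < folds)
    stop(sprintf("chromosome-sorted folds need >= %d chromosomes, got %d",
                 folds, length(groups)))
  # contiguous chromosome blocks, balanced by element count
  n_by <- table(chrom)[groups]
  target <- sum(n_by) / folds
  fold_of_group <- integer(length(groups))
  acc <- 0; f <- 1L
  for (g in seq_along(groups)) {
    fold_of_group[g] <- f
    acc <- acc + n_by[g]
    if (acc >= target * f && f < folds) f <- f + 1L
  }
  fold_of_group[match(chrom, groups)]
}

#' Default leapfrog feature-count grid
#'
#' q = 10; 100 to 900 by 100; 1000 to 6000 by 1000 (16 values).
#'
#' @return Integer vector of length 16.
#' @export
default_q_grid <- function() {
  as.integer(c(10, seq(100, 900, by = 100), seq(1000, 6000, by = 1000)))
}

#' Cross-validated KLR with nested feature-count selection
#'
#' Evaluates a KLR classifier by k-fold cross-validation. Within each
#' training fold, 10% (by default) is reserved as a validation set: one
#' leapfrog path is fitted on the remainder, the grid value `q`
#' maximizing validation PR-AUC is selected, and the model is refitted
#' at the selected `q` on the full training fold before scoring the
#' held-out fold. Unit-variance scales (count mode) are always fitted on
#' training data only. With a single-element `q_grid` the validation
#' stage is skipped. Curves are pooled over the concatenated held-out
#' scores; macro-averaged PR-AUC is reported alongside.
#'
#' @param dataset A [klr_dataset()].
#' @param q_grid Candidate feature counts (default [default_q_grid()]).
#' @param folds Number of folds (default 10).
#' @param val_frac Fraction of the training fold reserved for selecting
#'   q (default 0.1).
#' @param seed Integer seed controlling fold assignment and solvers.
#' @param split_mode `"random-stratified"` or `"chromosome-sorted"`
#'   (contiguous chromosome blocks per fold; requires coordinates).
#' @param opts Solver options ([klr_opts()]); the seed within is derived
#'   from `seed` per fold.
#' @return An object of class `klr_cv`: per-fold models, selected q,
#'   held-out scores/labels; pooled ROC/PR curves and AUCs; baseline.
#' @export
cross_validate <- function(dataset, q_grid = default_q_grid(), folds = 10L,
                           val_frac = 0.1, seed = 1L,
                           split_mode = c("random-stratified",
                                          "chromosome-sorted"),
                           opts = klr_opts()) {
  split_mode <- match.arg(split_mode)
  stopifnot(length(q_grid) >= 1L)
  y <- dataset$y
  fold_id <- switch(split_mode,
    "random-stratified" = stratified_folds(y, folds, seed),
    "chromosome-sorted" = chromosome_folds(dataset$chrom, dataset$start,
                                           folds))
  fold_results <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    if (length(unique(y[train_idx])) < 2L)
      stop("a training fold lost a class; use stratified folds")
    fopts <- opts
    fopts$seed <- as.integer((seed * 1000L + f) %% .Machine$integer.max)
    train_ds <- subset_dataset(dataset, train_idx)
    if (length(q_grid) > 1L) {
      val_idx_local <- with_seed(seed * 100L + f, {
        unlist(lapply(split(seq_along(train_idx), y[train_idx]),
                      function(ix) sample(ix, max(1L, round(
                        val_frac * length(ix))))))
      })
      sub_ds <- subset_dataset(train_ds, setdiff(seq_along(train_idx),
                                                 val_idx_local))
      val_ds <- subset_dataset(train_ds, val_idx_local)
      cand <- klr_leapfrog_multi(sub_ds, q_grid, fopts)
      val_auc <- vapply(cand, function(mdl) {
        evaluate_scores(predict(mdl, val_ds$x), val_ds$y)$pr_auc
      }, 0)
      q_sel <- q_grid[which.max(val_auc)]
    } else {
      q_sel <- q_grid[1L]
      val_auc <- NULL
    }
    model <- klr_leapfrog(train_ds, q_sel, fopts)
    sc <- predict(model, dataset$x[test_idx, , drop = FALSE])
    fold_results[[f]] <- list(model = model, q = q_sel,
                              val_pr_auc = val_auc,
                              test_idx = test_idx,
                              scores = sc, labels = y[test_idx])
  }
  pooled_scores <- unlist(lapply(fold_results, `[[`, "scores"))
  pooled_labels <- unlist(lapply(fold_results, `[[`, "labels"))
  ev <- evaluate_scores(pooled_scores, pooled_labels)
  macro <- mean(vapply(fold_results, function(fr) {
    if (length(unique(fr$labels)) < 2L) return(NA_real_)
    evaluate_scores(fr$scores, fr$labels)$pr_auc
  }, 0), na.rm = TRUE)
  structure(list(folds = fold_results,
                 selected_q = vapply(fold_results, `[[`, 0L, "q"),
                 scores = pooled_scores, labels = pooled_labels,
                 roc = ev$roc, pr = ev$pr,
                 roc_auc = ev$roc_auc, pr_auc = ev$pr_auc,
                 macro_pr_auc = macro, baseline = ev$baseline,
                 split_mode = split_mode),
            class = "klr_cv")
}

#' @export
print.klr_cv <- function(x, ...) {
  cat(sprintf(
    "klr_cv (%s, %d folds): pooled PR-AUC %.3f (baseline %.3f), ROC-AUC %.3f\n",
    x$split_mode, length(x$folds), x$pr_auc, x$baseline, x$roc_auc))
  cat("selected q per fold:", paste(x$selected_q, collapse = " "), "\n")
  invisible(x)
}

subset_dataset <- function(dataset, idx) {
  klr_dataset(dataset$x[idx, , drop = FALSE], dataset$y[idx],
              dataset$feature_labels, mode = dataset$mode,
              chrom = dataset$chrom[idx], start = dataset$start[idx],
              ids = dataset$ids[idx])
}

#' Write pooled CV curves to TSV
#'
#' @param cv A `klr_cv` object.
#' @param file Output path; ROC and PR points are stacked with a
#'   `curve` column.
#' @return `file`, invisibly.
#' @export
write_cv_curves <- function(cv, file) {
  roc <- data.frame(curve = "roc", x = cv$roc$fpr, y = cv$roc$tpr)
  pr <- data.frame(curve = "pr", x = cv$pr$recall, y = cv$pr$precision)
  write.table(rbind(roc, pr), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
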