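#' Labeled sparse dataset for KLR fitting
#'
#' Bundles a sparse feature matrix with binary labels, feature labels and
#' optional genomic metadata (used by chromosome-sorted cross-validation).
#'
#' @param x Sparse feature matrix (n x m), raw counts or occurrences.
#' @param y Binary labels (0/1), length n.
#' @param feature_labels Character vector of column labels (length m).
#' @param mode `"counts"` (scaled to unit variance at fit time) or
#'   `"occurrence"` (binary, never scaled).
#' @param chrom,start Optional per-row genomic coordinates.
#' @param ids Optional per-row element identifiers.
#' @return An object of class `klr_dataset`.
#' @export
klr_dataset <- function(x, y, feature_labels = NULL,
                        mode = c("counts", "occurrence"),
                        chrom = NULL, start = NULL, ids = NULL) {
  mode <- match.arg(mode)
  x <- methods::as(x, "CsparseMatrix")
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (!is.null(feature_labels)) stopifnot(length(feature_labels) == ncol(x))
  structure(list(x = x, y = y, feature_labels = feature_labels,
                 mode = mode, chrom = chrom, start = start, ids = ids),
            class = "klr_dataset")
}

#' @export
print.klr_dataset <- function(x, ...) {
  cat(sprintf("klr_dataset: n = %d (%d pos / %d neg), m = %d, mode = %s\n",
              nrow(x$x), sum(x$y == 1), sum(x$y == 0), ncol(x$x), x$mode))
  invisible(x)
}

#' Class weights for unbalanced binary data
#'
#' Computes w0 = n / (2 * sum(1 - y)) and w1 = n / (2 * sum(y)), which
#' reweight the two classes so each contributes total mass n/2 to the
#' likelihood.
#'
#' @param y Binary label vector with both classes present.
#' @return Named numeric vector `c(w0 = ..., w1 = ...)`.
#' @examples
#' class_weights(c(1, 1, 1, 0)) # w0 = 2, w1 = 2/3
#' @export
class_weights <- function(y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute class weights")
  n <- n0 + n1
  c(w0 = n / (2 * n0), w1 = n / (2 * n1))
}

#' Penalized objective of the KLR model
#'
#' The quantity minimized during fitting: the class-weighted negative
#' log-likelihood plus lambda times the L1 norm of the non-intercept
#' coefficients (the intercept is never penalized). Log terms are
#' evaluated through numerically stable log-sigmoid identities, so no
#' explicit clamping is required for finite linear predictors.
#'
#' @param theta Numeric vector of length m + 1; `theta[1]` is the
#'   intercept on the constant-1 coordinate.
#' @param dataset A [klr_dataset()] (features used as stored; apply
#'   scaling beforehand if desired).
#' @param lambda Penalty, >= 0.
#' @param weights Optional `c(w0, w1)`; defaults to [class_weights()].
#' @return Scalar objective value (to be minimized).
#' @export
klr_objective <- function(theta, dataset, lambda, weights = NULL) {
  x <- dataset$x; y <- dataset$y
  stopifnot(length(theta) == ncol(x) + 1L, lambda >= 0)
  if (is.null(weights)) weights <- class_weights(y)
  w <- ifelse(y == 1, weights[["w1"]], weights[["w0"]])
  z <- as.numeric(x %*% theta[-1L]) + theta[1L]
  # -log sigma(z) = log1p(exp(-z)); -log(1 - sigma(z)) = log1p(exp(z))
  nll <- sum(w * ifelse(y == 1,
                        -stats::plogis(z, log.p = TRUE),
                        -stats::plogis(-z, log.p = TRUE)))
  nll + lambda * sum(abs(theta[-1L]))
}

# Smallest penalty (sum scale) at which the null model is optimal:
# max_j |gradient_j| at the exact intercept-only optimum, where the
# weighted prevalence is 1/2 and hence the optimal intercept is 0.
klr_lambda_max <- function(x, y, weights) {
  r <- ifelse(y == 1, weights[["w1"]] * (0.5 - 1), weights[["w0"]] * 0.5)
  max(abs(as.numeric(Matrix::crossprod(x, r))))
}

#' Fit KLR at a fixed penalty with just-in-time SAGA
#'
#' Minimizes [klr_objective()] by a proximal stochastic-average-gradient
#' (SAGA) method. The per-sample logistic gradient is a scalar multiple
#' of the sample's feature vector, so the gradient table stores one
#' scalar per sample, and accumulated drift/soft-threshold updates are
#' applied lazily per coordinate; the per-step cost is proportional to
#' the nonzeros of the sampled row. For `lambda >= lambda_max` the exact
#' analytic null model (all coefficients zero, intercept equal to the
#' logit of the weighted prevalence, i.e. 0 under the default class
#' weights) is returned directly, as it satisfies the global optimality
#' conditions.
#'
#' @param dataset A [klr_dataset()]; features are used as stored (apply
#'   scaling beforehand, or use [klr_leapfrog()] which handles scaling).
#' @param lambda Penalty (sum scale), >= 0.
#' @param theta0 Optional warm-start vector of length m + 1.
#' @param opts Solver options from [klr_opts()].
#' @return List with `beta` (length m), `intercept`, `objective`,
#'   `support`, `epochs`, `converged`.
#' @export
klr_fit_lambda <- function(dataset, lambda, theta0 = NULL,
                           opts = klr_opts()) {
  x <- dataset$x; y <- dataset$y
  stopifnot(lambda >= 0)
  wts <- class_weights(y)
  lmax <- klr_lambda_max(x, y, wts)
  if (lambda >= lmax && lambda > 0) {
    wbar <- ifelse(y == 1, wts[["w1"]], wts[["w0"]])
    prev <- sum(wbar * y) / sum(wbar)  # = 1/2 under these weights
    b0 <- stats::qlogis(prev)
    beta <- numeric(ncol(x))
    obj <- klr_objective(c(b0, beta), dataset, lambda, wts)
    return(list(beta = beta, intercept = b0, objective = obj,
                support = 0L, epochs = 0L, converged = TRUE,
                lambda = lambda, analytic_null = TRUE))
  }
  if (is.null(theta0)) theta0 <- numeric(ncol(x) + 1L)
  xt <- if (is.null(dataset$xt)) Matrix::t(x) else dataset$xt
  fit <- saga_fit_cpp(xt, y, wts[["w0"]], wts[["w1"]], lambda,
                      theta0[-1L], theta0[1L],
                      opts$max_epochs, opts$tol, opts$seed,
                      if (is.null(opts$obj_every)) 1L else opts$obj_every)
  if (!fit$converged && isTRUE(opts$warn_nonconverged)) {
    warning(sprintf(
      "SAGA did not reach tolerance %.1e within %d epochs (objective %.6g)",
      opts$tol, opts$max_epochs, fit$objective))
  }
  fit$lambda <- lambda
  fit$analytic_null <- FALSE
  fit
}

#' Solver options
#'
#' @param max_epochs Maximum SAGA epochs per fit (default 200).
#' @param tol Relative objective-change convergence tolerance per epoch
#'   (default 1e-8).
#' @param seed Integer seed for the solver's sampling sequence; the same
#'   seed yields a byte-identical model.
#' @param path_factor Geometric decrease factor of the leapfrog lambda
#'   path (default 0.9).
#' @param max_bisect Bisection budget when a path step overshoots the
#'   target support (default 50).
#' @param path_epochs Epoch cap for the warm-started intermediate fits
#'   along the leapfrog path (default: `max_epochs`). Candidate models
#'   whose support matches the target are always re-verified at the full
#'   `max_epochs`/`tol` before being returned, so a small value speeds
#'   up the path walk without changing the support contract.
#' @param obj_every Compute the objective (and test convergence) every
#'   this many epochs (default 1; 2 roughly halves the bookkeeping cost
#'   of budget-capped fits).
#' @param warn_nonconverged Emit a warning when an individual fit stops
#'   at `max_epochs` without meeting `tol` (default TRUE).
#' @return List of options.
#' @export
klr_opts <- function(max_epochs = 200L, tol = 1e-8, seed = 1L,
                     path_factor = 0.9, max_bisect = 50L,
                     path_epochs = NULL, obj_every = 1L,
                     warn_nonconverged = TRUE) {
  if (is.null(path_epochs)) path_epochs <- max_epochs
  list(max_epochs = as.integer(max_epochs), tol = tol,
       seed = as.integer(seed), path_factor = path_factor,
       max_bisect = as.integer(max_bisect),
       path_epochs = as.integer(path_epochs),
       obj_every = as.integer(obj_every),
       warn_nonconverged = warn_nonconverged)
}

new_klr_model <- function(fit, q_target, scales, feature_labels, mode) {
  nz <- which(fit$beta != 0)
  structure(list(intercept = fit$intercept,
                 beta_index = nz, beta_value = fit$beta[nz],
                 m = length(fit$beta),
                 lambda = fit$lambda, q = length(nz), q_target = q_target,
                 exact_q = length(nz) == q_target,
                 scales = scales, feature_labels = feature_labels,
                 mode = mode, objective = fit$objective,
                 converged = fit$converged),
            class = "klr_model")
}

#' @export
print.klr_model <- function(x, ...) {
  cat(sprintf(
    "klr_model: %d nonzero coefficients (target q = %s), lambda = %.4g\n",
    x$q, x$q_target, x$lambda))
  invisible(x)
}

# dense coefficient vector (length m) of a model
klr_coef <- function(model) {
  b <- numeric(model$m)
  b[model$beta_index] <- model$beta_value
  b
}

#' Leapfrog fit: choose lambda to select a target number of features
#'
#' Walks a decreasing geometric lambda path from `lambda_max` (where the
#' fit is the exact null model) with warm starts, and bisects the
#' bracketing interval whenever a step overshoots the requested support
#' size, until the fitted model has exactly `q` nonzero non-intercept
#' coefficients. If exact `q` is unattainable within the bisection
#' budget (simultaneous feature entry), the model with the largest
#' support not exceeding `q` is returned and flagged via `exact_q`.
#' Count-mode datasets are scaled to unit variance (no centering) before
#' fitting; the scales are stored in the model and applied automatically
#' by [predict.klr_model()].
#'
#' @param dataset A [klr_dataset()] (raw counts or occurrences).
#' @param q Target number of nonzero non-intercept coefficients
#'   (`0 <= q <= m`). `q = 0` returns the intercept-only model.
#' @param opts Solver options, see [klr_opts()].
#' @return A `klr_model`.
#' @export
klr_leapfrog <- function(dataset, q, opts = klr_opts()) {
  models <- klr_leapfrog_multi(dataset, q, opts)
  models[[1L]]
}

#' Leapfrog fits for several targets along one path
#'
#' Fits one decreasing-lambda path and harvests a model for each target
#' support size, reusing warm starts; equivalent to repeated
#' [klr_leapfrog()] calls but cheaper.
#'
#' @inheritParams klr_leapfrog
#' @param q_targets Integer vector of target support sizes.
#' @return List of `klr_model`, in the order of `q_targets`.
#' @export
klr_leapfrog_multi <- function(dataset, q_targets, opts = klr_opts()) {
  x_full <- dataset$x; y <- dataset$y
  m <- ncol(x_full)
  q_targets <- as.integer(q_targets)
  if (any(q_targets < 0L) || any(q_targets > m))
    stop("q targets must lie in [0, m]")
  scales <- rep(1, m)
  if (dataset$mode == "counts") {
    scales <- fit_scales(x_full)
    x_full <- apply_scales(x_full, scales)
  }
  wts <- class_weights(y)
  # gradient screening: only features whose null-model gradient is large
  # can enter the path early; fit on the top-K columns and verify the
  # KKT conditions of the final models on the full matrix, expanding the
  # screen if any excluded feature violates them. Constant columns have
  # exactly zero null gradient under the class weights and are dropped
  # first; they can never enter an l1 path.
  r0 <- ifelse(y == 1, wts[["w1"]] * (0.5 - 1), wts[["w0"]] * 0.5)
  g0 <- abs(as.numeric(Matrix::crossprod(x_full, r0)))
  K <- min(m, max(1000L, 20L * max(q_targets, 1L)))
  keep <- order(g0, decreasing = TRUE)[seq_len(K)]
  keep <- sort(keep[g0[keep] > 0])
  if (!length(keep) && max(q_targets) > 0L)
    stop("no feature has a nonzero null-model gradient; ",
         "positive q targets are unattainable")
  if (!length(keep)) keep <- 1L  # q = 0 only; any column works
  repeat {
    res <- klr_leapfrog_screened(x_full, y, keep, q_targets, wts, scales,
                                 dataset, opts)
    viol <- integer(0)
    for (mdl in res) {
      if (mdl$q == 0L) next
      b <- numeric(m); b[mdl$beta_index] <- mdl$beta_value
      z <- as.numeric(x_full %*% b) + mdl$intercept
      w <- ifelse(y == 1, wts[["w1"]], wts[["w0"]])
      g <- abs(as.numeric(Matrix::crossprod(x_full, w * (stats::plogis(z) - y))))
      viol <- union(viol, setdiff(which(g > mdl$lambda * 1.001), keep))
    }
    if (!length(viol)) return(res)
    keep <- sort(union(keep, viol))
  }
}

klr_leapfrog_screened <- function(x_full, y, keep, q_targets, wts, scales,
                                  dataset, opts) {
  m <- ncol(x_full)
  x <- x_full[, keep, drop = FALSE]
  ds <- klr_dataset(x, y, NULL, mode = "occurrence")
  ds$xt <- Matrix::t(x)  # cached for the many fits along the path
  lmax <- klr_lambda_max(x, y, wts)
  # map a fit on screened columns back to the full feature space
  unscreen <- function(model) {
    model$beta_index <- keep[model$beta_index]
    model$m <- m
    model$scales <- scales
    model$feature_labels <- dataset$feature_labels
    model
  }

  ord <- order(q_targets)
  out <- vector("list", length(q_targets))

  popts <- opts
  popts$max_epochs <- opts$path_epochs
  popts$warn_nonconverged <- FALSE
  # verify a candidate at full accuracy (intermediate path fits may use a
  # reduced epoch budget; the support contract is checked on the
  # fully converged fit)
  verify <- function(f) {
    if (opts$path_epochs >= opts$max_epochs) return(f)
    klr_fit_lambda(ds, f$lambda, theta0 = c(f$intercept, f$beta),
                   opts = opts)
  }

  null_fit <- klr_fit_lambda(ds, lmax, opts = opts)
  # path state
  lam_hi <- lmax; fit_hi <- null_fit           # support <= current target
  theta <- c(null_fit$intercept, null_fit$beta)
  lam <- lmax
  fit <- null_fit
  for (oi in ord) {
    qt <- q_targets[oi]
    if (qt == 0L) {
      out[[oi]] <- unscreen(new_klr_model(null_fit, 0L, NULL, NULL,
                                          dataset$mode))
      next
    }
    # walk down until the support reaches or overshoots the target
    found <- NULL
    while (fit$support < qt) {
      lam_hi <- lam; fit_hi <- fit
      lam <- lam * opts$path_factor
      fit <- klr_fit_lambda(ds, lam, theta0 = theta, opts = popts)
      theta <- c(fit$intercept, fit$beta)
      if (lam < lmax * 1e-12)
        stop("leapfrog path exhausted before reaching the target support")
    }
    # reconcile the (possibly reduced-accuracy) path fit with the full
    # tolerance before deciding: walk further, accept, or bisect
    repeat {
      while (fit$support < qt) {
        lam_hi <- lam; fit_hi <- fit
        lam <- lam * opts$path_factor
        fit <- klr_fit_lambda(ds, lam, theta0 = theta, opts = popts)
        theta <- c(fit$intercept, fit$beta)
        if (lam < lmax * 1e-12)
          stop("leapfrog path exhausted before reaching the target support")
      }
      v <- verify(fit)
      theta <- c(v$intercept, v$beta)
      fit <- v
      if (fit$support == qt) found <- fit
      if (fit$support >= qt) break
    }
    if (is.null(found)) {
      # bisect at full accuracy: lam_lo (support > qt) vs lam_hi (< qt)
      lam_lo <- lam; fit_lo <- fit
      best_under <- NULL
      if (fit_hi$support <= qt) {
        # path-accuracy candidate: re-verify before it can be returned
        fh <- verify(fit_hi)
        if (fh$support <= qt) best_under <- fh
      }
      for (b in seq_len(opts$max_bisect)) {
        mid <- sqrt(lam_lo * lam_hi)  # geometric midpoint
        fmid <- klr_fit_lambda(ds, mid,
                               theta0 = c(fit_lo$intercept, fit_lo$beta),
                               opts = opts)
        if (fmid$support == qt) { found <- fmid; break }
        if (fmid$support > qt) {
          lam_lo <- mid; fit_lo <- fmid
        } else {
          lam_hi <- mid; fit_hi <- fmid
          if (is.null(best_under) || fmid$support > best_under$support)
            best_under <- fmid
        }
      }
      if (is.null(found)) {
        if (is.null(best_under))
          stop("bisection failed to find a support size <= q")
        warning(sprintf(
          "exact support q = %d unattainable; returning nearest below (%d)",
          qt, best_under$support))
        found <- best_under
      }
      # remember the dense end to resume the path for larger targets
      theta <- c(fit_lo$intercept, fit_lo$beta)
      fit <- fit_lo; lam <- lam_lo
    } else if (fit$support <= qt) {
      # resume from the found model itself
      theta <- c(found$intercept, found$beta)
      fit <- found; lam <- found$lambda
    }
    out[[oi]] <- unscreen(new_klr_model(found, qt, NULL, NULL,
                                        dataset$mode))
    # the found model is a valid sparse-end bracket for larger targets;
    # keeping it as lam_hi makes selected lambdas monotone in q
    lam_hi <- found$lambda; fit_hi <- found
  }
  out
}

#' Predict class probabilities
#'
#' Applies the model's stored unit-variance scales to raw feature
#' vectors and returns sigmoid(intercept + x beta). Occurrence-mode
#' models have unit scales, so raw occurrence vectors are used directly.
#'
#' @param object A `klr_model`.
#' @param newdata Feature matrix (sparse or dense, n x m) in raw
#'   count/occurrence space.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.klr_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- Matrix::Matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$m)
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), object$m))
  idx <- object$beta_index
  b <- object$beta_value / object$scales[idx]  # fold scaling into beta
  z <- as.numeric(newdata[, idx, drop = FALSE] %*% b) + object$intercept
  stats::plogis(z)
}

#' Full-batch proximal-gradient reference solver
#'
#' An accelerated (FISTA) proximal-gradient method with backtracking
#' line search for the same objective as [klr_fit_lambda()]. Exact but
#' O(n m) per iteration; intended as an independent reference for
#' verifying the stochastic solver on small problems.
#'
#' @inheritParams klr_fit_lambda
#' @param max_iter Iteration cap.
#' @param tol Relative objective-change stopping tolerance.
#' @return List with `beta`, `intercept`, `objective`, `support`.
#' @export
klr_fit_proxgrad <- function(dataset, lambda, max_iter = 20000L,
                             tol = 1e-12) {
  x <- as.matrix(dataset$x); y <- dataset$y
  wts <- class_weights(y)
  w <- ifelse(y == 1, wts[["w1"]], wts[["w0"]])
  m <- ncol(x)
  fval <- function(th) {
    z <- drop(x %*% th[-1L]) + th[1L]
    sum(w * ifelse(y == 1, -stats::plogis(z, log.p = TRUE),
                   -stats::plogis(-z, log.p = TRUE)))
  }
  grad <- function(th) {
    z <- drop(x %*% th[-1L]) + th[1L]
    r <- w * (stats::plogis(z) - y)
    c(sum(r), drop(crossprod(x, r)))
  }
  prox <- function(th, step) {
    b <- th[-1L]
    c(th[1L], sign(b) * pmax(abs(b) - step * lambda, 0))
  }
  th <- numeric(m + 1L)
  v <- th; tprev <- 1
  L <- max(0.25 * max(w) * (1 + rowSums(x^2)))
  step <- 1 / L
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    g <- grad(v)
    fv <- fval(v)
    repeat {  # backtracking on the smooth part
      th_new <- prox(v - step * g, step)
      d <- th_new - v
      if (fval(th_new) <= fv + sum(g * d) + sum(d^2) / (2 * step) + 1e-12)
        break
      step <- step / 2
    }
    tcur <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    v <- th_new + ((tprev - 1) / tcur) * (th_new - th)
    th <- th_new; tprev <- tcur
    obj <- fval(th) + lambda * sum(abs(th[-1L]))
    if (abs(obj_prev - obj) < tol * max(1, abs(obj))) break
    obj_prev <- obj
  }
  list(beta = th[-1L], intercept = th[1L],
       objective = fval(th) + lambda * sum(abs(th[-1L])),
       support = sum(th[-1L] != 0))
}

#' Serialize / restore a KLR model as JSON
#'
#' Stores the nonzero coefficients keyed by feature label, the
#' intercept, lambda, q, mode and the nonzero-feature scales.
#'
#' @param model A `klr_model` (requires feature labels).
#' @param file Path to write to / read from.
#' @return `model_to_json` returns `file` invisibly; `model_from_json`
#'   returns a `klr_model`. Restored models keep scale 1 for features
#'   with zero coefficients (which cannot affect predictions).
#' @export
model_to_json <- function(model, file) {
  stopifnot(!is.null(model$feature_labels))
  obj <- list(
    intercept = model$intercept,
    coefficients = setNames(as.list(model$beta_value),
                            model$feature_labels[model$beta_index]),
    scales = setNames(as.list(model$scales[model$beta_index]),
                      model$feature_labels[model$beta_index]),
    lambda = model$lambda, q = model$q, q_target = model$q_target,
    exact_q = model$exact_q, mode = model$mode, m = model$m,
    feature_space = "by-label")
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname model_to_json
#' @param feature_labels Full ordered label vector of the feature space
#'   the model is to be used with.
#' @export
model_from_json <- function(file, feature_labels) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  idx <- match(names(obj$coefficients), feature_labels)
  if (anyNA(idx)) stop("model contains labels absent from feature space")
  m <- length(feature_labels)
  scales <- rep(1, m)
  scales[idx] <- as.numeric(obj$scales)
  structure(list(intercept = obj$intercept,
                 beta_index = idx,
                 beta_value = as.numeric(obj$coefficients),
                 m = m, lambda = obj$lambda, q = obj$q,
                 q_target = obj$q_target, exact_q = obj$exact_q,
                 scales = scales, feature_labels = feature_labels,
                 mode = obj$mode, objective = NA_real_, converged = NA),
            class = "klr_model")
}
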