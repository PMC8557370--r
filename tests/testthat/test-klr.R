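# Class-weighted L1 logistic regression: weights, objective, solvers,
# leapfrog feature-count targeting, prediction.

test_that("class weights follow n/(2*class size) and balance the mass", {
  expect_equal(class_weights(c(1, 1, 0, 0)), c(w0 = 1, w1 = 1))
  w <- class_weights(c(1, 1, 1, 0))
  expect_equal(w, c(w0 = 2, w1 = 2 / 3))
  expect_error(class_weights(c(1, 1)), "both classes")
  set.seed(5)
  for (i in 1:10) {
    y <- rbinom(30, 1, 0.3)
    if (length(unique(y)) < 2) next
    w <- class_weights(y)
    expect_equal(w[["w1"]] * sum(y), length(y) / 2)
    expect_equal(w[["w0"]] * sum(1 - y), length(y) / 2)
  }
})

test_that("objective at zero equals n*log(2) and the penalty skips the intercept", {
  ds <- toy_instance(1)
  n <- length(ds$y); m <- ncol(ds$x)
  expect_equal(klr_objective(numeric(m + 1), ds, 0), n * log(2))
  # lambda irrelevant for an intercept-only theta
  th <- c(0.7, numeric(m))
  expect_equal(klr_objective(th, ds, 0), klr_objective(th, ds, lambda = 100))
  # lambda = 0 reduces to the plain weighted NLL
  th2 <- c(0.1, rnorm(m, sd = 0.2))
  expect_equal(klr_objective(th2, ds, 2),
               klr_objective(th2, ds, 0) + 2 * sum(abs(th2[-1])))
})

test_that("large-lambda fits return the exact null model with intercept 0", {
  ds <- toy_instance(2, unbalanced = TRUE)
  f <- klr_fit_lambda(ds, 1e6)
  expect_identical(f$support, 0L)
  expect_identical(f$intercept, 0)  # sigma(0) = weighted prevalence 1/2
  expect_true(all(f$beta == 0))
  # multiplying lambda by 10 does not move the intercept of the null fit
  f2 <- klr_fit_lambda(ds, 1e7)
  expect_identical(f2$intercept, f$intercept)
})

test_that("SAGA matches a weighted glm at lambda = 0", {
  for (seed in 1:5) {
    ds <- toy_instance(seed, n = 50, m = 6, unbalanced = seed %% 2 == 0,
                       flip = 0.2)
    f <- klr_fit_lambda(ds, 0, opts = klr_opts(max_epochs = 30000,
                                               tol = 0,
                                               warn_nonconverged = FALSE))
    w <- class_weights(ds$y)
    wv <- ifelse(ds$y == 1, w[["w1"]], w[["w0"]])
    g <- suppressWarnings(
      glm.fit(cbind(1, as.matrix(ds$x)), ds$y, weights = wv,
              family = binomial(),
              control = glm.control(epsilon = 1e-14)))
    expect_lt(max(abs(c(f$intercept, f$beta) - g$coefficients) /
                    pmax(abs(g$coefficients), 1e-3)), 1e-4)
  }
})

test_that("SAGA reaches the full-batch proximal-gradient objective", {
  gaps <- numeric(0)
  for (seed in 1:20) {
    set.seed(seed + 100)
    ds <- toy_instance(seed, n = sample(15:50, 1), m = sample(5:30, 1))
    lambda <- runif(1, 0.2, 4)
    f <- klr_fit_lambda(ds, lambda,
                        opts = klr_opts(max_epochs = 100000, tol = 0,
                                        warn_nonconverged = FALSE))
    o <- klr_fit_proxgrad(ds, lambda, max_iter = 400000L, tol = 1e-16)
    gaps <- c(gaps, f$objective - o$objective)
    expect_identical(which(f$beta != 0), which(o$beta != 0))
  }
  expect_lt(max(abs(gaps)), 1e-6)
})

test_that("identical solver seeds give identical models", {
  ds <- toy_instance(9, n = 40, m = 12)
  m1 <- klr_leapfrog(ds, 4L, klr_opts(seed = 42))
  m2 <- klr_leapfrog(ds, 4L, klr_opts(seed = 42))
  expect_identical(m1, m2)
  m3 <- klr_leapfrog(ds, 4L, klr_opts(seed = 43))
  expect_false(identical(m3$beta_value, m1$beta_value))
})

test_that("leapfrog hits the requested support size and q=0 is intercept-only", {
  ds <- toy_instance(4, n = 60, m = 20)
  for (q in c(0L, 2L, 5L, 10L)) {
    mdl <- klr_leapfrog(ds, q)
    expect_identical(mdl$q, q)
    expect_true(mdl$exact_q)
  }
  expect_identical(klr_leapfrog(ds, 0L)$intercept, 0)
  expect_error(klr_leapfrog(ds, ncol(ds$x) + 1L), "must lie in")
})

test_that("selected lambda decreases as the target support grows", {
  ds <- toy_instance(6, n = 60, m = 25)
  mods <- klr_leapfrog_multi(ds, c(3L, 8L, 15L))
  lams <- vapply(mods, `[[`, 0, "lambda")
  expect_true(all(diff(lams) < 0))
  # multi-target harvesting equals individual fits in support
  expect_equal(vapply(mods, `[[`, 0L, "q"), c(3L, 8L, 15L))
})

test_that("predictions apply stored scales and respect sigmoid identities", {
  set.seed(21)
  x <- Matrix::Matrix(rpois(60 * 10, 2), 60, 10, sparse = TRUE)
  y <- rbinom(60, 1, plogis(as.numeric(x[, 1]) - 2))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  ds <- klr_dataset(x, y, mode = "counts")
  mdl <- klr_leapfrog(ds, 3L)
  # scaling equivalence: raw vectors vs pre-scaled vectors + unit scales
  p_raw <- predict(mdl, x)
  xs <- apply_scales(x, mdl$scales)
  mdl_unit <- mdl; mdl_unit$scales <- rep(1, ncol(x))
  expect_equal(predict(mdl_unit, xs), p_raw)
  expect_true(all(p_raw > 0 & p_raw < 1))
  # negating theta complements the probability
  mdl_neg <- mdl
  mdl_neg$beta_value <- -mdl$beta_value
  mdl_neg$intercept <- -mdl$intercept
  expect_equal(predict(mdl_neg, x), 1 - p_raw)
  # monotone in a positive-coefficient feature
  jpos <- mdl$beta_index[which.max(mdl$beta_value)]
  if (length(jpos) && max(mdl$beta_value) > 0) {
    x2 <- x; x2[, jpos] <- x2[, jpos] + 1
    expect_true(all(predict(mdl, x2) >= p_raw - 1e-12))
  }
  # zero-coefficient model with intercept 0 predicts 0.5 everywhere
  null_m <- klr_leapfrog(ds, 0L)
  expect_equal(predict(null_m, x), rep(0.5, nrow(x)))
  expect_error(predict(mdl, x[, 1:3]), "columns")
})

test_that("models round-trip through JSON", {
  ds <- toy_instance(8, n = 40, m = 10)
  ds$feature_labels <- sprintf("f%02d", 1:10)
  mdl <- klr_leapfrog(ds, 4L)
  f <- tempfile(fileext = ".json")
  model_to_json(mdl, f)
  mdl2 <- model_from_json(f, ds$feature_labels)
  expect_equal(mdl2$beta_value, mdl$beta_value)
  expect_equal(mdl2$beta_index, mdl$beta_index)
  expect_equal(mdl2$intercept, mdl$intercept)
  expect_equal(predict(mdl2, ds$x), predict(mdl, ds$x))
  unlink(f)
})
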