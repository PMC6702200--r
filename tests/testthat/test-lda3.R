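# Cost matrices, discriminant fitting, posteriors, decisions, serialization.

sim_gauss3 <- function(n_per = c(30, 60, 30), p = 4, sep = 1.5, seed = 1) {
  set.seed(seed)
  mus <- rbind(rep(0, p), rep(sep, p), rep(2 * sep, p))
  X <- do.call(rbind, lapply(1:3, function(k)
    matrix(rnorm(n_per[k] * p, mus[k, ]), n_per[k], p)))
  colnames(X) <- paste0("f", seq_len(p))
  y <- rep(vulnerability_levels(), n_per)
  list(X = X, y = y)
}

test_that("the scalar cost family has the documented structure", {
  C1 <- make_cost_matrix(1)
  expect_true(all(diag(C1) == 0))
  expect_true(all(C1[row(C1) != col(C1)] == 1))
  C3 <- make_cost_matrix(3)
  expect_equal(unname(C3["resilient", "vulnerable"]), 3)
  expect_equal(unname(C3["vulnerable", "resilient"]), 3)
  expect_equal(unname(C3["intermediate", "resilient"]), 1)
  expect_equal(attr(C3, "scalar"), 3)
  expect_error(make_cost_matrix(0.9), "cost scalar")
  expect_equal(cost_grid_default(), seq(1, 5, 0.5))
  bad <- diag(3)
  expect_error(pvtvuln:::check_cost_matrix(bad), "zero diagonal")
})

test_that("the expected-cost rule reproduces a hand-computed decision", {
  post <- matrix(c(0.30, 0.36, 0.34), 1)
  # at cost scalar 3 the risks are (1.38, 1.92, 1.26): vulnerable wins
  risk <- post %*% make_cost_matrix(3)
  expect_equal(unname(drop(risk)), c(1.38, 1.92, 1.26))
  expect_identical(pvtvuln:::decide_cost(post, make_cost_matrix(3)), 3L)
  # at cost 1 the same posterior picks the argmax class (intermediate)
  expect_identical(pvtvuln:::decide_cost(post, make_cost_matrix(1)), 2L)
  # exact ties resolve to the least vulnerable class
  tie <- matrix(rep(1 / 3, 3), 1)
  expect_identical(pvtvuln:::decide_cost(tie, make_cost_matrix(1)), 1L)
})

test_that("uniform cost is equivalent to the maximum-posterior rule", {
  set.seed(11)
  e <- matrix(rexp(3000), ncol = 3)
  post <- e / rowSums(e)
  got <- pvtvuln:::decide_cost(post, make_cost_matrix(1))
  expect_identical(got, as.integer(max.col(post, ties.method = "first")))
})

test_that("posteriors match an explicit Gaussian density computation", {
  d <- sim_gauss3(seed = 12)
  fit <- lda3(d$X, d$y)
  # independent route: z-score, per-class means, pooled covariance via
  # stats::cov, mahalanobis densities, normalize
  Z <- scale(d$X, center = fit$mu, scale = fit$sigma)
  yk <- as.integer(factor(d$y, levels = vulnerability_levels()))
  m <- t(sapply(1:3, function(k) colMeans(Z[yk == k, , drop = FALSE])))
  S <- Reduce(`+`, lapply(1:3, function(k)
    (sum(yk == k) - 1) * stats::cov(Z[yk == k, , drop = FALSE]))) /
    (length(yk) - 3)
  logd <- sapply(1:3, function(k)
    -0.5 * stats::mahalanobis(Z, m[k, ], S) + log(mean(yk == k)))
  want <- exp(logd - apply(logd, 1, max))
  want <- want / rowSums(want)
  got <- posterior(fit, d$X)
  expect_lt(max(abs(got - unname(want))), 1e-9)
  expect_equal(unname(rowSums(got)), rep(1, nrow(d$X)), tolerance = 1e-12)
})

test_that("fitting is invariant to affine feature rescaling", {
  d <- sim_gauss3(seed = 13)
  f1 <- lda3(d$X, d$y, cost = 2)
  X2 <- sweep(sweep(d$X, 2, c(10, 0.1, 5, 2), "*"), 2, c(1, -3, 0, 7), "+")
  f2 <- lda3(X2, d$y, cost = 2)
  p1 <- predict(f1, d$X)
  p2 <- predict(f2, X2)
  expect_lt(max(abs(p1$posterior - p2$posterior)), 1e-9)
  expect_identical(p1$class, p2$class)
})

test_that("identical class distributions give prior posteriors", {
  set.seed(14)
  X <- matrix(rnorm(240), 120, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(vulnerability_levels(), c(30, 60, 30))
  fit <- lda3(X, y, priors = c(0.25, 0.5, 0.25))
  # class means estimated from pure noise are near 0: posteriors near priors
  p <- posterior(fit, matrix(0, 1, 2, dimnames = list(NULL, c("a", "b"))))
  expect_equal(unname(drop(p)), c(0.25, 0.5, 0.25), tolerance = 0.1)
})

test_that("a prior-only model predicts from the priors alone", {
  X <- matrix(numeric(0), nrow = 8, ncol = 0)
  y <- rep(vulnerability_levels(), c(2, 4, 2))
  fit <- lda3(X, y)
  p <- predict(fit, matrix(numeric(0), nrow = 3, ncol = 0))
  expect_equal(unname(p$posterior),
               matrix(rep(c(0.25, 0.5, 0.25), each = 3), 3))
  expect_true(all(p$class == "intermediate"))
  expect_identical(rownames(coef(fit)), "(const)")
})

test_that("training labels are classified well in a separable problem", {
  d <- sim_gauss3(sep = 3, seed = 15)
  fit <- lda3(d$X, d$y)
  expect_gt(mean(predict(fit, d$X, type = "class") == d$y), 0.95)
  expect_output(print(fit), "Three-class linear discriminant")
  expect_identical(dim(coef(fit)), c(5L, 3L))
})

test_that("posteriors agree with the reference implementation in MASS", {
  d <- sim_gauss3(seed = 16)
  fit <- lda3(d$X, d$y)
  ref <- MASS::lda(d$X, grouping = factor(d$y, vulnerability_levels()))
  ref_post <- predict(ref, d$X)$posterior
  expect_lt(max(abs(posterior(fit, d$X) - unname(ref_post))), 1e-6)
})

test_that("singular covariances fall back to the shrinkage ladder", {
  d <- sim_gauss3(seed = 17)
  X <- cbind(d$X, dup = d$X[, 1])   # exactly collinear
  expect_warning(fit <- lda3(X, d$y), "shrinkage raised")
  expect_gt(fit$shrinkage, 0)
  p <- predict(fit, X)
  expect_false(anyNA(p$posterior))
  # constant columns are tolerated via unit scale
  Xc <- cbind(d$X, flat = 1)
  expect_silent(fit2 <- lda3(Xc, d$y, shrinkage = 0.1))
  expect_false(anyNA(posterior(fit2, Xc)))
  expect_error(lda3(d$X, d$y, shrinkage = 2), "shrinkage")
})

test_that("rows with missing features yield NA predictions with a warning", {
  d <- sim_gauss3(seed = 18)
  fit <- lda3(d$X, d$y)
  nd <- d$X[1:4, ]
  nd[2, 3] <- NA
  expect_warning(p <- predict(fit, nd), "missing feature")
  expect_true(is.na(p$class[2]))
  expect_false(anyNA(p$class[-2]))
  expect_error(predict(fit, d$X[, 1:2]), "lacks feature columns")
})

test_that("JSON serialization round-trips to identical predictions", {
  d <- sim_gauss3(seed = 19)
  fit <- lda3(d$X, d$y, cost = 2.5)
  path <- tempfile(fileext = ".json")
  lda3_to_json(fit, path)
  back <- lda3_from_json(path)
  p1 <- predict(fit, d$X)
  p2 <- predict(back, d$X)
  expect_identical(p1$class, p2$class)
  expect_lt(max(abs(p1$posterior - p2$posterior)), 1e-12)
  expect_equal(attr(back$cost, "scalar"), 2.5)
})

test_that("class membership requirements are enforced", {
  X <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(lda3(X, c("resilient", "resilient", "intermediate",
                         "vulnerable")),
               "at least 2")
  expect_error(lda3(X, c("resilient", "hero", "intermediate", "vulnerable")),
               "unknown vulnerability labels")
})
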