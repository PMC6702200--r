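# Cost-sensitive three-class linear discriminant classifier. Features are
# z-scored with training-set parameters; each class k has a discriminant
# g_k = w_k z' + c_k with w_k = S^-1 m_k and
# c_k = -1/2 m_k' S^-1 m_k + log(prior_k), where S is the pooled
# within-class covariance (optionally shrunk toward its diagonal) and m_k the
# class mean in z-space. The softmax of (g_R, g_I, g_V) is the posterior;
# decisions minimize expected misclassification cost, which reduces to the
# highest-posterior (equivalently highest-discriminant) rule under a uniform
# cost matrix.

#' Build a scalar-generated cost matrix
#'
#' The cost family is generated by one scalar `c`: misclassifying an extreme
#' class (resilient or vulnerable) costs `c`, misclassifying an intermediate
#' participant costs 1, and correct classification costs 0. The grid used in
#' model search is `c = 1, 1.5, ..., 5`. Any bespoke 3x3 matrix with zero
#' diagonal and non-negative off-diagonal entries is also accepted wherever a
#' cost matrix is expected.
#'
#' @param c cost scalar, `c >= 1`.
#' @return A 3x3 matrix `C[true, predicted]` with dimnames in the canonical
#'   class order and attribute `"scalar"` recording `c`.
#' @export
make_cost_matrix <- function(c = 1) {
  assert_that(is.numeric(c) && length(c) == 1 && c >= 1,
              "cost scalar must be a single number >= 1")
  # rows index the true class, columns the predicted class: misclassified
  # extreme classes cost c, misclassified intermediates cost 1
  C <- matrix(0, 3, 3, dimnames = list(true = .classes, predicted = .classes))
  C["resilient", c("intermediate", "vulnerable")] <- c
  C["intermediate", c("resilient", "vulnerable")] <- 1
  C["vulnerable", c("resilient", "intermediate")] <- c
  attr(C, "scalar") <- c
  C
}

#' The default cost-scalar grid
#'
#' @return `seq(1, 5, by = 0.5)` (9 values).
#' @export
cost_grid_default <- function() seq(1, 5, by = 0.5)

# validate an arbitrary cost matrix
check_cost_matrix <- function(C) {
  assert_that(is.matrix(C) && all(dim(C) == c(3, 3)),
              "cost matrix must be 3x3")
  assert_that(all(diag(C) == 0), "cost matrix must have a zero diagonal")
  assert_that(all(C >= 0), "cost matrix entries must be non-negative")
  C
}

# ---- internal core (no S3 overhead; used heavily inside cross-validation) --

# X: numeric matrix (n x p, p may be 0); y: integer class codes 1..3.
# Returns minimal model list or NULL when a class has < 1 member.
lda3_core <- function(X, y, shrinkage = 0, priors = NULL) {
  n <- length(y)
  counts <- tabulate(y, 3)
  if (is.null(priors)) priors <- counts / n
  p <- ncol(X)
  if (p == 0) {
    return(list(p = 0L, mu = numeric(0), sigma = numeric(0),
                w = matrix(0, 0, 3), const = log(priors), priors = priors,
                shrinkage = shrinkage, counts = counts))
  }
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  if (any(sigma == 0)) sigma[sigma == 0] <- 1 # constant column: centred to 0
  Z <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  m <- matrix(0, 3, p)
  S <- matrix(0, p, p)
  for (k in 1:3) {
    Zk <- Z[y == k, , drop = FALSE]
    m[k, ] <- colMeans(Zk)
    S <- S + crossprod(sweep(Zk, 2, m[k, ]))
  }
  S <- S / (n - 3)
  # a feature constant within every class leaves a zero row/column that no
  # diagonal shrinkage can repair; give it unit variance (its z-scores are
  # all 0, so it contributes nothing either way)
  flat <- which(diag(S) == 0)
  if (length(flat) > 0) {
    S[flat, ] <- 0
    S[, flat] <- 0
    S[cbind(flat, flat)] <- 1
  }
  ladder <- sort(unique(c(shrinkage, 0.1, 0.5, 1)))
  ladder <- ladder[ladder >= shrinkage]
  Sinv <- NULL
  used <- shrinkage
  for (lam in ladder) {
    Ss <- (1 - lam) * S + lam * diag(diag(S), p)
    Sinv <- tryCatch(solve(Ss), error = function(e) NULL)
    if (!is.null(Sinv)) { used <- lam; break }
  }
  if (is.null(Sinv)) stop("pooled covariance is singular even at shrinkage 1")
  w <- Sinv %*% t(m)                        # p x 3
  const <- -0.5 * colSums(t(m) * w) + log(priors)
  list(p = p, mu = mu, sigma = sigma, w = w, const = const, priors = priors,
       shrinkage = used, counts = counts)
}

# discriminant scores g (n x 3) for raw feature matrix X
lda3_scores <- function(core, X) {
  n <- nrow(X)
  if (core$p == 0) {
    return(matrix(core$const, n, 3, byrow = TRUE))
  }
  Z <- sweep(sweep(X, 2, core$mu), 2, core$sigma, "/")
  sweep(Z %*% core$w, 2, core$const, "+")
}

# softmax rows
softmax_rows <- function(g) {
  g <- g - apply(g, 1, max)
  e <- exp(g)
  e / rowSums(e)
}

# expected-cost decision: integer codes 1..3; ties -> lowest class code
decide_cost <- function(post, cost) {
  risk <- post %*% cost
  apply(risk, 1, which.min)
}

# ---- public S3 interface ---------------------------------------------------

#' Fit a cost-sensitive three-class linear discriminant model
#'
#' @param x numeric matrix or data.frame of features (participants in rows).
#' @param grouping vulnerability labels (character or factor with levels
#'   resilient, intermediate, vulnerable); at least 2 members per class.
#' @param cost a cost matrix from [make_cost_matrix()], a bespoke 3x3 matrix,
#'   or a cost scalar.
#' @param shrinkage regularization intensity in `[0, 1]`: the pooled
#'   covariance is replaced by `(1 - shrinkage) * S + shrinkage * diag(S)`.
#'   If the covariance is singular the shrinkage is raised along the ladder
#'   0, 0.1, 0.5, 1 with a warning.
#' @param priors class prior probabilities (default: empirical frequencies).
#' @return An object of class `lda3` with components `features` (column
#'   names), `mu`, `sigma` (z-score parameters), `w` (p x 3 class weights),
#'   `const` (class constants), `priors`, `cost`, `shrinkage`, `counts`.
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(40, 2), 20),
#'            matrix(rnorm(20, 4), 10))
#' colnames(x) <- c("f1", "f2")
#' y <- rep(c("resilient", "intermediate", "vulnerable"), c(10, 20, 10))
#' fit <- lda3(x, y)
#' predict(fit, x)$class[1:5]
#' @export
lda3 <- function(x, grouping, cost = make_cost_matrix(1), shrinkage = 0,
                 priors = NULL) {
  X <- as.matrix(x)
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  storage.mode(X) <- "double"
  y <- as.integer(as_vuln_factor(grouping))
  assert_that(nrow(X) == length(y), "x and grouping lengths differ")
  assert_that(all(tabulate(y, 3) >= 2),
              "each class needs at least 2 participants")
  if (is.numeric(cost) && !is.matrix(cost)) cost <- make_cost_matrix(cost)
  check_cost_matrix(cost)
  assert_that(shrinkage >= 0 && shrinkage <= 1,
              "shrinkage must lie in [0, 1]")
  core <- lda3_core(X, y, shrinkage = shrinkage, priors = priors)
  if (core$shrinkage != shrinkage) {
    warning(sprintf("singular pooled covariance; shrinkage raised to %g",
                    core$shrinkage), call. = FALSE)
  }
  structure(
    c(list(features = colnames(X), cost = cost), core),
    class = "lda3"
  )
}

#' Predict from a fitted three-class discriminant model
#'
#' @param object an [lda3()] fit.
#' @param newdata matrix or data.frame containing the model's feature
#'   columns. Rows with missing feature values yield `NA` predictions.
#' @param type `"class"` for labels only (the default returns both).
#' @param ... unused.
#' @return A list with `class` (factor; expected-cost-minimizing label),
#'   `posterior` (n x 3 matrix) and `scores` (discriminant values g).
#' @export
predict.lda3 <- function(object, newdata, type = c("all", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (object$p > 0) {
    if (!is.null(colnames(X))) {
      missing_cols <- setdiff(object$features, colnames(X))
      if (length(missing_cols) > 0) {
        stop("newdata lacks feature columns: ",
             paste(missing_cols, collapse = ", "))
      }
      X <- X[, object$features, drop = FALSE]
    } else {
      assert_that(ncol(X) == object$p, "newdata has the wrong width")
    }
  }
  complete <- if (object$p > 0) stats::complete.cases(X) else
    rep(TRUE, nrow(X))
  g <- matrix(NA_real_, nrow(X), 3,
              dimnames = list(rownames(X), .classes))
  post <- g
  cls <- rep(NA_integer_, nrow(X))
  if (any(complete)) {
    gs <- lda3_scores(object, X[complete, , drop = FALSE])
    ps <- softmax_rows(gs)
    g[complete, ] <- gs
    post[complete, ] <- ps
    cls[complete] <- decide_cost(ps, object$cost)
  }
  if (any(!complete)) {
    warning(sum(!complete),
            " row(s) with missing feature values yield NA predictions",
            call. = FALSE)
  }
  out <- list(class = factor(.classes[cls], levels = .classes),
              posterior = post, scores = g)
  if (type == "class") out$class else out
}

#' Posterior class probabilities
#'
#' Softmax of the three discriminant values; invariant to adding a constant
#' to every discriminant and summing to 1 by construction.
#'
#' @param object an [lda3()] fit.
#' @param newdata feature matrix or data.frame.
#' @return n x 3 matrix of posterior probabilities.
#' @export
posterior <- function(object, newdata) UseMethod("posterior")

#' @export
posterior.lda3 <- function(object, newdata) {
  predict(object, newdata)$posterior
}

#' @export
print.lda3 <- function(x, ...) {
  cat("Three-class linear discriminant model\n")
  cat(sprintf("  features: %s\n",
              if (x$p == 0) "(none: prior-only model)"
              else paste(x$features, collapse = ", ")))
  cat(sprintf("  class counts: R=%d I=%d V=%d; priors: %s\n",
              x$counts[1], x$counts[2], x$counts[3],
              paste(sprintf("%.3f", x$priors), collapse = "/")))
  cat(sprintf("  cost scalar: %s; shrinkage: %g\n",
              if (is.null(attr(x$cost, "scalar"))) "(custom matrix)"
              else format(attr(x$cost, "scalar")), x$shrinkage))
  invisible(x)
}

#' @export
coef.lda3 <- function(object, ...) {
  if (object$p == 0) {
    return(matrix(object$const, 1, 3,
                  dimnames = list("(const)", .classes)))
  }
  rbind(object$w, `(const)` = object$const)
}

#' Serialize a fitted model to JSON
#'
#' Stores the selected feature names, z-score parameters, class weights and
#' constants, priors, cost matrix and shrinkage so that a round-trip via
#' [lda3_from_json()] reproduces identical predictions.
#'
#' @param object an [lda3()] fit.
#' @param path JSON file path.
#' @export
lda3_to_json <- function(object, path) {
  jsonlite::write_json(
    list(features = object$features, mu = object$mu, sigma = object$sigma,
         w = object$w, const = object$const, priors = object$priors,
         cost = unclass(object$cost), cost_scalar = attr(object$cost, "scalar"),
         shrinkage = object$shrinkage, counts = object$counts,
         p = object$p),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname lda3_to_json
#' @export
lda3_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cost <- matrix(unlist(x$cost), 3, 3,
                 dimnames = list(true = .classes, predicted = .classes))
  if (!is.null(x$cost_scalar)) attr(cost, "scalar") <- x$cost_scalar
  w <- matrix(unlist(x$w), ncol = 3)
  structure(
    list(features = as.character(x$features), cost = cost, p = as.integer(x$p),
         mu = as.numeric(x$mu), sigma = as.numeric(x$sigma), w = w,
         const = as.numeric(x$const), priors = as.numeric(x$priors),
         shrinkage = x$shrinkage, counts = as.integer(x$counts)),
    class = "lda3"
  )
}
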