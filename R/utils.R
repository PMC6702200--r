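# Internal helpers shared across modules.

# Canonical class order used for labels, tie-breaking and confusion matrices.
.classes <- c("resilient", "intermediate", "vulnerable")

#' Vulnerability class levels
#'
#' Returns the canonical ordered set of vulnerability labels used throughout
#' the package: `"resilient"`, `"intermediate"`, `"vulnerable"`. This order is
#' also the deterministic tie-break order wherever ties can occur (equal
#' posterior probabilities, equal expected costs, modal-assignment ties).
#'
#' @return Character vector of length 3.
#' @export
vulnerability_levels <- function() .classes

# Coerce labels to a factor with the canonical level order, validating values.
as_vuln_factor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels[!is.na(labels)]), .classes)
  if (length(bad) > 0) {
    stop("unknown vulnerability labels: ", paste(bad, collapse = ", "))
  }
  factor(labels, levels = .classes)
}

# Deterministic seed-stream splitting. All stochastic stages derive their
# seeds from a single master seed via this integer mix so that, e.g., each
# participant x session pair gets its own reproducible stream regardless of
# evaluation order. Arithmetic stays within 2^31 - 1.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Run an expression under a local RNG state seeded from `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# stopifnot-style check with a readable message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
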