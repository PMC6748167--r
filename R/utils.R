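#' Clamp proportions away from the unit-interval boundary
#'
#' The beta likelihood is undefined at exactly 0 or 1, so observed beta
#' values are nudged into the open interval before model fitting.
#'
#' @param y Numeric vector of proportions in `[0, 1]` (`NA` allowed).
#' @param epsilon Half-width of the exclusion zone; must lie in `(0, 0.5)`.
#' @return `y` with every value clamped to `[epsilon, 1 - epsilon]`.
#'   Idempotent: `squeeze(squeeze(y)) == squeeze(y)`.
#' @examples
#' squeeze(c(0, 0.5, 1))
#' @export
squeeze <- function(y, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      !is.finite(epsilon) || epsilon <= 0 || epsilon >= 0.5) {
    stop("`epsilon` must be a single number in (0, 0.5)", call. = FALSE)
  }
  pmin(pmax(y, epsilon), 1 - epsilon)
}

# Gauss-Hermite nodes/weights for weight function exp(-z^2).
gh_rule <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  gh <- pracma::gaussHermite(as.integer(n))
  list(nodes = gh$x, weights = gh$w)
}

# Internal: stop with a structural-error class used across modules.
stop_structural <- function(...) {
  stop(structure(class = c("dualmark_structural_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_input <- function(...) {
  stop(structure(class = c("dualmark_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Check two matrices share dimnames; used by matrix-level operations.
check_aligned <- function(a, b, what_a = "first", what_b = "second") {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    bad_rows <- union(setdiff(rownames(a), rownames(b)),
                      setdiff(rownames(b), rownames(a)))
    bad_cols <- union(setdiff(colnames(a), colnames(b)),
                      setdiff(colnames(b), colnames(a)))
    stop_structural(
      "matrices are not aligned (", what_a, " vs ", what_b, "); ",
      "offending probes: ", paste(utils::head(bad_rows, 5), collapse = ", "),
      "; offending samples: ", paste(utils::head(bad_cols, 5), collapse = ", "))
  }
  invisible(TRUE)
}
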