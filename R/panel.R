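#' Ordinal multitask panel
#'
#' Container for the observed data of the multitask ordinal probit model:
#' \code{n} patients, each with \code{J} ordinal ratings (tasks) on a common
#' \code{1..R} scale, and a length-\code{p} covariate vector.  In the drug
#' review application the covariates are identical across tasks; a per-task
#' covariate array is also accepted so the structure permits task-specific
#' designs.
#'
#' @param y integer matrix, \code{n x J}, ratings in \code{1..R}.
#' @param x numeric matrix \code{n x p} (covariates shared across tasks) or a
#'   numeric array \code{n x p x J} (task-specific covariates).
#' @param R number of ordinal levels; defaults to \code{max(y)} but should be
#'   given explicitly when the top category may be unobserved.
#' @param patient_ids identifiers used for patient-level resampling; defaults
#'   to \code{1:n}.
#' @return an object of class \code{"ordinal_panel"}: a list with elements
#'   \code{y}, \code{x}, \code{n}, \code{J}, \code{R}, \code{p},
#'   \code{patient_ids}, \code{x_names}, \code{shared_x}.
#' @examples
#' y <- cbind(c(1, 3, 5), c(2, 3, 4))
#' x <- cbind(a = c(0.1, -0.2, 0.5), b = c(1, 0, 1))
#' pan <- ordinal_panel(y, x, R = 5)
#' pan$J
#' @export
ordinal_panel <- function(y, x, R = max(y), patient_ids = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  n <- nrow(y)
  J <- ncol(y)
  if (J < 1L || n < 1L) stop("panel must have n >= 1 patients and J >= 1 tasks")
  if (R < 2L) stop("R must be at least 2")
  if (anyNA(y) || any(y < 1L) || any(y > R))
    stop("all ratings must lie in 1..R with no missing values")

  shared_x <- !(is.array(x) && length(dim(x)) == 3L)
  if (shared_x) {
    x <- as.matrix(x)
    if (nrow(x) != n) stop("x must have one row per patient")
    p <- ncol(x)
    x_names <- colnames(x)
  } else {
    if (dim(x)[1] != n || dim(x)[3] != J)
      stop("task-specific x must be an n x p x J array")
    p <- dim(x)[2]
    x_names <- dimnames(x)[[2]]
  }
  if (p < 1L) stop("panel needs at least one covariate")
  if (!all(is.finite(x))) stop("covariates must be finite")
  if (is.null(x_names)) x_names <- paste0("x", seq_len(p))

  if (is.null(patient_ids)) patient_ids <- seq_len(n)
  if (length(patient_ids) != n) stop("patient_ids must have length n")

  structure(
    list(y = y, x = x, n = n, J = J, R = as.integer(R), p = p,
         patient_ids = patient_ids, x_names = x_names, shared_x = shared_x),
    class = "ordinal_panel")
}

#' @export
print.ordinal_panel <- function(x, ...) {
  cat(sprintf("Ordinal panel: n = %d patients, J = %d tasks, R = %d levels, p = %d covariates\n",
              x$n, x$J, x$R, x$p))
  tab <- table(factor(x$y, levels = seq_len(x$R)))
  cat("Pooled rating counts:", paste(sprintf("%d:%d", seq_len(x$R), tab), collapse = "  "), "\n")
  invisible(x)
}

# covariate matrix for task j (n x p), regardless of storage form
panel_x <- function(panel, j) {
  if (panel$shared_x) panel$x else panel$x[, , j, drop = FALSE][, , 1]
}

#' Subset a panel by patient
#'
#' @param panel an \code{ordinal_panel}.
#' @param idx integer row indices of the patients to keep.
#' @return a new \code{ordinal_panel} with the selected patients.
#' @export
panel_subset <- function(panel, idx) {
  x <- if (panel$shared_x) panel$x[idx, , drop = FALSE] else panel$x[idx, , , drop = FALSE]
  ordinal_panel(panel$y[idx, , drop = FALSE], x, R = panel$R,
                patient_ids = panel$patient_ids[idx])
}
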