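#' Gap-junction coupling matrix
#'
#' A valid gap-junction (diffusive) coupling matrix `G` has non-negative
#' off-diagonal conductances and each diagonal entry equal to minus the sum
#' of the off-diagonal entries of its row, so that every row sums to zero.
#' Row sums of zero make the coupling vanish whenever all membrane
#' potentials are equal -- the conservation property the synchronization
#' analysis relies on.
#'
#' @param G A square numeric matrix.
#' @param validate Check the constraints on construction (default `TRUE`).
#' @param tol Row-sum / sign tolerance used when `validate = TRUE`.  The
#'   default `5e-7` accommodates matrices printed to five significant
#'   figures; exactly constructed matrices satisfy `1e-12`.
#' @return An object of class `"coupling_matrix"` with fields `n` and `G`.
#' @seealso [validate_coupling()], [coupling_from_offdiagonal()],
#'   [random_coupling()], [reference_coupling()]
#' @export
coupling_matrix <- function(G, validate = TRUE, tol = 5e-7) {
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("coupling matrix must be square")
  storage.mode(G) <- "double"
  dimnames(G) <- NULL
  cm <- structure(list(n = nrow(G), G = G), class = "coupling_matrix")
  if (validate) {
    rep <- validate_coupling(G, tol = tol)
    if (!rep$valid)
      stop("invalid coupling matrix: ",
           paste(unique(rep$violations$reason), collapse = "; "),
           " (max |row sum| = ", format(rep$max_row_sum_abs), ")")
  }
  cm
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat("Gap-junction coupling matrix (", x$n, "x", x$n, ")\n", sep = "")
  print(x$G, ...)
  invisible(x)
}

#' Validate a gap-junction coupling matrix
#'
#' Checks the structural constraints: every off-diagonal entry must be
#' non-negative (absent gap junctions are zeros, which satisfy this), and
#' every diagonal entry must equal minus its off-diagonal row sum, i.e. all
#' row sums must vanish within `tol`.
#'
#' @param G A square numeric matrix (a plain matrix or a
#'   [coupling_matrix()]).
#' @param tol Numeric tolerance for the row-sum condition.
#' @return A list of class `"coupling_validation"` with elements `valid`
#'   (logical), `max_row_sum_abs` and `violations` (data frame with columns
#'   `row`, `column`, `reason`).
#' @examples
#' validate_coupling(reference_coupling()$G)
#' @export
validate_coupling <- function(G, tol = 5e-7) {
  if (inherits(G, "coupling_matrix")) G <- G$G
  G <- as.matrix(G)
  if (nrow(G) != ncol(G)) stop("coupling matrix must be square")
  n <- nrow(G)
  viol <- list()
  off <- G
  diag(off) <- 0
  neg <- which(off < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    viol[[length(viol) + 1L]] <- data.frame(
      row = neg[, 1L], column = neg[, 2L], reason = "negative off-diagonal")
  rs <- rowSums(G)
  bad <- which(abs(rs) > tol)
  if (length(bad) > 0)
    viol[[length(viol) + 1L]] <- data.frame(
      row = bad, column = NA_integer_,
      reason = "row sum exceeds tolerance (diagonal must equal minus the off-diagonal row sum)")
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(row = integer(), column = integer(), reason = character())
  structure(list(valid = nrow(violations) == 0L,
                 max_row_sum_abs = max(abs(rs)),
                 violations = violations,
                 tol = tol),
            class = "coupling_validation")
}

#' @export
print.coupling_validation <- function(x, ...) {
  cat("Coupling validation:", if (x$valid) "VALID" else "INVALID",
      "(max |row sum| =", format(x$max_row_sum_abs),
      ", tol =", format(x$tol), ")\n")
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}

#' Build a coupling matrix from its off-diagonal conductances
#'
#' Takes a non-negative matrix `W` of gap-junction conductances with zero
#' diagonal and fills the diagonal with minus the row sums, producing a
#' matrix whose rows sum to zero exactly.
#'
#' @param W Square non-negative numeric matrix with zero diagonal.
#' @return A [coupling_matrix()] (validated at tolerance `1e-12`).
#' @export
coupling_from_offdiagonal <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("'W' must be square")
  if (any(diag(W) != 0)) stop("'W' must have a zero diagonal")
  if (any(W < 0)) stop("'W' must be non-negative")
  G <- W
  diag(G) <- -rowSums(W)
  coupling_matrix(G, validate = TRUE, tol = 1e-12)
}

#' Random gap-junction coupling matrix
#'
#' Generates a symmetric off-diagonal support (gap junctions are
#' bidirectional): each unordered pair is connected with probability
#' `density`, with conductance drawn uniformly on `(0, scale]`; the diagonal
#' is filled with minus the row sums.
#'
#' @param n Number of neurons (at least 2).
#' @param density Connection probability in `(0, 1]`.
#' @param scale Upper bound of the uniform conductance magnitudes
#'   (positive).
#' @param seed Optional integer seed for reproducibility.
#' @return A [coupling_matrix()].
#' @export
random_coupling <- function(n, density = 1, scale = 1e-3, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1)
    stop("'density' must lie in (0, 1]")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("'scale' must be positive")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  idx <- which(upper.tri(W))
  on <- stats::runif(length(idx)) < density
  w <- stats::runif(length(idx), min = 0, max = scale)
  W[idx] <- ifelse(on, w, 0)
  W <- W + t(W)
  coupling_from_offdiagonal(W)
}

#' Reference five-neuron gap-junction matrix
#'
#' The 5x5 gap-junction conductance matrix used by the packaged reference
#' scenarios (entries printed to five significant figures; its row sums
#' vanish to within about `4e-8`).
#'
#' @return A [coupling_matrix()] with `n = 5`.
#' @examples
#' reference_coupling()$G[2, 3]  # 8.3269e-04
#' @export
reference_coupling <- function() {
  G <- matrix(c(
    -1.0735e-03, 3.6412e-04, 4.0396e-04, 2.0640e-05, 2.8481e-04,
     3.6412e-04, -1.5070e-03, 8.3269e-04, 1.6223e-04, 1.4797e-04,
     4.0396e-04, 8.3269e-04, -2.2451e-03, 8.1832e-04, 1.9013e-04,
     2.0640e-05, 1.6223e-04, 8.1832e-04, -1.6371e-03, 6.3596e-04,
     2.8481e-04, 1.4797e-04, 1.9013e-04, 6.3596e-04, -1.2589e-03),
    nrow = 5, byrow = TRUE)
  coupling_matrix(G, validate = TRUE, tol = 5e-7)
}

#' Read / write a coupling matrix as CSV
#'
#' The file is a plain `n x n` numeric grid without a header.
#'
#' @param path File path.
#' @param tol Validation tolerance used when reading.
#' @return `read_coupling()` returns a [coupling_matrix()];
#'   `write_coupling()` returns `path` invisibly.
#' @export
read_coupling <- function(path, tol = 5e-7) {
  M <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  coupling_matrix(M, validate = TRUE, tol = tol)
}

#' @param cm A [coupling_matrix()] (or plain square matrix).
#' @rdname read_coupling
#' @export
write_coupling <- function(cm, path) {
  G <- if (inherits(cm, "coupling_matrix")) cm$G else as.matrix(cm)
  txt <- apply(G, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = ","))
  writeLines(txt, path)
  invisible(path)
}
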