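# Modular Response Analysis (MRA) algebra.
#
# A network model consists of an interaction matrix r (local response
# coefficients, diagonal fixed at -1) and direct perturbation effects s.
# Measured responses R (log2 fold changes, nodes x conditions) satisfy
#   r . R + s = epsilon      (residual form)
# and the noiseless steady-state response to a direct perturbation vector
# s_total is the unique solution of r . R + s_total = 0, i.e.
#   R = -r^{-1} . s_total.
# An inhibitor (s < 0) therefore lowers its own target's activity in the
# absence of feedback.

check_interaction_matrix <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) stop("r must be a square matrix")
  if (!all(is.finite(r))) stop("r contains non-finite entries")
  if (any(abs(diag(r) + 1) > 1e-12)) {
    stop("diagonal of an interaction matrix must equal -1")
  }
  invisible(r)
}

#' MRA residuals
#'
#' Entrywise residual `epsilon = r %*% R + s` of an interaction matrix and a
#' perturbation matrix against measured responses.
#'
#' @param r interaction matrix (nodes x nodes, diagonal -1).
#' @param s perturbation matrix (nodes x conditions) of scaled direct effects.
#' @param R response matrix (nodes x conditions) of log2 fold changes.
#' @return Residual matrix with the shape and labels of `R`.
#' @export
mra_residuals <- function(r, s, R) {
  check_interaction_matrix(r)
  stop_if_not_aligned(s, R, "s vs R")
  if (nrow(r) != nrow(R)) stop("r and R disagree on the number of nodes")
  if (!is.null(rownames(r)) && !is.null(rownames(R)) &&
      !identical(rownames(r), rownames(R))) {
    stop("node labels of r and R do not match")
  }
  eps <- r %*% R + s
  dimnames(eps) <- dimnames(R)
  eps
}

#' Simulate the steady-state response to a direct perturbation
#'
#' Solves `r %*% R + s_total = 0` for `R`, i.e. `R = -solve(r) %*% s_total`.
#'
#' @param r interaction matrix (invertible, diagonal -1).
#' @param s_total numeric vector of total direct effects per node (sum over
#'   the applied drugs), or a nodes x k matrix of such vectors.
#' @return Simulated log2 fold changes, same shape as `s_total`.
#' @export
simulate_response <- function(r, s_total) {
  check_interaction_matrix(r)
  if (is.matrix(s_total) && nrow(s_total) != nrow(r)) {
    stop("s_total does not match the number of nodes")
  }
  if (!is.matrix(s_total) && length(s_total) != nrow(r)) {
    stop("s_total does not match the number of nodes")
  }
  sol <- tryCatch(solve(r, -s_total),
                  error = function(e) stop("interaction matrix is singular: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.matrix(s_total)) dimnames(sol) <- dimnames(s_total)
  else names(sol) <- names(s_total)
  sol
}

#' Root mean square of residuals
#'
#' `sqrt(sum(eps^2) / N)` over all entries of one residual matrix or a list of
#' residual matrices (e.g. one per cell line, stacked).
#'
#' @param eps residual matrix or list of residual matrices.
#' @return Scalar RMS.
#' @export
rms_residuals <- function(eps) {
  if (is.list(eps)) eps <- unlist(eps, use.names = FALSE)
  n <- length(eps)
  if (n == 0) stop("empty residual set")
  sqrt(sum(eps^2) / n)
}

#' Write / read a network as an edge-list TSV
#'
#' Columns: source, target, cell_line, weight; one row per nonzero
#' off-diagonal interaction coefficient `r[target, source]`.
#'
#' @param r_by_line named list of interaction matrices, one per cell line.
#' @param path file path.
#' @param tol entries with |weight| <= tol are treated as absent.
#' @return `write_network` returns the edge data frame invisibly;
#'   `read_network` returns a named list of interaction matrices.
#' @export
write_network <- function(r_by_line, path, tol = 1e-10) {
  rows <- list()
  for (line in names(r_by_line)) {
    r <- r_by_line[[line]]
    nodes <- rownames(r)
    idx <- which(abs(r) > tol & row(r) != col(r), arr.ind = TRUE)
    if (nrow(idx)) {
      rows[[line]] <- data.frame(
        source = nodes[idx[, "col"]], target = nodes[idx[, "row"]],
        cell_line = line, weight = r[idx])
    }
  }
  edges <- do.call(rbind, rows)
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        cell_line = character(), weight = numeric())
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}

#' @rdname write_network
#' @param nodes node order for the reconstructed matrices.
#' @export
read_network <- function(path, nodes) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  out <- list()
  for (line in unique(edges$cell_line)) {
    r <- diag(-1, length(nodes))
    dimnames(r) <- list(nodes, nodes)
    sub <- edges[edges$cell_line == line, , drop = FALSE]
    r[cbind(match(sub$target, nodes), match(sub$source, nodes))] <- sub$weight
    out[[line]] <- r
  }
  out
}

#' Write / read a response matrix TSV (rows = nodes, columns = conditions)
#'
#' @param R response matrix with node row names and condition column names.
#' @param path file path.
#' @return `read_response_matrix` returns a numeric matrix.
#' @export
write_response_matrix <- function(R, path) {
  df <- data.frame(node = rownames(R), R, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  R <- as.matrix(df[, -1, drop = FALSE])
  rownames(R) <- df[[1]]
  R
}
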