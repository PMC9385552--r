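# Constrained least squares: the convex subproblem of the CNR program once
# all binary indicators are fixed (or relaxed). Zero constraints and
# equality-across-lines constraints are eliminated structurally (columns
# dropped / merged); the remaining linear inequalities (dose-ordering margins
# and optional big-M boxes) are handled by quadprog.

# A: m x p design, y: length m. zero_idx: variables forced to 0.
# eq_pairs: 2-column matrix of variable index pairs forced equal.
# G, h: inequality system G w <= h on the full variables (optional).
# Returns list(w, ssr, fitted).
constrained_lsq <- function(A, y, zero_idx = integer(0), eq_pairs = NULL,
                            G = NULL, h = NULL, ridge = 1e-9) {
  p <- ncol(A)
  # union-find over variables; group of a zeroed variable is dropped
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(eq_pairs) && nrow(eq_pairs)) {
    for (k in seq_len(nrow(eq_pairs))) {
      a <- find(eq_pairs[k, 1]); b <- find(eq_pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(p), find, 1L)
  zero_roots <- unique(root[zero_idx])
  keep <- setdiff(unique(root), zero_roots)
  q <- length(keep)
  w <- numeric(p)

  if (q == 0L) {
    return(list(w = w, ssr = sum(y^2), fitted = numeric(length(y))))
  }
  red <- match(root, keep) # NA for zeroed groups
  M <- matrix(0, p, q)
  ok <- !is.na(red)
  M[cbind(which(ok), red[ok])] <- 1

  Ar <- A %*% M
  D <- 2 * crossprod(Ar)
  lam <- ridge * max(diag(D), 1)
  diag(D) <- diag(D) + lam
  d <- as.numeric(2 * crossprod(Ar, y))

  Gr <- NULL
  if (!is.null(G) && nrow(G)) {
    Gr <- G %*% M
    live <- rowSums(abs(Gr)) > 0
    if (any(!live & h < -1e-12)) {
      stop("inequality constraint infeasible after indicator fixing ",
           "(dose-ordering margin on an eliminated variable)")
    }
    Gr <- Gr[live, , drop = FALSE]
    hh <- h[live]
  }

  if (is.null(Gr) || nrow(Gr) == 0L) {
    wr <- solve(D, d)
  } else {
    sol <- tryCatch(
      quadprog::solve.QP(D, d, Amat = -t(Gr), bvec = -hh),
      error = function(e) stop("QP subproblem failed (constraint family: ",
                               "dose ordering / big-M bounds): ",
                               conditionMessage(e), call. = FALSE))
    wr <- sol$solution
  }
  w <- as.numeric(M %*% wr)
  fitted <- as.numeric(A %*% w)
  list(w = w, ssr = sum((fitted - y)^2), fitted = fitted)
}
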