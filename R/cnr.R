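# Comparative Network Reconstruction (CNR).
#
# Jointly fits per-cell-line MRA models (r, s) to perturbation response
# matrices by minimizing
#
#   sum_{i,n,x} eps_inx^2 + eta * sum I_edge + theta * sum (I_diff + I_sdiff)
#
# subject to indicator implications (I_edge = 0 => r_ij^x = 0; I_diff = 0 =>
# r_ij equal across lines; I_sdiff = 0 => both dose-level s values equal
# across lines), and dose-ordering margins 0 > s(IC50) > s(IC90) realized as
# <= -delta.
#
# The objective and all constraints separate exactly by target node i (each
# row of r and s), so the mixed-integer QP is solved as one small exact
# branch-and-bound per row: the relaxation at a search node is the convex QP
# under the constraints implied by indicators fixed to 0, plus the penalties
# of indicators fixed to 1; incumbents come from rounding the relaxed
# solution. Optimality is certified by exhaustive pruning (tolerance 1e-9),
# and verified against brute-force indicator enumeration in the test suite.

#' Build a CNR problem
#'
#' @param R_by_line named list (one per cell line) of response matrices
#'   (nodes x conditions, identical dimnames). Condition names encode the
#'   treatments as `"DRUG@DOSE"` joined by `"+"`.
#' @param prior_edges data frame (`source`, `target`) of prior-topology edges
#'   whose edge indicators are fixed to 1.
#' @param drug_target_map named list drug -> directly perturbed node(s).
#'   Drugs named in `catalytic` additionally perturb the prior-topology
#'   children of the named node.
#' @param eta edge-count penalty weight (>= 0).
#' @param theta between-line difference penalty weight (>= 0, may be `Inf`
#'   to forbid differences).
#' @param candidates `"all"` (every ordered off-diagonal pair), `"prior"`, or
#'   a data frame of candidate edges. Prior edges are always included.
#' @param fixed_topology if TRUE all candidate edge indicators are fixed to 1
#'   (used for final models and null ensembles).
#' @param encoding `"indicator"` (exact elimination) or `"bigM"` (adds
#'   `|r|, |s| <= B` box constraints; equivalent at binary points, kept as a
#'   cross-check).
#' @param B big-M bound on coefficient magnitudes.
#' @param delta strictness margin of the dose-ordering inequalities.
#' @param catalytic named character vector `drug = node` expanded against the
#'   prior topology (default: the MEK-inhibitor case).
#' @return An object of class `cnr_problem`.
#' @export
build_cnr_problem <- function(R_by_line, prior_edges, drug_target_map,
                              eta = 0.1, theta = 2.0,
                              candidates = "all",
                              fixed_topology = FALSE,
                              encoding = c("indicator", "bigM"),
                              B = 10, delta = 1e-6,
                              catalytic = c(MEKi = "MEK1")) {
  encoding <- match.arg(encoding)
  stopifnot(eta >= 0, theta >= 0, B > 0, delta >= 0)
  if (!is.list(R_by_line) || is.null(names(R_by_line))) {
    stop("R_by_line must be a named list of response matrices")
  }
  lines <- names(R_by_line)
  ref <- R_by_line[[1]]
  for (x in lines) {
    stop_if_not_aligned(R_by_line[[x]], ref, paste0("responses[", x, "]"))
    if (!all(is.finite(R_by_line[[x]]))) stop("non-finite response entries in ", x)
  }
  nodes <- rownames(ref)
  conditions <- colnames(ref)
  if (is.null(nodes) || is.null(conditions)) {
    stop("response matrices need node row names and condition column names")
  }

  map <- expand_target_map(drug_target_map, prior_edges, catalytic)
  bad <- vapply(map, function(tg) length(intersect(tg, nodes)) == 0L, TRUE)
  if (any(bad)) {
    stop("drug(s) with no mappable target among the nodes: ",
         paste(names(map)[bad], collapse = ", "))
  }
  map <- lapply(map, intersect, x = nodes)
  map <- lapply(map, function(tg) tg) # keep order

  treatments <- parse_condition(conditions)
  names(treatments) <- conditions
  used_drugs <- unique(unlist(lapply(treatments, `[[`, "drug")))
  unknown <- setdiff(used_drugs, names(map))
  if (length(unknown)) {
    stop("condition(s) reference unknown drug(s): ", paste(unknown, collapse = ", "))
  }

  # candidate edge set
  all_pairs <- expand.grid(source = nodes, target = nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$source != all_pairs$target, c("source", "target")]
  if (is.character(candidates) && length(candidates) == 1L) {
    cand <- switch(candidates,
                   all = all_pairs,
                   prior = prior_edges[, c("source", "target")],
                   stop("unknown candidate mode: ", candidates))
  } else {
    cand <- candidates[, c("source", "target")]
  }
  key <- function(e) paste(e$source, e$target, sep = "->")
  prior_edges <- prior_edges[, c("source", "target")]
  extra <- prior_edges[!key(prior_edges) %in% key(cand), , drop = FALSE]
  cand <- rbind(cand, extra)
  cand <- cand[!duplicated(key(cand)), , drop = FALSE]
  if (!all(cand$source %in% nodes) || !all(cand$target %in% nodes)) {
    stop("candidate/prior edges reference unknown nodes")
  }
  cand$prior <- key(cand) %in% key(prior_edges)
  rownames(cand) <- NULL

  # s parameters: one per (drug, dose, target) used anywhere in the design
  used <- unique(do.call(rbind, treatments))
  s_params <- do.call(rbind, lapply(seq_len(nrow(used)), function(k) {
    data.frame(drug = used$drug[k], dose = used$dose[k],
               target = map[[used$drug[k]]])
  }))
  rownames(s_params) <- NULL

  structure(list(
    R_by_line = R_by_line, nodes = nodes, conditions = conditions,
    cell_lines = lines, treatments = treatments,
    cand = cand, prior_edges = prior_edges, map = map, s_params = s_params,
    eta = eta, theta = theta, fixed_topology = fixed_topology,
    encoding = encoding, B = B, delta = delta
  ), class = "cnr_problem")
}

#' @export
print.cnr_problem <- function(x, ...) {
  cat("CNR problem: ", length(x$nodes), " nodes, ", length(x$conditions),
      " conditions, ", length(x$cell_lines), " cell lines\n", sep = "")
  cat("  candidate edges: ", nrow(x$cand), " (", sum(x$cand$prior),
      " prior)\n", sep = "")
  cat("  eta = ", x$eta, ", theta = ", x$theta, ", encoding = ", x$encoding,
      if (x$fixed_topology) ", fixed topology", "\n", sep = "")
  invisible(x)
}

# --- per-row variable layout -------------------------------------------------

row_layout <- function(prob, node) {
  L <- length(prob$cell_lines)
  cand_i <- which(prob$cand$target == node)
  sp_i <- which(prob$s_params$target == node)
  nE <- length(cand_i); nS <- length(sp_i)
  pvars <- nE + nS
  m <- length(prob$conditions)

  var_idx <- function(x, slot) (x - 1L) * pvars + slot # slot in 1..pvars

  A <- matrix(0, L * m, L * pvars)
  y <- numeric(L * m)
  for (x in seq_len(L)) {
    Rm <- prob$R_by_line[[x]]
    rows <- (x - 1L) * m + seq_len(m)
    if (nE) {
      for (e in seq_len(nE)) {
        A[rows, var_idx(x, e)] <- Rm[prob$cand$source[cand_i[e]], ]
      }
    }
    if (nS) {
      for (s in seq_len(nS)) {
        d <- prob$s_params$drug[sp_i[s]]; l <- prob$s_params$dose[sp_i[s]]
        inc <- vapply(prob$treatments, function(tr) {
          any(tr$drug == d & tr$dose == l)
        }, TRUE)
        A[rows, var_idx(x, nE + s)] <- as.numeric(inc)
      }
    }
    y[rows] <- Rm[node, ]
  }

  # dose-ordering inequalities (and big-M boxes), on full variables
  Grows <- list(); hvals <- numeric(0)
  add_row <- function(coef_idx, coef_val, rhs) {
    g <- numeric(L * pvars); g[coef_idx] <- coef_val
    Grows[[length(Grows) + 1L]] <<- g
    hvals[length(hvals) + 1L] <<- rhs
  }
  sdrugs <- unique(prob$s_params$drug[sp_i])
  for (x in seq_len(L)) {
    for (d in sdrugs) {
      slots <- which(prob$s_params$drug[sp_i] == d)
      doses <- prob$s_params$dose[sp_i][slots]
      v <- stats::setNames(var_idx(x, nE + slots), doses)
      if (all(c("IC50", "IC90") %in% doses)) {
        add_row(v[["IC50"]], 1, -prob$delta)                 # s50 <= -delta
        add_row(c(v[["IC90"]], v[["IC50"]]), c(1, -1), -prob$delta) # s90 <= s50-delta
      } else {
        add_row(v[[1]], 1, -prob$delta)
      }
    }
  }
  if (prob$encoding == "bigM") {
    for (v in seq_len(L * pvars)) {
      add_row(v, 1, prob$B)
      add_row(v, -1, prob$B)
    }
  }
  G <- if (length(Grows)) do.call(rbind, Grows) else NULL

  list(node = node, L = L, nE = nE, nS = nS, pvars = pvars,
       cand_i = cand_i, sp_i = sp_i, sdrugs = sdrugs,
       var_idx = var_idx, A = A, y = y, G = G, h = hvals)
}

# --- branch and bound over one row's indicators ------------------------------

# binaries: data.frame(type, ref, fixed) where ref indexes layout$cand_i
# (edge/diff) or layout$sdrugs (sdiff); fixed in {NA, 0, 1}.
row_binaries <- function(prob, lay, forced_diffs = NULL) {
  b <- list()
  for (e in seq_len(lay$nE)) {
    fixed <- if (prob$fixed_topology || prob$cand$prior[lay$cand_i[e]]) 1 else NA
    b[[length(b) + 1L]] <- data.frame(type = "edge", ref = e, fixed = fixed)
  }
  if (lay$L >= 2) {
    for (e in seq_len(lay$nE)) {
      b[[length(b) + 1L]] <- data.frame(type = "diff", ref = e,
                                        fixed = if (is.infinite(prob$theta)) 0 else NA)
    }
    for (k in seq_along(lay$sdrugs)) {
      b[[length(b) + 1L]] <- data.frame(type = "sdiff", ref = k,
                                        fixed = if (is.infinite(prob$theta)) 0 else NA)
    }
  }
  bin <- if (length(b)) do.call(rbind, b) else
    data.frame(type = character(), ref = integer(), fixed = numeric())

  if (!is.null(forced_diffs)) {
    ek <- paste(prob$cand$source[lay$cand_i], prob$cand$target[lay$cand_i], sep = "->")
    fe <- if (!is.null(forced_diffs$edges) && nrow(forced_diffs$edges)) {
      paste(forced_diffs$edges$source, forced_diffs$edges$target, sep = "->")
    } else character(0)
    fs <- if (!is.null(forced_diffs$sdiffs) && nrow(forced_diffs$sdiffs)) {
      forced_diffs$sdiffs[forced_diffs$sdiffs$target == lay$node, "drug"]
    } else character(0)
    for (r in seq_len(nrow(bin))) {
      if (bin$type[r] == "diff") bin$fixed[r] <- as.numeric(ek[bin$ref[r]] %in% fe)
      if (bin$type[r] == "sdiff") bin$fixed[r] <- as.numeric(lay$sdrugs[bin$ref[r]] %in% fs)
    }
  }
  bin
}

# constraints implied by indicators currently fixed to 0
assignment_constraints <- function(a, bin, lay) {
  zero <- integer(0)
  eq <- list()
  for (r in seq_len(nrow(bin))) {
    if (is.na(a[r]) || a[r] != 0) next
    if (bin$type[r] == "edge") {
      zero <- c(zero, vapply(seq_len(lay$L), function(x) lay$var_idx(x, bin$ref[r]), 1L))
    } else if (bin$type[r] == "diff") {
      v <- vapply(seq_len(lay$L), function(x) lay$var_idx(x, bin$ref[r]), 1L)
      for (x in seq_len(lay$L - 1L)) eq[[length(eq) + 1L]] <- c(v[1], v[x + 1L])
    } else { # sdiff spans both dose-level variables of the drug
      d <- lay$sdrugs[bin$ref[r]]
      for (sl in which(attr(lay, "sp_drug") == d)) {
        v <- vapply(seq_len(lay$L), function(x) lay$var_idx(x, lay$nE + sl), 1L)
        for (x in seq_len(lay$L - 1L)) eq[[length(eq) + 1L]] <- c(v[1], v[x + 1L])
      }
    }
  }
  list(zero = zero,
       eq = if (length(eq)) do.call(rbind, eq) else NULL)
}

assignment_penalty <- function(a, bin, eta, theta) {
  n_edge <- sum(a == 1 & bin$type == "edge", na.rm = TRUE)
  n_diff <- sum(a == 1 & bin$type != "edge", na.rm = TRUE)
  pen <- eta * n_edge
  if (n_diff > 0) pen <- pen + theta * n_diff
  pen
}

# round the relaxed solution into a full indicator assignment
round_assignment <- function(a, bin, lay, w, tol = 1e-7) {
  disparity <- function(v) {
    vals <- w[v]
    max(abs(vals - mean(vals)))
  }
  edge_active <- logical(lay$nE)
  for (r in which(bin$type == "edge")) {
    e <- bin$ref[r]
    v <- vapply(seq_len(lay$L), function(x) lay$var_idx(x, e), 1L)
    edge_active[e] <- if (!is.na(a[r])) a[r] == 1 else any(abs(w[v]) > tol)
    a[r] <- as.numeric(edge_active[e])
  }
  for (r in which(bin$type == "diff")) {
    e <- bin$ref[r]
    if (is.na(a[r])) {
      v <- vapply(seq_len(lay$L), function(x) lay$var_idx(x, e), 1L)
      a[r] <- as.numeric(edge_active[e] && disparity(v) > tol)
    }
  }
  for (r in which(bin$type == "sdiff")) {
    if (is.na(a[r])) {
      d <- lay$sdrugs[bin$ref[r]]
      slots <- which(attr(lay, "sp_drug") == d)
      dis <- max(vapply(slots, function(sl) {
        disparity(vapply(seq_len(lay$L), function(x) lay$var_idx(x, lay$nE + sl), 1L))
      }, 1))
      a[r] <- as.numeric(dis > tol)
    }
  }
  a
}

solve_row <- function(prob, node, forced_diffs = NULL) {
  lay <- row_layout(prob, node)
  attr(lay, "sp_drug") <- prob$s_params$drug[lay$sp_i]
  bin <- row_binaries(prob, lay, forced_diffs)

  cache <- new.env(parent = emptyenv())
  qp <- function(a) {
    con <- assignment_constraints(a, bin, lay)
    key <- paste0("k:", paste(c(sort(con$zero), if (!is.null(con$eq)) t(con$eq)),
                              collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- constrained_lsq(lay$A, lay$y, zero_idx = con$zero, eq_pairs = con$eq,
                           G = lay$G, h = lay$h)
    cache[[key]] <- res
    res
  }

  a0 <- bin$fixed
  free <- which(is.na(a0))
  if (length(free) == 0L) {
    sol <- qp(a0)
    return(list(lay = lay, bin = bin, assignment = a0, sol = sol,
                obj = sol$ssr + assignment_penalty(a0, bin, prob$eta, prob$theta),
                nodes_explored = 1L))
  }

  # static branching order from the root relaxation
  root <- qp(a0)
  score <- numeric(nrow(bin))
  for (r in free) {
    if (bin$type[r] == "edge") {
      v <- vapply(seq_len(lay$L), function(x) lay$var_idx(x, bin$ref[r]), 1L)
      score[r] <- 3 + max(abs(root$w[v]))
    } else if (bin$type[r] == "sdiff") {
      d <- lay$sdrugs[bin$ref[r]]
      slots <- which(attr(lay, "sp_drug") == d)
      score[r] <- 2 + max(vapply(slots, function(sl) {
        vals <- root$w[vapply(seq_len(lay$L), function(x) lay$var_idx(x, lay$nE + sl), 1L)]
        max(abs(vals - mean(vals)))
      }, 1))
    } else {
      v <- vapply(seq_len(lay$L), function(x) lay$var_idx(x, bin$ref[r]), 1L)
      score[r] <- 1 + max(abs(root$w[v] - mean(root$w[v])))
    }
  }
  order_free <- free[order(-score[free])]

  best <- new.env(parent = emptyenv())
  best$obj <- Inf; best$a <- NULL; best$sol <- NULL; best$n <- 0L

  consider <- function(a_full) {
    sol <- qp(a_full)
    obj <- sol$ssr + assignment_penalty(a_full, bin, prob$eta, prob$theta)
    if (obj < best$obj - 1e-12) {
      best$obj <- obj; best$a <- a_full; best$sol <- sol
    }
    obj
  }

  recurse <- function(a, depth) {
    best$n <- best$n + 1L
    relax <- qp(a)
    lb <- relax$ssr + assignment_penalty(a, bin, prob$eta, prob$theta)
    if (lb >= best$obj - 1e-9) return()
    rounded <- round_assignment(a, bin, lay, relax$w)
    consider(rounded)
    if (depth > length(order_free)) return()
    r <- order_free[depth]
    if (!is.na(a[r])) return(recurse(a, depth + 1L))
    first <- rounded[r]
    for (val in c(first, 1 - first)) {
      a2 <- a
      a2[r] <- val
      if (bin$type[r] == "edge" && val == 0) {
        # an absent edge cannot differ between lines
        dr <- which(bin$type == "diff" & bin$ref == bin$ref[r])
        if (length(dr) && is.na(a2[dr])) a2[dr] <- 0
      }
      recurse(a2, depth + 1L)
    }
  }
  recurse(a0, 1L)

  list(lay = lay, bin = bin, assignment = best$a, sol = best$sol,
       obj = best$obj, nodes_explored = best$n)
}

# --- full solve --------------------------------------------------------------

#' Solve a CNR problem to optimality
#'
#' Exact row-decomposed branch-and-bound (see the package vignette).
#'
#' @param problem a `cnr_problem`.
#' @param forced_diffs optional list with elements `edges` (data frame
#'   `source`, `target`) and `sdiffs` (data frame `drug`, `target`): exactly
#'   these difference indicators are fixed to 1 and all others to 0 (used by
#'   the random-differences null ensemble).
#' @return An object of class `cnr_result`: per-line `r` matrices, the fitted
#'   `s` table, active indicators, residuals, objective value, fit
#'   correlation and solver status.
#' @export
solve_cnr <- function(problem, forced_diffs = NULL) {
  stopifnot(inherits(problem, "cnr_problem"))
  nodes <- problem$nodes
  lines <- problem$cell_lines
  L <- length(lines)
  n <- length(nodes)
  m <- length(problem$conditions)

  r <- lapply(lines, function(x) {
    mat <- diag(-1, n); dimnames(mat) <- list(nodes, nodes); mat
  })
  names(r) <- lines
  s_rows <- list()
  edge_active <- rep(FALSE, nrow(problem$cand))
  diff_active <- rep(FALSE, nrow(problem$cand))
  sdiff_list <- list()
  objective <- 0
  explored <- 0L

  for (node in nodes) {
    rs <- solve_row(problem, node, forced_diffs)
    lay <- rs$lay; bin <- rs$bin; w <- rs$sol$w; a <- rs$assignment
    objective <- objective + rs$obj
    explored <- explored + rs$nodes_explored
    for (e in seq_len(lay$nE)) {
      ci <- lay$cand_i[e]
      er <- which(bin$type == "edge" & bin$ref == e)
      act <- a[er] == 1
      edge_active[ci] <- act
      if (act) {
        for (x in seq_len(L)) {
          r[[x]][node, problem$cand$source[ci]] <- w[lay$var_idx(x, e)]
        }
      }
      dr <- which(bin$type == "diff" & bin$ref == e)
      if (length(dr)) diff_active[ci] <- act && a[dr] == 1
    }
    for (s in seq_len(lay$nS)) {
      sp <- problem$s_params[lay$sp_i[s], ]
      for (x in seq_len(L)) {
        s_rows[[length(s_rows) + 1L]] <- data.frame(
          drug = sp$drug, dose = sp$dose, target = sp$target,
          cell_line = lines[x], value = w[lay$var_idx(x, lay$nE + s)])
      }
    }
    for (k in seq_along(lay$sdrugs)) {
      sr <- which(bin$type == "sdiff" & bin$ref == k)
      if (length(sr)) {
        sdiff_list[[length(sdiff_list) + 1L]] <- data.frame(
          drug = lay$sdrugs[k], target = node, active = a[sr] == 1)
      }
    }
  }

  s <- do.call(rbind, s_rows)
  rownames(s) <- NULL
  lk <- s_lookup(s)
  s_matrix <- lapply(lines, function(x) {
    S <- matrix(0, n, m, dimnames = list(nodes, problem$conditions))
    for (cid in problem$conditions) {
      tr <- problem$treatments[[cid]]
      for (i in seq_len(nrow(tr))) {
        for (tg in problem$map[[tr$drug[i]]]) {
          S[tg, cid] <- S[tg, cid] + lk[[s_key(tr$drug[i], tr$dose[i], tg, x)]]
        }
      }
    }
    S
  })
  names(s_matrix) <- lines

  residuals <- lapply(lines, function(x) {
    mra_residuals(r[[x]], s_matrix[[x]], problem$R_by_line[[x]])
  })
  names(residuals) <- lines

  predicted <- lapply(lines, function(x) simulate_response(r[[x]], s_matrix[[x]]))
  names(predicted) <- lines
  fit_cor <- stats::cor(unlist(predicted), unlist(problem$R_by_line))

  edges <- problem$cand
  edges$active <- edge_active
  edges$diff <- diff_active
  sdiffs <- if (length(sdiff_list)) do.call(rbind, sdiff_list) else
    data.frame(drug = character(), target = character(), active = logical())

  structure(list(
    r = r, s = s, s_matrix = s_matrix, residuals = residuals,
    predicted = predicted, fit_cor = fit_cor,
    edges = edges, sdiffs = sdiffs,
    n_differences = sum(diff_active) + sum(sdiffs$active),
    objective = objective, rms = rms_residuals(residuals),
    status = "optimal", nodes_explored = explored,
    eta = problem$eta, theta = problem$theta,
    cell_lines = lines, map = problem$map
  ), class = "cnr_result")
}

#' @export
print.cnr_result <- function(x, ...) {
  cat("CNR fit (", x$status, "): objective = ", format(x$objective, digits = 6),
      ", RMS = ", format(x$rms, digits = 4),
      ", fit correlation = ", format(x$fit_cor, digits = 3), "\n", sep = "")
  cat("  active edges: ", sum(x$edges$active),
      " | differing edges: ", sum(x$edges$diff),
      " | differing perturbations: ", sum(x$sdiffs$active), "\n", sep = "")
  invisible(x)
}

#' Export a CNR result as JSON (+ edge list TSV)
#'
#' @param result a `cnr_result`.
#' @param path JSON output path; an edge-list TSV is written next to it.
#' @return `path`, invisibly.
#' @export
write_cnr_result <- function(result, path) {
  jsonlite::write_json(list(
    cell_lines = result$cell_lines,
    r = lapply(result$r, as.data.frame),
    s = result$s,
    edges = result$edges,
    sdiffs = result$sdiffs,
    objective = result$objective, rms = result$rms,
    fit_cor = result$fit_cor, status = result$status,
    eta = result$eta, theta = result$theta
  ), path, auto_unbox = TRUE, digits = NA)
  write_network(result$r, sub("\\.json$", "_edges.tsv", path))
  invisible(path)
}
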