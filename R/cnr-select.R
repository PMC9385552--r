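# Hyperparameter selection by leave-one-out cross-validation over two-drug
# conditions, and the fixed-topology final model.

# names of multi-drug conditions
combo_conditions <- function(conditions) {
  conditions[vapply(parse_condition(conditions), nrow, 1L) >= 2L]
}

# predict a held-out condition column from fitted (r, s): R = -r^{-1} s_cond
predict_condition <- function(result, cid) {
  lk <- s_lookup(result$s)
  trt <- parse_condition(cid)[[1]]
  out <- list()
  for (line in result$cell_lines) {
    s <- stats::setNames(numeric(nrow(result$r[[line]])),
                         rownames(result$r[[line]]))
    for (i in seq_len(nrow(trt))) {
      for (tg in result$map[[trt$drug[i]]]) {
        key <- s_key(trt$drug[i], trt$dose[i], tg, line)
        if (is.na(lk[key])) stop("no fitted s for ", key)
        s[tg] <- s[tg] + lk[[key]]
      }
    }
    out[[line]] <- simulate_response(result$r[[line]], s)
  }
  out
}

#' Select CNR hyperparameters by leave-one-out cross-validation
#'
#' Each two-drug condition is held out in turn (single-drug conditions are
#' never held out: every drug concentration must remain present to estimate
#' its parameter); the model is refit and the held-out response column is
#' predicted as `-r^{-1}(s_A + s_B)`. The grid point minimizing the mean
#' per-entry squared held-out error wins; ties (within 1e-9) break toward
#' the smallest `eta`, then the largest `theta`.
#'
#' @param R_by_line,prior_edges,drug_target_map as [build_cnr_problem()].
#' @param eta_grid,theta_grid numeric grids (non-empty).
#' @param ... further options passed to [build_cnr_problem()].
#' @return List with `hyperparams` (`eta`, `theta`), `added_edges` (non-prior
#'   edges active in the full refit at the selected point), `cv_errors` (grid
#'   data frame), and `fit` (the full refit).
#' @export
cnr_loocv <- function(R_by_line, prior_edges, drug_target_map,
                      eta_grid, theta_grid, ...) {
  if (length(eta_grid) == 0 || length(theta_grid) == 0) {
    stop("empty hyperparameter grid")
  }
  conds <- colnames(R_by_line[[1]])
  combos <- combo_conditions(conds)
  if (length(combos) == 0) stop("LOOCV requires at least one two-drug condition")

  grid <- expand.grid(eta = eta_grid, theta = theta_grid)
  grid$cv_error <- NA_real_
  for (g in seq_len(nrow(grid))) {
    errs <- vapply(combos, function(cid) {
      keep <- setdiff(conds, cid)
      R_minus <- lapply(R_by_line, function(Rm) Rm[, keep, drop = FALSE])
      prob <- build_cnr_problem(R_minus, prior_edges, drug_target_map,
                                eta = grid$eta[g], theta = grid$theta[g], ...)
      fit <- solve_cnr(prob)
      pred <- predict_condition(fit, cid)
      se <- vapply(names(pred), function(line) {
        mean((pred[[line]] - R_by_line[[line]][, cid])^2)
      }, 1)
      mean(se)
    }, 1)
    grid$cv_error[g] <- mean(errs)
  }

  best_err <- min(grid$cv_error)
  tied <- which(grid$cv_error <= best_err + 1e-9)
  tied <- tied[order(grid$eta[tied], -grid$theta[tied])]
  sel <- tied[1]

  prob <- build_cnr_problem(R_by_line, prior_edges, drug_target_map,
                            eta = grid$eta[sel], theta = grid$theta[sel], ...)
  fit <- solve_cnr(prob)
  added <- fit$edges[fit$edges$active & !fit$edges$prior,
                     c("source", "target"), drop = FALSE]
  list(hyperparams = list(eta = grid$eta[sel], theta = grid$theta[sel]),
       added_edges = added, cv_errors = grid, fit = fit)
}

#' Fit the final CNR model on a fixed topology
#'
#' Fixes the edge indicators to the given topology (prior plus any
#' cross-validation-selected additions) and re-optimizes with only the
#' difference indicators free.
#'
#' @param R_by_line named list of response matrices.
#' @param topology data frame (`source`, `target`) of the fixed edge set.
#' @param theta difference penalty (may be `Inf`).
#' @param drug_target_map drug -> target map.
#' @param eta edge penalty, only contributes a constant on a fixed topology.
#' @param ... further options for [build_cnr_problem()].
#' @return A `cnr_result`.
#' @export
cnr_final_model <- function(R_by_line, topology, theta = 2.0,
                            drug_target_map = default_drug_target_map(),
                            eta = 0.1, ...) {
  prob <- build_cnr_problem(R_by_line, prior_edges = topology,
                            drug_target_map = drug_target_map,
                            eta = eta, theta = theta,
                            candidates = topology, fixed_topology = TRUE, ...)
  solve_cnr(prob)
}
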