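# Simulation and optimization of unseen multi-drug combinations.
#
# A combo model bundles, per cell line, the reconstructed interaction matrix
# r, the fitted dose-inhibition curves, and the viability parameters K_M.
# The response to drugs A+B+C at concentrations [I_A], [I_B], [I_C] is
#   R = -r^{-1} (s_A([I_A]) + s_B([I_B]) + s_C([I_C]))
# and viability follows the Michaelis-Menten-like model from R_AKT, R_ERK.
# Selectivity is v_parental - v_mutant (first cell line minus second);
# anti-selectivity is its negation.

#' Bundle network, dose and viability models for combination simulation
#'
#' @param r_by_line named list of interaction matrices (first line = the
#'   protected/parental line by convention).
#' @param dose_params `dose_params` data frame from [fit_dose_params()].
#' @param K_M named list per cell line of `c(AKT=, ERK=)`.
#' @param conc_cap named numeric vector: per-drug maximal normalized
#'   concentration (defaults to each drug's IC10 when `design` is given).
#' @param design optional `study_design` used to derive `conc_cap`.
#' @param viability_nodes named map of roles AKT/ERK to node names.
#' @param form viability model form used in simulation (default `"4c"`).
#' @return An object of class `combo_model`.
#' @export
combo_model <- function(r_by_line, dose_params, K_M,
                        conc_cap = NULL, design = NULL,
                        viability_nodes = c(AKT = "AKT1", ERK = "ERK1"),
                        form = "4c") {
  lines <- names(r_by_line)
  stopifnot(length(lines) >= 2)
  drugs <- unique(dose_params$drug)
  if (is.null(conc_cap)) {
    if (is.null(design)) stop("provide conc_cap or a design to derive IC10 caps")
    conc_cap <- vapply(drugs, function(d) design$dose_levels[[d]][["IC10"]], 1)
  }
  inv_neg <- lapply(r_by_line, function(r) {
    check_interaction_matrix(r)
    -solve(r)
  })
  # fast path: per (line, drug), cache the dose-curve parameters alongside the
  # AKT/ERK rows of -r^{-1} restricted to the drug's targets, so viability
  # evaluation inside the optimizer is a few flops
  fx <- lapply(lines, function(line) {
    akt <- inv_neg[[line]][viability_nodes[["AKT"]], ]
    erk <- inv_neg[[line]][viability_nodes[["ERK"]], ]
    per_drug <- lapply(drugs, function(d) {
      sub <- dose_params[dose_params$drug == d & dose_params$cell_line == line, ]
      list(Imax = sub$Imax, KI = sub$KI,
           ca = unname(akt[sub$target]), ce = unname(erk[sub$target]))
    })
    names(per_drug) <- drugs
    per_drug
  })
  names(fx) <- lines
  structure(list(
    r = r_by_line, inv_neg = inv_neg, lines = lines,
    dose_params = dose_params, drugs = drugs, K_M = K_M, fx = fx,
    conc_cap = conc_cap, viability_nodes = viability_nodes, form = form
  ), class = "combo_model")
}

# total direct-effect vector for one line at given per-drug concentrations
combo_s_total <- function(model, line, drugs, conc) {
  nodes <- rownames(model$r[[line]])
  s <- stats::setNames(numeric(length(nodes)), nodes)
  dp <- model$dose_params
  for (d in drugs) {
    sub <- dp[dp$drug == d & dp$cell_line == line, , drop = FALSE]
    if (nrow(sub) == 0) stop("missing dose parameters for drug ", d,
                             " in line ", line)
    for (k in seq_len(nrow(sub))) {
      s[sub$target[k]] <- s[sub$target[k]] +
        inhibition_at(list(Imax = sub$Imax[k], KI = sub$KI[k]), conc[[d]])
    }
  }
  s
}

# (R_AKT, R_ERK) per line for fast repeated evaluation
combo_akterk <- function(model, line, drugs, conc) {
  fx <- model$fx[[line]]
  RA <- RE <- 0
  for (d in drugs) {
    f <- fx[[d]]
    if (is.null(f) || length(f$Imax) == 0) {
      stop("missing dose parameters for drug ", d, " in line ", line)
    }
    s <- f$Imax * conc[[d]] / (f$KI + conc[[d]])
    RA <- RA + sum(f$ca * s)
    RE <- RE + sum(f$ce * s)
  }
  c(AKT = RA, ERK = RE)
}

combo_v <- function(model, line, drugs, conc) {
  ae <- combo_akterk(model, line, drugs, conc)
  predict_viability(model$form, list(K = model$K_M[[line]]),
                    R_AKT = ae[["AKT"]], R_ERK = ae[["ERK"]])
}

#' Simulate a drug combination at given concentrations
#'
#' @param model a `combo_model`.
#' @param drugs character vector of drug names (typically 3).
#' @param conc named numeric vector of normalized concentrations in `[0, 1]`.
#' @return An object of class `combo_prediction` with the full simulated
#'   response per line, predicted viabilities, and (anti-)selectivity.
#' @export
simulate_combo <- function(model, drugs, conc) {
  if (!all(drugs %in% names(conc))) stop("conc must name every drug")
  R <- v <- list()
  for (line in model$lines) {
    s <- combo_s_total(model, line, drugs, conc)
    R[[line]] <- simulate_response(model$r[[line]], s)
    vn <- model$viability_nodes
    v[[line]] <- unname(predict_viability(model$form, list(K = model$K_M[[line]]),
                                          R_AKT = R[[line]][vn[["AKT"]]],
                                          R_ERK = R[[line]][vn[["ERK"]]]))
  }
  v <- unlist(v)
  sel <- unname(v[model$lines[1]] - v[model$lines[2]])
  structure(list(drugs = drugs, conc = conc[drugs], v = v, response = R,
                 selectivity = sel, anti_selectivity = -sel),
            class = "combo_prediction")
}

#' @export
print.combo_prediction <- function(x, ...) {
  cat(paste(x$drugs, collapse = " + "), "\n")
  cat("  conc: ", paste(names(x$conc), format(x$conc, digits = 3),
                        sep = "=", collapse = ", "), "\n", sep = "")
  cat("  v: ", paste(names(x$v), format(x$v, digits = 4),
                     sep = "=", collapse = ", "),
      " | selectivity = ", format(x$selectivity, digits = 4), "\n", sep = "")
  invisible(x)
}

opt_roles <- function(model, direction) {
  # selective: minimize the mutant, protect the parental; anti: the reverse
  if (direction == "selective") list(x = model$lines[2], y = model$lines[1])
  else list(x = model$lines[1], y = model$lines[2])
}

#' Dense-grid evaluation of a 3-drug combination
#'
#' Vectorized evaluation of both lines' viabilities on a full concentration
#' grid; used as the optimizer's seeding device and as an independent oracle
#' in tests.
#'
#' @param model a `combo_model`.
#' @param drugs drug triple.
#' @param n_grid grid points per drug on `[0, cap]`.
#' @param direction `"selective"`, `"anti_selective"`, or `"control"`.
#' @param v_min protected-line viability floor (ignored for control).
#' @return List: best `conc`, `objective` (v_x, or the control quadratic
#'   loss), `v` at the best point, plus the grid axes.
#' @export
grid_search_combo <- function(model, drugs, n_grid = 21,
                              direction = c("anti_selective", "selective", "control"),
                              v_min = 0.8) {
  direction <- match.arg(direction)
  if (model$form != "4c") stop("grid search is implemented for the form-4c model")
  axes <- lapply(drugs, function(d) seq(0, model$conc_cap[[d]], length.out = n_grid))
  names(axes) <- drugs
  vn <- model$viability_nodes

  v_arrays <- lapply(model$lines, function(line) {
    # per-drug AKT/ERK contributions at each axis point, then outer sums
    contrib <- lapply(drugs, function(d) {
      vapply(axes[[d]], function(cc) {
        combo_akterk(model, line, d, stats::setNames(cc, d))
      }, c(AKT = 0, ERK = 0))
    })
    add3 <- function(ch) {
      a1 <- contrib[[1]][ch, ]; a2 <- contrib[[2]][ch, ]; a3 <- contrib[[3]][ch, ]
      outer(outer(a1, a2, "+"), a3, "+")
    }
    RA <- add3("AKT"); RE <- add3("ERK")
    K <- model$K_M[[line]]
    den <- 1 - RA / K[["AKT"]] - RE / K[["ERK"]]
    v <- 1 / den
    v[den <= 0] <- NA # outside the model's domain
    v
  })
  names(v_arrays) <- model$lines

  if (direction == "control") {
    obj <- (v_arrays[[1]] - 0.8)^2 + (v_arrays[[2]] - 0.8)^2
  } else {
    roles <- opt_roles(model, direction)
    obj <- v_arrays[[roles$x]]
    obj[v_arrays[[roles$y]] < v_min] <- NA
  }
  best <- which.min(obj)
  idx <- arrayInd(best, rep(length(axes[[1]]), 3))
  conc <- stats::setNames(mapply(function(ax, i) ax[i], axes, idx[1, ]), drugs)
  list(conc = conc, objective = obj[best],
       v = vapply(v_arrays, `[`, 1, best), axes = axes)
}

optimize_box <- function(fn, starts, lower, upper) {
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(pmin(pmax(as.numeric(starts[k, ]), lower), upper), fn,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("combination optimizer failed from every start")
  best
}

#' Optimize a triple's concentrations for (anti-)selectivity
#'
#' Solves: minimize v_x subject to v_y >= v_min and 0 <= conc <= cap, by
#' multi-start projected quasi-Newton with a ramped quadratic penalty for the
#' viability floor, seeded from a coarse grid; the returned point satisfies
#' the constraint within 1e-6 (concentrations are scaled back toward zero if
#' needed, which is always feasible since v(0) = 1).
#'
#' @param model a `combo_model`.
#' @param drugs drug triple.
#' @param direction `"selective"` (minimize the second line, protect the
#'   first) or `"anti_selective"` (the reverse).
#' @param v_min protected-line viability floor.
#' @param n_starts number of multi-start points (coarse-grid seeded).
#' @param seed_grid coarse grid resolution per drug used for seeding.
#' @return A `combo_prediction` with attributes `objective` (optimized v_x)
#'   and `direction`.
#' @export
optimize_selectivity <- function(model, drugs,
                                 direction = c("anti_selective", "selective"),
                                 v_min = 0.8, n_starts = 8, seed_grid = 5) {
  direction <- match.arg(direction)
  roles <- opt_roles(model, direction)
  cap <- vapply(drugs, function(d) model$conc_cap[[d]], 1)

  vx <- function(conc) combo_v(model, roles$x, drugs, stats::setNames(conc, drugs))
  vy <- function(conc) combo_v(model, roles$y, drugs, stats::setNames(conc, drugs))

  # coarse-grid seeding
  gs <- grid_search_combo(model, drugs, n_grid = seed_grid,
                          direction = direction, v_min = v_min)
  starts <- rbind(gs$conc,
                  rep(0, 3), cap, cap / 2,
                  as.matrix(expand.grid(lapply(cap, function(cc) c(cc / 4, cc)))))
  starts <- unique(starts)[seq_len(min(n_starts + 3, nrow(unique(starts)))), ,
                           drop = FALSE]

  for (mu in c(1e4, 1e7)) {
    pen_fn <- function(conc) {
      vyv <- tryCatch(vy(conc), error = function(e) NA_real_)
      vxv <- tryCatch(vx(conc), error = function(e) NA_real_)
      if (!is.finite(vyv) || !is.finite(vxv)) return(10)
      vxv + mu * max(0, v_min - vyv)^2
    }
    o <- optimize_box(pen_fn, starts, lower = rep(0, 3), upper = cap)
    starts <- rbind(o$par, starts) # warm start the next ramp stage
  }
  cand <- o$par
  # feasibility polish: pull concentrations toward zero until v_y >= v_min
  vy_safe <- function(conc) tryCatch(vy(conc), error = function(e) -Inf)
  if (vy_safe(cand) < v_min - 1e-6) {
    t_star <- stats::uniroot(function(t) vy_safe(t * cand) - v_min, c(0, 1),
                             tol = 1e-10)$root
    cand <- t_star * cand
  }
  pred <- simulate_combo(model, drugs, stats::setNames(cand, drugs))
  attr(pred, "objective") <- unname(pred$v[roles$x])
  attr(pred, "direction") <- direction
  attr(pred, "v_min") <- v_min
  pred
}

#' Select a non-selective control dosing for a triple
#'
#' Minimizes `(v_x - 0.8)^2 + (v_y - 0.8)^2` over the capped concentration
#' box (both lines pushed toward 80% viability).
#'
#' @inheritParams optimize_selectivity
#' @param target common viability target (0.8).
#' @return A `combo_prediction` with attribute `objective` (the achieved
#'   quadratic loss).
#' @export
select_controls <- function(model, drugs, target = 0.8, n_starts = 8,
                            seed_grid = 5) {
  cap <- vapply(drugs, function(d) model$conc_cap[[d]], 1)
  v1 <- function(conc) combo_v(model, model$lines[1], drugs, stats::setNames(conc, drugs))
  v2 <- function(conc) combo_v(model, model$lines[2], drugs, stats::setNames(conc, drugs))
  fn <- function(conc) {
    a <- tryCatch(v1(conc), error = function(e) NA_real_)
    b <- tryCatch(v2(conc), error = function(e) NA_real_)
    if (!is.finite(a) || !is.finite(b)) return(10)
    (a - target)^2 + (b - target)^2
  }
  gs <- grid_search_combo(model, drugs, n_grid = seed_grid, direction = "control")
  starts <- rbind(gs$conc, rep(0, 3), cap, cap / 2,
                  as.matrix(expand.grid(lapply(cap, function(cc) c(cc / 4, cc)))))
  starts <- unique(starts)[seq_len(min(n_starts + 3, nrow(unique(starts)))), ,
                           drop = FALSE]
  o <- optimize_box(fn, starts, lower = rep(0, 3), upper = cap)
  pred <- simulate_combo(model, drugs, stats::setNames(o$par, drugs))
  attr(pred, "objective") <- o$value
  pred
}

#' Rank all drug triples by optimized (anti-)selectivity
#'
#' Runs [optimize_selectivity()] over every 3-drug subset of the model's
#' drugs and sorts by the optimized (anti-)selectivity. Per-triple failures
#' are collected, not fatal.
#'
#' @inheritParams optimize_selectivity
#' @param drugs drug universe (defaults to the model's).
#' @param anti_selectivity_floor reported filter threshold.
#' @return Data frame of class `ranked_combos` (one row per triple, sorted),
#'   with the filtered subset in attribute `"filtered"`.
#' @export
rank_all_triples <- function(model, drugs = model$drugs,
                             direction = c("anti_selective", "selective"),
                             v_min = 0.8, anti_selectivity_floor = 0.1, ...) {
  direction <- match.arg(direction)
  if (length(drugs) < 3) stop("need at least 3 drugs")
  triples <- utils::combn(drugs, 3)
  rows <- list()
  for (k in seq_len(ncol(triples))) {
    tri <- triples[, k]
    pred <- tryCatch(
      optimize_selectivity(model, tri, direction = direction, v_min = v_min, ...),
      error = function(e) e)
    if (inherits(pred, "error")) {
      rows[[k]] <- data.frame(drug1 = tri[1], drug2 = tri[2], drug3 = tri[3],
                              conc1 = NA, conc2 = NA, conc3 = NA,
                              v1 = NA, v2 = NA, selectivity = NA,
                              anti_selectivity = NA,
                              status = conditionMessage(pred))
    } else {
      rows[[k]] <- data.frame(
        drug1 = tri[1], drug2 = tri[2], drug3 = tri[3],
        conc1 = pred$conc[[1]], conc2 = pred$conc[[2]], conc3 = pred$conc[[3]],
        v1 = unname(pred$v[model$lines[1]]), v2 = unname(pred$v[model$lines[2]]),
        selectivity = pred$selectivity,
        anti_selectivity = pred$anti_selectivity,
        status = "ok")
    }
  }
  out <- do.call(rbind, rows)
  score <- if (direction == "anti_selective") out$anti_selectivity else out$selectivity
  out <- out[order(-score, na.last = TRUE), ]
  rownames(out) <- NULL
  sc <- if (direction == "anti_selective") out$anti_selectivity else out$selectivity
  attr(out, "filtered") <- out[!is.na(sc) & sc > anti_selectivity_floor, ]
  attr(out, "direction") <- direction
  class(out) <- c("ranked_combos", "data.frame")
  out
}

#' Power analysis for a validation experiment
#'
#' Per simulation, i.i.d. Gaussian noise (default sd 0.25, the scale of the
#' viability prediction residuals) is added to each combination's predicted
#' selectivity in both groups and a two-sided rank-sum test is run; power is
#' the fraction of simulations detecting a group difference at `alpha`.
#'
#' @param group1,group2 numeric vectors of predicted (anti-)selectivities.
#' @param noise_sd noise standard deviation.
#' @param n_sims number of simulations.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return Scalar power estimate.
#' @export
power_analysis <- function(group1, group2, noise_sd = 0.25, n_sims = 1000,
                           alpha = 0.05, seed = 1L) {
  if (length(group1) == 0 || length(group2) == 0) stop("both groups must be non-empty")
  withr::with_seed(seed, {
    hits <- vapply(seq_len(n_sims), function(i) {
      x <- group1 + stats::rnorm(length(group1), 0, noise_sd)
      y <- group2 + stats::rnorm(length(group2), 0, noise_sd)
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value) < alpha
    }, TRUE)
    mean(hits)
  })
}

#' Size of the combinatorial search space
#'
#' `choose(n_drugs, k) * n_conc^k`: the number of k-drug combinations when
#' each drug can be dosed at `n_conc` levels.
#'
#' @param n_drugs number of drugs.
#' @param k combination size.
#' @param n_conc dose levels per drug.
#' @return Numeric count.
#' @export
search_space_size <- function(n_drugs, k, n_conc = 1) {
  stopifnot(k >= 0, k <= n_drugs, n_conc >= 1)
  choose(n_drugs, k) * n_conc^k
}

#' Validation statistics for measured combination viabilities
#'
#' Computes per-combination anti-selectivity (second line minus first,
#' paired by replicate), compares the two prediction groups with an unpaired
#' rank-sum test, and runs per-combination one-sided t-tests against zero and
#' against a monotherapy reference.
#'
#' @param viability long data frame (condition, cell_line, replicate, value)
#'   with exactly two cell lines.
#' @param groups data frame (condition, group) assigning each combination to
#'   a prediction group (e.g. "anti_selective" vs "control").
#' @param reference named numeric vector (per condition) or single scalar:
#'   monotherapy anti-selectivity to test against (optional).
#' @param lines the (parental, mutant) cell-line labels; defaults to the
#'   order of appearance.
#' @return List with `per_combo` (data frame) and `group_test` (htest).
#' @export
validation_stats <- function(viability, groups, reference = NULL, lines = NULL) {
  if (is.null(lines)) lines <- unique(viability$cell_line)
  stopifnot(length(lines) == 2)
  per <- list()
  for (cid in unique(viability$condition)) {
    sub <- viability[viability$condition == cid, ]
    w <- stats::reshape(sub, direction = "wide", idvar = "replicate",
                        timevar = "cell_line", v.names = "value",
                        drop = "condition")
    anti <- w[[paste0("value.", lines[2])]] - w[[paste0("value.", lines[1])]]
    anti <- anti[is.finite(anti)]
    row <- data.frame(condition = cid, n = length(anti),
                      anti_selectivity = mean(anti),
                      sd = stats::sd(anti),
                      p_vs_zero = NA_real_, p_vs_reference = NA_real_)
    if (length(anti) >= 2) {
      row$p_vs_zero <- stats::t.test(anti, mu = 0, alternative = "greater")$p.value
      if (!is.null(reference)) {
        ref <- if (length(reference) == 1L && is.null(names(reference))) reference
               else reference[[cid]]
        if (!is.null(ref) && is.finite(ref)) {
          row$p_vs_reference <-
            stats::t.test(anti, mu = ref, alternative = "greater")$p.value
        }
      }
    } else {
      warning("condition ", cid, " has fewer than 2 paired replicates; ",
              "per-combination tests skipped")
    }
    per[[cid]] <- row
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  per$group <- groups$group[match(per$condition, groups$condition)]
  gl <- unique(stats::na.omit(per$group))
  group_test <- NULL
  if (length(gl) == 2) {
    group_test <- suppressWarnings(stats::wilcox.test(
      per$anti_selectivity[per$group == gl[1]],
      per$anti_selectivity[per$group == gl[2]], exact = FALSE))
  }
  list(per_combo = per, group_test = group_test)
}
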