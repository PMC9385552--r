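# Randomization-based significance assessment of a fitted network model.
#
# Three ensembles, each solved with differences between the cell lines
# forbidden (theta = Inf) so that only the randomized ingredient varies:
#   random_topology    - random edge sets of the same size as the model
#   node_permutation   - node labels of the input data permuted, true topology
#   random_differences - true topology, a fixed number of randomly chosen
#                        difference indicators forced active
# The reference RMS is the actual model's, computed under the same regime.

#' Build a null ensemble of randomized network models
#'
#' @param R_by_line named list of response matrices.
#' @param topology data frame (`source`, `target`): the actual model's edges.
#' @param drug_target_map drug -> target map.
#' @param mode one of `"random_topology"`, `"node_permutation"`,
#'   `"random_differences"`.
#' @param n_models ensemble size.
#' @param n_edges (random_topology) number of edges per random model.
#' @param n_diffs (random_differences) number of difference indicators
#'   forced active per model.
#' @param theta difference penalty used in the random_differences reference
#'   and the forced-difference solves (finite value irrelevant to RMS).
#' @param seed integer seed.
#' @param ... further options for [build_cnr_problem()].
#' @return An object of class `null_ensemble`: mode, `rms_values`,
#'   `reference_rms`, seed.
#' @export
null_ensemble <- function(R_by_line, topology, drug_target_map,
                          mode = c("random_topology", "node_permutation",
                                   "random_differences"),
                          n_models = 1000,
                          n_edges = nrow(topology), n_diffs = 13,
                          theta = 2.0, seed = 1L, ...) {
  mode <- match.arg(mode)
  stopifnot(n_models >= 1)
  nodes <- rownames(R_by_line[[1]])
  n <- length(nodes)

  fit_fixed <- function(R, topo, forced = NULL) {
    th <- if (is.null(forced)) Inf else theta
    prob <- build_cnr_problem(R, prior_edges = topo,
                              drug_target_map = drug_target_map,
                              eta = 0, theta = th,
                              candidates = topo, fixed_topology = TRUE, ...)
    solve_cnr(prob, forced_diffs = forced)
  }

  reference <- fit_fixed(R_by_line, topology)

  all_pairs <- expand.grid(source = nodes, target = nodes,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ]
  if (mode == "random_topology" && n_edges > nrow(all_pairs)) {
    stop("requested edge count exceeds the number of candidate edges (",
         nrow(all_pairs), ")")
  }

  # pool of difference indicators: one per edge, one per (drug, target) pair
  sd_pool <- unique(do.call(rbind, lapply(names(drug_target_map), function(d) {
    tg <- intersect(drug_target_map[[d]], nodes)
    if (length(tg)) data.frame(drug = d, target = tg) else NULL
  })))

  rms_values <- withr::with_seed(seed, vapply(seq_len(n_models), function(b) {
    if (mode == "random_topology") {
      pick <- sample.int(nrow(all_pairs), n_edges)
      fit_fixed(R_by_line, all_pairs[pick, ])$rms
    } else if (mode == "node_permutation") {
      perm <- sample.int(n)
      R_perm <- lapply(R_by_line, function(Rm) {
        out <- Rm[perm, , drop = FALSE]
        rownames(out) <- nodes
        out
      })
      fit_fixed(R_perm, topology)$rms
    } else {
      n_pool <- nrow(topology) + nrow(sd_pool)
      if (n_diffs > n_pool) stop("n_diffs exceeds the difference-indicator pool")
      pick <- sample.int(n_pool, n_diffs)
      forced <- list(
        edges = topology[pick[pick <= nrow(topology)], , drop = FALSE],
        sdiffs = sd_pool[pick[pick > nrow(topology)] - nrow(topology), ,
                         drop = FALSE])
      fit_fixed(R_by_line, topology, forced = forced)$rms
    }
  }, 1))

  structure(list(mode = mode, n_models = n_models, rms_values = rms_values,
                 reference_rms = reference$rms, reference_fit = reference,
                 seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null ensemble (", x$mode, "): ", x$n_models, " models\n", sep = "")
  cat("  reference RMS = ", format(x$reference_rms, digits = 5),
      "; null RMS range = [", format(min(x$rms_values), digits = 5), ", ",
      format(max(x$rms_values), digits = 5), "]\n", sep = "")
  cat("  empirical p = ", format(empirical_pvalue(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Empirical p value of a null ensemble
#'
#' `p = (k + 1) / (n + 1)` with `k` the number of null models whose RMS is
#' less than or equal to the reference (ties count as beating the reference;
#' the add-one rule avoids p = 0).
#'
#' @param ensemble a `null_ensemble`, or a list with elements `rms_values`
#'   and `reference_rms`.
#' @return Scalar p value.
#' @export
empirical_pvalue <- function(ensemble) {
  k <- sum(ensemble$rms_values <= ensemble$reference_rms)
  n <- length(ensemble$rms_values)
  (k + 1) / (n + 1)
}

#' Write a null ensemble to disk
#'
#' @param ensemble a `null_ensemble`.
#' @param prefix output path prefix; writes `<prefix>.tsv` (per-model RMS)
#'   and `<prefix>_summary.json`.
#' @return `prefix`, invisibly.
#' @export
write_null_ensemble <- function(ensemble, prefix) {
  utils::write.table(
    data.frame(model = seq_along(ensemble$rms_values), rms = ensemble$rms_values),
    paste0(prefix, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    mode = ensemble$mode, n_models = ensemble$n_models,
    reference_rms = ensemble$reference_rms,
    p_value = empirical_pvalue(ensemble), seed = ensemble$seed
  ), paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
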