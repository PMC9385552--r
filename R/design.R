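# Study design: nodes, drugs, dose levels and perturbation conditions of a
# two-cell-line kinase inhibitor screen.

#' Default signaling nodes
#'
#' The nine phospho-protein readouts of the MAPK/AKT panel.
#' @return Character vector of node names.
#' @export
default_nodes <- function() {
  c("CREB1", "EGFR", "ERK1", "GSK3", "MEK1", "p70S6K", "PRAS40", "RPS6", "AKT1")
}

#' Default inhibitor panel
#' @return Character vector of drug names.
#' @export
default_drugs <- function() {
  c("EGFRi", "IGF1Ri", "RAFi", "MEKi", "ERKi", "GSK3i", "PI3Ki", "AKTi", "mTORi")
}

#' Canonical prior network topology
#'
#' A canonical MAPK/PI3K-pathway edge list among the nine measured nodes,
#' used as prior information for network reconstruction and as the default
#' ground-truth topology of the synthetic generator. Direction is
#' source -> target (the source is the upstream regulator).
#'
#' @return Data frame with columns `source` and `target` (12 edges).
#' @export
default_prior_network <- function() {
  e <- rbind(
    c("EGFR",   "MEK1"),   # RAS/RAF (unmeasured) relay
    c("EGFR",   "AKT1"),   # PI3K (unmeasured) relay
    c("MEK1",   "ERK1"),
    c("ERK1",   "CREB1"),  # via p90RSK
    c("ERK1",   "RPS6"),
    c("ERK1",   "GSK3"),
    c("ERK1",   "EGFR"),   # negative feedback on receptor
    c("AKT1",   "GSK3"),
    c("AKT1",   "PRAS40"),
    c("AKT1",   "p70S6K"), # via mTORC1
    c("AKT1",   "CREB1"),
    c("p70S6K", "RPS6")
    # note: no p70S6K -> AKT1 feedback -- together with mTORi perturbing both
    # nodes it makes the AKT1 row of the design exactly rank-deficient
    # (structurally unidentifiable even from noiseless data)
  )
  data.frame(source = e[, 1], target = e[, 2])
}

#' Drug to direct-target map
#'
#' Maps each inhibitor to the measured node(s) modeled as directly perturbed.
#' Inhibitors of unmeasured kinases act on their first measured canonical
#' downstream node: IGF1Ri on MEK1 and AKT1, PI3Ki on AKT1, RAFi on MEK1,
#' mTORi on AKT1 and p70S6K. Drugs listed in `catalytic` additionally perturb
#' the prior-topology children of their target, reflecting interference with
#' catalytic efficiency (the MEK-inhibitor case).
#'
#' @param prior prior network edge list (data frame `source`, `target`) used
#'   to resolve downstream children of catalytic-class drugs.
#' @param catalytic named character vector `drug = target` of drugs whose
#'   downstream children are also perturbed directly.
#' @return Named list: drug -> character vector of target nodes.
#' @export
default_drug_target_map <- function(prior = default_prior_network(),
                                    catalytic = c(MEKi = "MEK1")) {
  map <- list(
    EGFRi  = "EGFR",
    IGF1Ri = c("MEK1", "AKT1"),
    RAFi   = "MEK1",
    MEKi   = "MEK1",
    ERKi   = "ERK1",
    GSK3i  = "GSK3",
    PI3Ki  = "AKT1",
    AKTi   = "AKT1",
    mTORi  = c("AKT1", "p70S6K")
  )
  expand_target_map(map, prior, catalytic)
}

#' Expand a drug-target map with catalytic downstream targets
#'
#' @param map named list drug -> target nodes.
#' @param prior prior edge list used to look up children.
#' @param catalytic named character vector `drug = node`; the prior-topology
#'   children of `node` are appended to that drug's targets.
#' @return The expanded map.
#' @export
expand_target_map <- function(map, prior, catalytic = c(MEKi = "MEK1")) {
  for (drug in names(catalytic)) {
    if (!drug %in% names(map)) next
    kids <- prior$target[prior$source == catalytic[[drug]]]
    map[[drug]] <- union(map[[drug]], kids)
  }
  map
}

#' Construct a perturbation study design
#'
#' Builds the condition layout of the screen: every drug tested singly at its
#' IC50 and IC90 (except drugs in `single_dose_drugs`, tested at IC90 only),
#' plus `combo_count` distinct two-drug combinations with both drugs at IC50,
#' drawn deterministically from `seed`. The defaults reproduce the study
#' shape: 17 single-drug + 17 two-drug = 34 conditions over 9 nodes and 2
#' cell lines.
#'
#' @param nodes,drugs character vectors of node and drug names.
#' @param combo_count number of two-drug IC50+IC50 combinations.
#' @param single_dose_drugs drugs tested only at IC90.
#' @param dose_levels named numeric vector of normalized concentrations for
#'   the labels IC10/IC50/IC90 (IC90 must be 1), or a named list of such
#'   vectors per drug. Defaults correspond to a unit Hill slope
#'   (IC50/IC90 = 1/9, IC10/IC90 = 1/81).
#' @param cell_lines labels of the (>= 2) cell lines; the first is treated as
#'   the parental/protected line downstream.
#' @param seed integer seed controlling combination choice.
#' @return An object of class `study_design`.
#' @export
make_study_design <- function(nodes = default_nodes(),
                              drugs = default_drugs(),
                              combo_count = 17,
                              single_dose_drugs = "RAFi",
                              dose_levels = c(IC10 = 1 / 81, IC50 = 1 / 9, IC90 = 1),
                              cell_lines = c("parental", "mutant"),
                              seed = 1L) {
  stopifnot(length(nodes) >= 1, length(drugs) >= 1, length(cell_lines) >= 2)
  if (anyDuplicated(nodes) || anyDuplicated(drugs)) {
    stop("node and drug names must be unique")
  }
  if (!is.list(dose_levels)) {
    dose_levels <- stats::setNames(rep(list(dose_levels), length(drugs)), drugs)
  }
  for (d in drugs) {
    dl <- dose_levels[[d]]
    if (is.null(dl) || !all(c("IC10", "IC50", "IC90") %in% names(dl))) {
      stop("dose levels for drug ", d, " must name IC10, IC50 and IC90")
    }
    if (!(dl[["IC10"]] > 0 && dl[["IC10"]] < dl[["IC50"]] &&
          dl[["IC50"]] < dl[["IC90"]] && dl[["IC90"]] == 1)) {
      stop("dose levels for drug ", d,
           " must satisfy 0 < IC10 < IC50 < IC90 = 1")
    }
  }
  # Combinations are drawn among drugs that also have a single IC50 condition,
  # so every (drug, dose) in a combination is anchored by a monotherapy.
  combo_pool <- setdiff(drugs, single_dose_drugs)
  n_pairs <- choose(length(combo_pool), 2)
  if (combo_count > n_pairs) {
    stop("combo_count (", combo_count, ") exceeds the number of eligible drug pairs (",
         n_pairs, ")")
  }

  singles <- list()
  for (d in drugs) {
    doses <- if (d %in% single_dose_drugs) "IC90" else c("IC50", "IC90")
    for (l in doses) {
      singles[[condition_id(d, l)]] <- data.frame(drug = d, dose = l)
    }
  }

  combos <- list()
  if (combo_count > 0) {
    pairs <- utils::combn(combo_pool, 2)
    pick <- withr::with_seed(seed, sample.int(n_pairs, combo_count))
    for (p in pick) {
      pr <- pairs[, p]
      combos[[condition_id(pr, c("IC50", "IC50"))]] <-
        data.frame(drug = pr, dose = c("IC50", "IC50"))
    }
  }

  structure(list(
    nodes = nodes, drugs = drugs,
    dose_levels = dose_levels,
    single_dose_drugs = intersect(single_dose_drugs, drugs),
    conditions = c(singles, combos),
    cell_lines = cell_lines,
    seed = seed
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Perturbation study design\n")
  cat("  nodes:      ", length(x$nodes), " (", paste(x$nodes, collapse = ", "), ")\n", sep = "")
  cat("  drugs:      ", length(x$drugs), "\n", sep = "")
  n_single <- sum(vapply(x$conditions, nrow, 1L) == 1L)
  cat("  conditions: ", length(x$conditions), " (", n_single, " single, ",
      length(x$conditions) - n_single, " combinations)\n", sep = "")
  cat("  cell lines: ", paste(x$cell_lines, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of response measurements implied by a design
#'
#' nodes x conditions x cell lines.
#' @param design a `study_design`.
#' @return Integer count.
#' @export
design_measurement_count <- function(design) {
  length(design$nodes) * length(design$conditions) * length(design$cell_lines)
}

# (drug, dose) pairs present anywhere in the design, per drug.
design_dose_usage <- function(design) {
  u <- unique(do.call(rbind, design$conditions))
  u[order(u$drug, u$dose), , drop = FALSE]
}
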