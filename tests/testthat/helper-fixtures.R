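# Shared fixtures: small worlds built in code, and an exhaustive-enumeration
# oracle for the CNR mixed-integer program that is independent of the
# branch-and-bound path (per-assignment least squares via plain qr).

# A compact 4-node / 3-drug world whose design matrices are identifiable.
small_world <- function(seed = 42, n_diffs = 2, combo_count = 3,
                        noise_sd = 0, viability_noise_sd = 0) {
  nodes <- c("N1", "N2", "N3", "N4")
  drugs <- c("D1", "D2", "D3")
  map <- list(D1 = "N1", D2 = "N2", D3 = "N4")
  prior <- data.frame(source = c("N1", "N2", "N1"),
                      target = c("N2", "N3", "N4"))
  design <- make_study_design(nodes = nodes, drugs = drugs,
                              combo_count = combo_count,
                              single_dose_drugs = character(0),
                              cell_lines = c("parental", "mutant"),
                              seed = seed)
  truth <- generate_ground_truth(design, n_diffs = n_diffs, seed = seed,
                                 edges = prior, target_map = map,
                                 viability_nodes = c(AKT = "N1", ERK = "N2"),
                                 K_M = list(parental = c(AKT = 2, ERK = 2.5),
                                            mutant = c(AKT = 2.2, ERK = 2.8)))
  dataset <- simulate_dataset(truth, design, noise_sd = noise_sd,
                              viability_noise_sd = viability_noise_sd,
                              seed = seed + 1)
  list(nodes = nodes, drugs = drugs, map = map, prior = prior,
       design = design, truth = truth, dataset = dataset)
}

# The default-shaped 9-node world (prior topology as truth).
default_world <- function(seed = 7, n_diffs = 13, noise_sd = 0,
                          viability_noise_sd = 0, planted = NULL) {
  design <- make_study_design(seed = seed)
  truth <- generate_ground_truth(design, edges = default_prior_network(),
                                 n_diffs = n_diffs, seed = seed,
                                 planted = planted)
  dataset <- simulate_dataset(truth, design, noise_sd = noise_sd,
                              viability_noise_sd = viability_noise_sd,
                              seed = seed + 1)
  list(design = design, truth = truth, dataset = dataset,
       prior = default_prior_network(), map = truth$target_map)
}

# count entries (edge weights + perturbation strengths) differing between the
# two lines of a ground truth
count_truth_diffs <- function(truth) {
  lines <- truth$cell_lines
  r_diff <- sum(abs(truth$r[[lines[1]]] - truth$r[[lines[2]]]) > 1e-12)
  s1 <- truth$s_spec[truth$s_spec$cell_line == lines[1], ]
  s2 <- truth$s_spec[truth$s_spec$cell_line == lines[2], ]
  key <- function(s) paste(s$drug, s$dose, s$target)
  s2v <- stats::setNames(s2$value, key(s2))
  # an (drug, target) pair counts once even though it spans two dose levels
  pair_diff <- unique(paste(s1$drug, s1$target)[abs(s1$value - s2v[key(s1)]) > 1e-12])
  r_diff + length(pair_diff)
}

# ---- exhaustive enumeration oracle -----------------------------------------
# Enumerates every indicator assignment of a (small) CNR problem and solves
# the per-assignment least squares directly with qr (no quadprog, no
# branch-and-bound). Inequality (dose-ordering) constraints are checked, not
# enforced: assignments whose LS solution violates them are skipped, so use
# worlds where the truth is strictly interior.
enum_cnr_oracle <- function(problem) {
  stopifnot(inherits(problem, "cnr_problem"))
  total <- 0
  for (node in problem$nodes) {
    lay <- combonet:::row_layout(problem, node)
    attr(lay, "sp_drug") <- problem$s_params$drug[lay$sp_i]
    bin <- combonet:::row_binaries(problem, lay, NULL)
    free <- which(is.na(bin$fixed))
    best <- Inf
    n_free <- length(free)
    for (mask in seq_len(2^n_free) - 1L) {
      a <- bin$fixed
      if (n_free) a[free] <- bitwAnd(mask, 2^(seq_len(n_free) - 1L)) > 0
      # diffs on absent edges are meaningless; canonicalize to 0
      for (r in which(bin$type == "diff")) {
        er <- which(bin$type == "edge" & bin$ref == bin$ref[r])
        if (a[er] == 0 && a[r] == 1) a[r] <- NA # skip non-canonical duplicates
      }
      if (anyNA(a)) next
      con <- combonet:::assignment_constraints(a, bin, lay)
      # merge/zero columns by hand
      p <- ncol(lay$A)
      parent <- seq_len(p)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      if (!is.null(con$eq)) for (k in seq_len(nrow(con$eq))) {
        x <- find(con$eq[k, 1]); z <- find(con$eq[k, 2])
        if (x != z) parent[max(x, z)] <- min(x, z)
      }
      root <- vapply(seq_len(p), find, 1L)
      root[root %in% unique(root[con$zero])] <- 0L
      keep <- setdiff(unique(root), 0L)
      w <- numeric(p)
      if (length(keep)) {
        M <- outer(root, keep, "==") * 1
        fitq <- qr(lay$A %*% M)
        wr <- qr.coef(fitq, lay$y)
        wr[is.na(wr)] <- 0
        w <- as.numeric(M %*% wr)
      }
      if (!is.null(lay$G) && nrow(lay$G) &&
          any(lay$G %*% w > lay$h + 1e-9)) next
      ssr <- sum((lay$A %*% w - lay$y)^2)
      pen <- combonet:::assignment_penalty(a, bin, problem$eta, problem$theta)
      best <- min(best, ssr + pen)
    }
    total <- total + best
  }
  total
}
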