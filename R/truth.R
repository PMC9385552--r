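# Ground-truth generation and forward simulation of noisy datasets.
#
# A ground truth holds, per cell line, an MRA interaction matrix r
# (diagonal -1) and direct perturbation effects s per (drug, dose, target),
# plus the Michaelis-Menten-like viability parameters K_M. The two lines
# share topology; a configurable number of entries (edge weights or
# perturbation strengths) are quantitatively different ("planted"
# differences), emulating an isogenic pair with a knocked-in mutation.

s_key <- function(drug, dose, target, line) paste(drug, dose, target, line, sep = "|")

s_lookup <- function(s_spec) {
  stats::setNames(s_spec$value,
                  s_key(s_spec$drug, s_spec$dose, s_spec$target, s_spec$cell_line))
}

#' Generate a two-cell-line ground-truth network
#'
#' Samples a shared random topology (or uses `edges`), draws edge weights and
#' direct perturbation effects, and plants exactly `n_diffs` quantitative
#' differences between the cell lines by multiplying/dividing the affected
#' coefficient by a factor drawn from `diff_factor_range`. Interaction
#' matrices are guaranteed invertible (resampled on near-singularity).
#'
#' @param design a `study_design`.
#' @param n_edges number of off-diagonal edges when sampling a random
#'   topology (ignored when `edges` is given).
#' @param n_diffs number of planted differences, drawn among edges and
#'   (drug, target) perturbation pairs.
#' @param seed integer seed.
#' @param edges optional fixed topology (data frame `source`, `target`).
#' @param target_map drug -> target nodes map; defaults to the canonical map.
#' @param weight_range magnitude range of edge weights.
#' @param p_negative probability that an edge weight is negative.
#' @param diff_factor_range range of the multiplicative effect size of
#'   planted differences (applied as *f or /f with equal probability).
#' @param s90_range magnitude range of the direct effect at IC90
#'   (values are negative: inhibitors).
#' @param s50_frac_range range of the ratio s(IC50)/s(IC90), in (0, 1), which
#'   enforces 0 > s(IC50) > s(IC90).
#' @param K_M named list (per cell line) of c(AKT=, ERK=) viability
#'   half-inhibition parameters.
#' @param viability_nodes named character vector mapping the roles AKT/ERK to
#'   node names.
#' @param planted optional explicit differences, a data frame with columns
#'   `kind` ("edge" or "perturbation"), `source` (edge source or drug name),
#'   `target` and `multiplier` (second line = first line * multiplier);
#'   sampled differences fill up to `n_diffs`.
#' @param max_tries resampling attempts before giving up on invertibility.
#' @return An object of class `ground_truth`.
#' @export
generate_ground_truth <- function(design,
                                  n_edges = 16, n_diffs = 13, seed = 1L,
                                  edges = NULL,
                                  target_map = default_drug_target_map(),
                                  weight_range = c(0.3, 1.2),
                                  p_negative = 0.2,
                                  diff_factor_range = c(1.5, 3),
                                  s90_range = c(0.5, 2),
                                  s50_frac_range = c(0.3, 0.8),
                                  K_M = NULL,
                                  viability_nodes = c(AKT = "AKT1", ERK = "ERK1"),
                                  planted = NULL,
                                  max_tries = 100) {
  nodes <- design$nodes
  n <- length(nodes)
  lines <- design$cell_lines[1:2]
  if (is.null(K_M)) {
    K_M <- stats::setNames(list(c(AKT = 1.5, ERK = 2.0), c(AKT = 1.8, ERK = 2.4)),
                           lines)
  }
  target_map <- target_map[intersect(names(target_map), design$drugs)]
  if (!all(viability_nodes %in% nodes)) stop("viability nodes not in node set")

  usage <- design_dose_usage(design)
  pert_pairs <- unique(do.call(rbind, lapply(seq_len(nrow(usage)), function(i) {
    d <- usage$drug[i]
    tg <- target_map[[d]]
    if (is.null(tg)) stop("drug ", d, " has no entry in the target map")
    data.frame(drug = d, target = tg)
  })))

  if (is.null(edges)) {
    if (n_edges > n * (n - 1)) stop("n_edges exceeds the number of ordered node pairs")
  } else {
    n_edges <- nrow(edges)
  }
  n_explicit <- if (is.null(planted)) 0L else nrow(planted)
  if (n_diffs < n_explicit) stop("n_diffs smaller than the explicit planted set")
  if (n_diffs > n_edges + nrow(pert_pairs)) {
    stop("n_diffs exceeds the number of edges plus perturbation pairs")
  }

  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      # topology + line-1 weights
      if (is.null(edges)) {
        offdiag <- which(diag(n) == 0, arr.ind = TRUE) # (row=target, col=source)
        pick <- sample.int(nrow(offdiag), n_edges)
        topo <- data.frame(source = nodes[offdiag[pick, "col"]],
                           target = nodes[offdiag[pick, "row"]])
      } else {
        topo <- edges[, c("source", "target")]
      }
      r1 <- diag(-1, n); dimnames(r1) <- list(nodes, nodes)
      w <- stats::runif(nrow(topo), weight_range[1], weight_range[2]) *
        ifelse(stats::runif(nrow(topo)) < p_negative, -1, 1)
      r1[cbind(match(topo$target, nodes), match(topo$source, nodes))] <- w

      # line-1 perturbation effects per used (drug, dose, target)
      s_rows <- list()
      for (i in seq_len(nrow(pert_pairs))) {
        d <- pert_pairs$drug[i]; tg <- pert_pairs$target[i]
        doses <- sort(unique(usage$dose[usage$drug == d]))
        s90 <- -stats::runif(1, s90_range[1], s90_range[2])
        vals <- c(IC50 = s90 * stats::runif(1, s50_frac_range[1], s50_frac_range[2]),
                  IC90 = s90)
        for (l in doses) {
          s_rows[[length(s_rows) + 1L]] <- data.frame(
            drug = d, dose = l, target = tg, cell_line = lines[1],
            value = vals[[l]])
        }
      }
      s1 <- do.call(rbind, s_rows)

      # planted differences
      pool <- rbind(data.frame(kind = rep("edge", nrow(topo)),
                               source = topo$source, target = topo$target),
                    data.frame(kind = rep("perturbation", nrow(pert_pairs)),
                               source = pert_pairs$drug,
                               target = pert_pairs$target))
      if (n_explicit > 0) {
        key_pool <- paste(pool$kind, pool$source, pool$target)
        key_exp <- paste(planted$kind, planted$source, planted$target)
        if (!all(key_exp %in% key_pool)) {
          stop("explicit planted differences refer to absent edges/perturbations")
        }
        pool <- pool[!key_pool %in% key_exp, , drop = FALSE]
      }
      n_sample <- n_diffs - n_explicit
      sampled <- pool[sample.int(nrow(pool), n_sample), , drop = FALSE]
      if (n_sample > 0) {
        f <- stats::runif(n_sample, diff_factor_range[1], diff_factor_range[2])
        up <- stats::runif(n_sample) < 0.5
        sampled$multiplier <- ifelse(up, f, 1 / f)
      } else {
        sampled$multiplier <- numeric(0)
      }
      diffs <- rbind(
        if (n_explicit > 0) planted[, c("kind", "source", "target", "multiplier")],
        sampled)
      rownames(diffs) <- NULL

      # apply to line 2
      r2 <- r1
      s2 <- s1; s2$cell_line <- lines[2]
      for (i in seq_len(nrow(diffs))) {
        if (diffs$kind[i] == "edge") {
          ij <- cbind(match(diffs$target[i], nodes), match(diffs$source[i], nodes))
          r2[ij] <- r2[ij] * diffs$multiplier[i]
        } else {
          hit <- s2$drug == diffs$source[i] & s2$target == diffs$target[i]
          s2$value[hit] <- s2$value[hit] * diffs$multiplier[i]
        }
      }

      ok <- rcond(r1) > 1e-8 && rcond(r2) > 1e-8
      if (ok) {
        # the viability model (v = 1/(1 - R_AKT/K - R_ERK/K)) must be defined
        # on every condition: resample truths whose noiseless responses leave
        # its domain (as real training data do by construction)
        cand <- structure(list(
          nodes = nodes, cell_lines = lines, edges = topo,
          r = stats::setNames(list(r1, r2), lines),
          s_spec = rbind(s1, s2), target_map = target_map), class = "ground_truth")
        for (x in seq_along(lines)) {
          S <- build_s_matrix(cand, design, lines[x])
          R0 <- simulate_response(cand$r[[x]], S)
          K <- K_M[[lines[x]]]
          den <- 1 - R0[viability_nodes[["AKT"]], ] / K[["AKT"]] -
            R0[viability_nodes[["ERK"]], ] / K[["ERK"]]
          if (any(den < 0.05) || max(abs(R0)) > 8) { ok <- FALSE; break }
        }
      }
      if (ok) {
        truth <- structure(list(
          nodes = nodes, cell_lines = lines,
          edges = topo,
          r = stats::setNames(list(r1, r2), lines),
          s_spec = rbind(s1, s2),
          planted_diffs = diffs,
          target_map = target_map,
          K_M = K_M,
          viability_nodes = viability_nodes,
          seed = seed
        ), class = "ground_truth")
        return(truth)
      }
    }
    stop("could not sample an invertible interaction matrix in ", max_tries, " tries")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth two-line network: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges, ", nrow(x$planted_diffs),
      " planted differences\n", sep = "")
  invisible(x)
}

# nodes x conditions matrix of total direct effects for one cell line.
build_s_matrix <- function(truth, design, line) {
  nodes <- truth$nodes
  lk <- s_lookup(truth$s_spec)
  S <- matrix(0, length(nodes), length(design$conditions),
              dimnames = list(nodes, names(design$conditions)))
  for (cid in names(design$conditions)) {
    trt <- design$conditions[[cid]]
    for (i in seq_len(nrow(trt))) {
      d <- trt$drug[i]; l <- trt$dose[i]
      for (tg in truth$target_map[[d]]) {
        key <- s_key(d, l, tg, line)
        if (is.na(lk[key])) stop("no ground-truth s for ", key)
        S[tg, cid] <- S[tg, cid] + lk[[key]]
      }
    }
  }
  S
}

#' Simulate a noisy response/viability dataset from a ground truth
#'
#' Per condition the total direct effect vector is propagated through each
#' line's network (`R = -r^{-1} s`), then i.i.d. Gaussian noise (log2 units)
#' is added entrywise. Viability is computed from the *noiseless* pAKT/pERK
#' responses with the Michaelis-Menten-like model and each line's K_M, with
#' Gaussian noise truncated at 0 per replicate.
#'
#' @param truth a `ground_truth`.
#' @param design the `study_design` used to generate it.
#' @param noise_sd response noise sd (log2 fold-change units).
#' @param viability_noise_sd viability noise sd (fraction of control).
#' @param n_replicates viability replicates per condition.
#' @param seed integer seed.
#' @return An object of class `synthetic_dataset`: list with `responses` and
#'   `truth_responses` (named lists of nodes x conditions matrices),
#'   `viability` (long data frame: condition, cell_line, replicate, value),
#'   `viability_true`, `design`.
#' @export
simulate_dataset <- function(truth, design, noise_sd = 0.1,
                             viability_noise_sd = 0.05,
                             n_replicates = 3, seed = 1L) {
  stopifnot(noise_sd >= 0, viability_noise_sd >= 0, n_replicates >= 1)
  lines <- truth$cell_lines
  withr::with_seed(seed, {
    responses <- truth_responses <- list()
    viability_true <- list()
    viab_rows <- list()
    for (line in lines) {
      S <- build_s_matrix(truth, design, line)
      R0 <- simulate_response(truth$r[[line]], S)
      truth_responses[[line]] <- R0
      responses[[line]] <- R0 +
        matrix(stats::rnorm(length(R0), 0, noise_sd), nrow(R0), ncol(R0))
      dimnames(responses[[line]]) <- dimnames(R0)

      vn <- truth$viability_nodes
      v0 <- predict_viability("4c", list(K = truth$K_M[[line]]),
                              R_AKT = R0[vn[["AKT"]], ],
                              R_ERK = R0[vn[["ERK"]], ])
      viability_true[[line]] <- v0
      for (rep in seq_len(n_replicates)) {
        viab_rows[[length(viab_rows) + 1L]] <- data.frame(
          condition = names(v0), cell_line = line, replicate = rep,
          value = pmax(0, v0 + stats::rnorm(length(v0), 0, viability_noise_sd)))
      }
    }
    viability <- do.call(rbind, viab_rows)
    rownames(viability) <- NULL
    structure(list(responses = responses, truth_responses = truth_responses,
                   viability = viability, viability_true = viability_true,
                   design = design, noise_sd = noise_sd,
                   viability_noise_sd = viability_noise_sd, seed = seed),
              class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset (and its provenance) to a directory
#'
#' Response matrices as one TSV per cell line, viability as a long TSV,
#' design and ground truth as JSON.
#'
#' @param dataset a `synthetic_dataset`.
#' @param truth the generating `ground_truth`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (line in names(dataset$responses)) {
    write_response_matrix(dataset$responses[[line]],
                          file.path(dir, paste0("responses_", line, ".tsv")))
  }
  utils::write.table(dataset$viability, file.path(dir, "viability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  design <- dataset$design
  jsonlite::write_json(
    list(nodes = design$nodes, drugs = design$drugs,
         dose_levels = design$dose_levels,
         single_dose_drugs = design$single_dose_drugs,
         conditions = lapply(design$conditions, function(x) x),
         cell_lines = design$cell_lines, seed = design$seed),
    file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(nodes = truth$nodes, cell_lines = truth$cell_lines,
         edges = truth$edges,
         r = lapply(truth$r, function(m) as.data.frame(m)),
         s_spec = truth$s_spec, planted_diffs = truth$planted_diffs,
         target_map = truth$target_map, K_M = truth$K_M,
         viability_nodes = as.list(truth$viability_nodes), seed = truth$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
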