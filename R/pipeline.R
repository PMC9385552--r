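# The end-to-end pipeline: synthetic data (or user tables) -> comparative
# network reconstruction -> optional null ensemble -> viability model ->
# dose curves -> combination optimization -> power analysis.

#' Run the full prioritization pipeline
#'
#' In synthetic mode a ground truth is generated and a noisy dataset
#' simulated; otherwise response and viability tables are read from the
#' configured paths. Reconstruction uses the prior topology (plus
#' cross-validation-selected edges when `cv` is enabled), the viability model
#' is the Michaelis-Menten-like form (with the full model comparison run when
#' `compare_forms`), dose curves are interpolated from the fitted anchors,
#' all drug triples are optimized for the configured direction, control
#' dosings are selected for the filtered set, and the power analysis compares
#' the two groups. All artifacts are written under `out_dir` together with a
#' manifest (seeds, package version, input hashes).
#'
#' @param config named list (or path to a YAML file) with optional entries:
#'   `synthetic` (logical, default TRUE), `seed`, `out_dir`, `nodes`,
#'   `edges`, `diffs`, `noise_sd`, `viability_noise_sd`, `combo_count`,
#'   `eta`, `theta`, `cv` (logical), `eta_grid`, `theta_grid`, `nulls`
#'   (logical), `null_models`, `direction`, `v_min`,
#'   `anti_selectivity_floor`, `compare_forms` (logical), `power_noise_sd`,
#'   `power_sims`, and in non-synthetic mode `responses` (named list of TSV
#'   paths per cell line), `viability` (TSV path), `prior` (edge TSV path).
#' @return Invisibly, a list bundle of all stage results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    synthetic = TRUE, seed = 1L, out_dir = tempfile("combonet_run_"),
    nodes = 9, edges = NULL, diffs = 3, combo_count = 17,
    noise_sd = 0.1, viability_noise_sd = 0.05, replicates = 3,
    eta = 0.1, theta = 2.0, cv = FALSE,
    eta_grid = c(0.05, 0.1, 0.2), theta_grid = c(0.5, 2, 8),
    nulls = FALSE, null_models = 200, null_edges = NULL,
    direction = "anti_selective", v_min = 0.8,
    anti_selectivity_floor = 0.1, compare_forms = FALSE,
    power_noise_sd = 0.25, power_sims = 1000, planted = NULL
  ), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  log_lines <- c(paste0("combonet ", as.character(utils::packageVersion("combonet")),
                        " | seed = ", seed))
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  bundle <- list(config = cfg)

  # --- inputs ---------------------------------------------------------------
  if (isTRUE(cfg$synthetic)) {
    say("stage synth: generating design, truth and dataset")
    design <- make_study_design(combo_count = cfg$combo_count,
                                seed = sub_seed(seed, "design"))
    prior <- default_prior_network()
    planted <- cfg$planted
    if (!is.null(planted)) planted <- as.data.frame(planted)
    truth <- generate_ground_truth(design,
                                   n_diffs = cfg$diffs,
                                   edges = if (is.null(cfg$edges)) prior else cfg$edges,
                                   planted = planted,
                                   seed = sub_seed(seed, "truth"))
    dataset <- simulate_dataset(truth, design, noise_sd = cfg$noise_sd,
                                viability_noise_sd = cfg$viability_noise_sd,
                                n_replicates = cfg$replicates,
                                seed = sub_seed(seed, "data"))
    write_synthetic_dataset(dataset, truth, file.path(cfg$out_dir, "synthetic"))
    responses <- dataset$responses
    viability <- dataset$viability
    map <- truth$target_map
    bundle$design <- design; bundle$truth <- truth; bundle$dataset <- dataset
  } else {
    if (is.null(cfg$responses)) stop("stage input: config$responses is required")
    responses <- lapply(cfg$responses, read_response_matrix)
    prior <- if (is.null(cfg$prior)) default_prior_network()
             else utils::read.table(cfg$prior, sep = "\t", header = TRUE)
    design <- make_study_design(combo_count = cfg$combo_count, seed = seed)
    map <- default_drug_target_map(prior)
    viability <- if (is.null(cfg[["viability"]])) NULL
                 else read_viability_table(cfg[["viability"]])
    bundle$design <- design
  }

  # --- reconstruction -------------------------------------------------------
  say("stage reconstruct: comparative network reconstruction")
  topology <- prior
  if (isTRUE(cfg$cv)) {
    cv <- cnr_loocv(responses, prior, map, cfg$eta_grid, cfg$theta_grid)
    topology <- rbind(prior, cv$added_edges)
    cfg$eta <- cv$hyperparams$eta; cfg$theta <- cv$hyperparams$theta
    bundle$cv <- cv
    say("  selected eta = ", cfg$eta, ", theta = ", cfg$theta,
        ", added edges = ", nrow(cv$added_edges))
  }
  fit <- cnr_final_model(responses, topology, theta = cfg$theta,
                         drug_target_map = map, eta = cfg$eta)
  write_cnr_result(fit, file.path(cfg$out_dir, "network_model.json"))
  say("  objective = ", format(fit$objective, digits = 6),
      ", fit correlation = ", format(fit$fit_cor, digits = 3),
      ", differences = ", fit$n_differences)
  bundle$fit <- fit

  if (isTRUE(cfg$nulls)) {
    say("stage nulls: random-topology ensemble (n = ", cfg$null_models, ")")
    ens <- null_ensemble(responses, topology, map, mode = "random_topology",
                         n_models = cfg$null_models,
                         n_edges = if (is.null(cfg$null_edges)) nrow(topology)
                                   else cfg$null_edges,
                         seed = sub_seed(seed, "nulls"))
    write_null_ensemble(ens, file.path(cfg$out_dir, "null_ensemble"))
    say("  empirical p = ", format(empirical_pvalue(ens), digits = 4))
    bundle$nulls <- ens
  }

  if (is.null(viability)) {
    say("no viability table configured; stopping after reconstruction")
    writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
    return(invisible(bundle))
  }

  # --- viability model ------------------------------------------------------
  say("stage fit-viability: signaling-to-viability model")
  vdata <- assemble_viability_data(responses, viability)
  if (isTRUE(cfg$compare_forms)) {
    fits <- lapply(viability_forms, fit_viability_model, data = vdata)
    comparison <- compare_viability_models(fits)
    utils::write.table(comparison, file.path(cfg$out_dir, "viability_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$viability_comparison <- comparison
    vfit <- fits[[which(vapply(fits, `[[`, "", "form") == "4c")]]
  } else {
    vfit <- fit_viability_model("4c", vdata, loocv = FALSE)
  }
  K_M <- lapply(vfit$params, `[[`, "K")
  say("  K_M: ", paste(vapply(names(K_M), function(g) {
    paste0(g, "(AKT=", format(K_M[[g]][["AKT"]], digits = 3),
           ", ERK=", format(K_M[[g]][["ERK"]], digits = 3), ")")
  }, ""), collapse = " "))
  bundle$viability_fit <- vfit

  # --- dose curves ----------------------------------------------------------
  say("stage dose-fit: inhibition-vs-concentration curves")
  dose <- fit_dose_params(fit, design)
  write_dose_params(dose, file.path(cfg$out_dir, "dose_params.tsv"))
  bundle$dose <- dose

  # --- combination optimization --------------------------------------------
  say("stage optimize: ranking all drug triples (", cfg$direction, ")")
  model <- combo_model(fit$r, dose, K_M, design = design)
  ranked <- rank_all_triples(model, direction = cfg$direction,
                             v_min = cfg$v_min,
                             anti_selectivity_floor = cfg$anti_selectivity_floor)
  utils::write.table(ranked, file.path(cfg$out_dir, "ranked_combos.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- attr(ranked, "filtered")
  say("  ", nrow(hits), " triple(s) above the ",
      cfg$anti_selectivity_floor, " floor")
  bundle$model <- model; bundle$ranked <- ranked

  # --- controls + power -----------------------------------------------------
  n_ctrl <- min(nrow(hits), max(3, nrow(hits)))
  if (nrow(hits) >= 1) {
    say("stage controls: non-selective control dosings")
    ctrl <- lapply(seq_len(n_ctrl), function(k) {
      select_controls(model, unlist(hits[k, c("drug1", "drug2", "drug3")]))
    })
    ctrl_sel <- vapply(ctrl, function(p) {
      if (cfg$direction == "anti_selective") p$anti_selectivity else p$selectivity
    }, 1)
    score <- if (cfg$direction == "anti_selective") hits$anti_selectivity
             else hits$selectivity
    say("stage power: group power analysis")
    power <- power_analysis(score, ctrl_sel,
                            noise_sd = cfg$power_noise_sd,
                            n_sims = cfg$power_sims,
                            seed = sub_seed(seed, "power"))
    say("  estimated power = ", format(power, digits = 3))
    bundle$controls <- ctrl
    bundle$power <- power
  } else {
    say("no combinations passed the floor; skipping controls and power")
  }

  # --- manifest -------------------------------------------------------------
  arts <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  arts <- arts[!grepl("manifest.json$|run.log$", arts)]
  manifest <- list(
    package = "combonet",
    version = as.character(utils::packageVersion("combonet")),
    seed = seed,
    stage_seeds = list(design = sub_seed(seed, "design"),
                       truth = sub_seed(seed, "truth"),
                       data = sub_seed(seed, "data"),
                       nulls = sub_seed(seed, "nulls"),
                       power = sub_seed(seed, "power")),
    artifacts = stats::setNames(as.list(unname(tools::md5sum(arts))),
                                basename(arts)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(bundle)
}
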