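# cnr: problem construction, exact MIQP solve, hyperparameter selection

test_that("candidate edge accounting: 9 nodes give 72 ordered pairs", {
  w <- default_world(seed = 2, n_diffs = 0)
  prob <- build_cnr_problem(w$dataset$responses, w$prior, w$map,
                            candidates = "all")
  expect_equal(nrow(prob$cand), 72)
  expect_equal(sum(prob$cand$prior), nrow(w$prior))
  # prior-only mode exposes no free topology indicators
  prob2 <- build_cnr_problem(w$dataset$responses, w$prior, w$map,
                             candidates = "prior")
  expect_equal(nrow(prob2$cand), nrow(w$prior))
  expect_true(all(prob2$cand$prior))
})

test_that("problem construction validates drugs and conditions", {
  w <- small_world()
  expect_error(
    build_cnr_problem(w$dataset$responses, w$prior,
                      list(D1 = "N1", D2 = "N2", D3 = "ABSENT")),
    "no mappable target")
  R_bad <- lapply(w$dataset$responses, function(R) {
    colnames(R)[1] <- "Dx@IC50"; R
  })
  expect_error(build_cnr_problem(R_bad, w$prior, w$map), "unknown drug")
})

test_that("MIQP optimum matches exhaustive indicator enumeration", {
  # 3-node instances, free candidate topology + difference indicators
  nodes <- c("N1", "N2", "N3")
  map <- list(D1 = "N1", D2 = "N2")
  design <- make_study_design(nodes = nodes, drugs = c("D1", "D2"),
                              combo_count = 1,
                              single_dose_drugs = character(0),
                              seed = 1)
  prior <- data.frame(source = "N1", target = "N2")
  cand <- rbind(prior, data.frame(source = c("N2", "N1", "N3"),
                                  target = c("N3", "N3", "N1")))
  for (seed in c(4, 11)) {
    truth <- generate_ground_truth(design, n_diffs = 1, seed = seed,
                                   edges = prior[, 1:2], target_map = map,
                                   viability_nodes = c(AKT = "N1", ERK = "N2"))
    ds <- simulate_dataset(truth, design, noise_sd = 0.15, seed = seed)
    for (hp in list(c(0.05, 0.5), c(0.2, 2))) {
      prob <- build_cnr_problem(ds$responses, prior, map, eta = hp[1],
                                theta = hp[2], candidates = cand)
      fit <- solve_cnr(prob)
      expect_equal(fit$objective, enum_cnr_oracle(prob), tolerance = 1e-6)
    }
  }
})

test_that("big-M and indicator encodings agree", {
  w <- small_world(noise_sd = 0.1)
  for (th in c(1, Inf)) {
    p1 <- build_cnr_problem(w$dataset$responses, w$prior, w$map, eta = 0.1,
                            theta = th, candidates = "all", encoding = "indicator")
    p2 <- build_cnr_problem(w$dataset$responses, w$prior, w$map, eta = 0.1,
                            theta = th, candidates = "all", encoding = "bigM")
    f1 <- solve_cnr(p1); f2 <- solve_cnr(p2)
    expect_true(max(abs(unlist(f1$r)), abs(f1$s$value)) < 9) # interior to B
    expect_equal(f1$objective, f2$objective, tolerance = 1e-6)
  }
})

test_that("optimal objective is monotone in the penalties", {
  w <- small_world(noise_sd = 0.1)
  obj <- function(eta, theta) {
    solve_cnr(build_cnr_problem(w$dataset$responses, w$prior, w$map,
                                eta = eta, theta = theta,
                                candidates = "all"))$objective
  }
  o <- c(obj(0.01, 0.5), obj(0.1, 0.5), obj(0.5, 0.5))
  expect_true(all(diff(o) >= -1e-9))
  o2 <- c(obj(0.1, 0.1), obj(0.1, 1), obj(0.1, Inf))
  expect_true(all(diff(o2) >= -1e-9))
})

test_that("noiseless single-line fit recovers the generative network", {
  w <- default_world(seed = 7, n_diffs = 0, noise_sd = 0)
  fit <- cnr_final_model(w$dataset$responses["parental"], w$prior,
                         theta = Inf, drug_target_map = w$map, eta = 0.01)
  expect_lt(max(abs(fit$r[[1]] - w$truth$r[["parental"]])), 1e-4)
  # and the fitted s values match the generative ones
  lk_fit <- combonet:::s_lookup(fit$s)
  s1 <- w$truth$s_spec[w$truth$s_spec$cell_line == "parental", ]
  keys <- combonet:::s_key(s1$drug, s1$dose, s1$target, s1$cell_line)
  expect_lt(max(abs(lk_fit[keys] - s1$value)), 1e-4)
})

test_that("identical cell lines yield no difference indicators", {
  w <- small_world(n_diffs = 0, noise_sd = 0.05)
  # both lines literally the same data
  R <- list(parental = w$dataset$responses$parental,
            mutant = w$dataset$responses$parental)
  fit <- cnr_final_model(R, w$prior, theta = 0.5, drug_target_map = w$map)
  expect_equal(fit$n_differences, 0)
  expect_equal(fit$r$parental, fit$r$mutant)
})

test_that("theta sweep recovers the planted difference set exactly", {
  w <- small_world(seed = 42, n_diffs = 2, noise_sd = 0)
  chosen <- NULL
  for (th in c(8, 2, 0.5, 0.1, 0.02)) {
    fit <- cnr_final_model(w$dataset$responses, w$prior, theta = th,
                           drug_target_map = w$map, eta = 0.1)
    if (sum(unlist(fit$residuals)^2) < 1e-8) { chosen <- fit; break }
  }
  expect_false(is.null(chosen))
  planted <- w$truth$planted_diffs
  got_edges <- chosen$edges[chosen$edges$diff, c("source", "target")]
  want_edges <- planted[planted$kind == "edge", c("source", "target")]
  expect_setequal(paste(got_edges$source, got_edges$target),
                  paste(want_edges$source, want_edges$target))
  got_sd <- chosen$sdiffs[chosen$sdiffs$active, c("drug", "target")]
  want_sd <- planted[planted$kind == "perturbation", c("source", "target")]
  expect_setequal(paste(got_sd$drug, got_sd$target),
                  paste(want_sd$source, want_sd$target))
})

test_that("solved s values respect the dose-ordering constraints", {
  w <- small_world(noise_sd = 0.2)
  fit <- cnr_final_model(w$dataset$responses, w$prior, theta = 1,
                         drug_target_map = w$map)
  sp <- split(fit$s, paste(fit$s$drug, fit$s$target, fit$s$cell_line))
  for (grp in sp) {
    v <- stats::setNames(grp$value, grp$dose)
    expect_true(all(v <= -1e-6 + 1e-12))
    if (all(c("IC50", "IC90") %in% names(v))) {
      expect_lte(v[["IC90"]], v[["IC50"]] - 1e-6 + 1e-12)
    }
  }
})

test_that("LOOCV selects sensible hyperparameters and echoes the grid", {
  w <- small_world(seed = 13, n_diffs = 1, noise_sd = 0.05)
  # single grid point: returned as-is (the study's defaults)
  res1 <- cnr_loocv(w$dataset$responses, w$prior, w$map,
                    eta_grid = 0.1, theta_grid = 2.0)
  expect_equal(res1$hyperparams, list(eta = 0.1, theta = 2.0))
  expect_equal(nrow(res1$cv_errors), 1)

  # noiseless world: the penalized model's held-out error should not lose to
  # the unpenalized full-candidate fit
  w0 <- small_world(seed = 13, n_diffs = 1, noise_sd = 0)
  res <- cnr_loocv(w0$dataset$responses, w0$prior, w0$map,
                   eta_grid = c(0, 0.1), theta_grid = c(0.05, Inf))
  tab <- res$cv_errors
  err_sel <- min(tab$cv_error)
  err_full <- tab$cv_error[tab$eta == 0][which.max(tab$theta[tab$eta == 0])]
  expect_lte(err_sel, err_full + 1e-12)
  expect_error(cnr_loocv(w$dataset$responses, w$prior, w$map,
                         eta_grid = numeric(0), theta_grid = 1), "empty")
})

test_that("fit quality reporting is present", {
  w <- small_world(noise_sd = 0.1)
  fit <- cnr_final_model(w$dataset$responses, w$prior, theta = 2,
                         drug_target_map = w$map)
  expect_true(is.finite(fit$fit_cor) && abs(fit$fit_cor) <= 1)
  expect_identical(fit$status, "optimal")
  # JSON export round-trips the essentials
  path <- withr::local_tempfile(fileext = ".json")
  write_cnr_result(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$objective, fit$objective, tolerance = 1e-10)
})
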