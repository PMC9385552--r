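# combos: simulation, constrained optimization, ranking, power, validation

# full pipeline objects for the default 9-node world, built once
combo_fixture <- local({
  cache <- NULL
  function(noise_sd = 0) {
    if (!is.null(cache)) return(cache)
    w <- default_world(seed = 7, n_diffs = 3, noise_sd = noise_sd,
                       planted = data.frame(kind = "perturbation",
                                            source = "IGF1Ri", target = "AKT1",
                                            multiplier = 0.25))
    fit <- cnr_final_model(w$dataset$responses, w$prior, theta = 0.05,
                           drug_target_map = w$map, eta = 0.1)
    dose <- fit_dose_params(fit, w$design)
    model <- combo_model(fit$r, dose, w$truth$K_M, design = w$design)
    cache <<- list(w = w, fit = fit, dose = dose, model = model)
    cache
  }
})

test_that("zero concentration gives vehicle viability in both lines", {
  fx <- combo_fixture()
  p <- simulate_combo(fx$model, c("EGFRi", "MEKi", "AKTi"),
                      c(EGFRi = 0, MEKi = 0, AKTi = 0))
  expect_equal(unname(p$v), c(1, 1))
  expect_equal(p$selectivity, 0)
  expect_equal(p$anti_selectivity, 0)
})

test_that("identical line models give zero selectivity at any dose", {
  fx <- combo_fixture()
  m <- fx$model
  sym <- combo_model(list(parental = m$r$parental, mutant = m$r$parental),
                     m$dose_params[m$dose_params$cell_line == "parental", ] |>
                       (\(d) rbind(d, transform(d, cell_line = "mutant")))(),
                     list(parental = m$K_M$parental, mutant = m$K_M$parental),
                     conc_cap = m$conc_cap)
  p <- simulate_combo(sym, c("EGFRi", "MEKi", "AKTi"),
                      c(EGFRi = 0.01, MEKi = 0.005, AKTi = 0.009))
  expect_equal(p$selectivity, 0, tolerance = 1e-12)
  opt <- optimize_selectivity(sym, c("EGFRi", "MEKi", "AKTi"))
  expect_equal(opt$selectivity, 0, tolerance = 1e-9)
})

test_that("a trained two-drug condition is reproduced from the fitted pieces", {
  # noiseless world; dose anchors and K_M taken at the generative truth
  fx <- combo_fixture()
  w <- fx$w
  combos <- names(w$design$conditions)[
    vapply(w$design$conditions, nrow, 1L) == 2L]
  cid <- combos[1]
  trt <- w$design$conditions[[cid]]
  conc <- stats::setNames(
    vapply(trt$drug, function(d) w$design$dose_levels[[d]][["IC50"]], 1),
    trt$drug)
  p <- simulate_combo(fx$model, trt$drug, conc)
  for (line in w$truth$cell_lines) {
    expect_equal(unname(p$v[line]), unname(w$dataset$viability_true[[line]][cid]),
                 tolerance = 1e-6)
  }
})

test_that("optimizer matches the dense-grid oracle and respects constraints", {
  fx <- combo_fixture()
  triples <- list(c("EGFRi", "IGF1Ri", "PI3Ki"),
                  c("MEKi", "ERKi", "AKTi"),
                  c("IGF1Ri", "GSK3i", "mTORi"))
  for (tri in triples) {
    opt <- optimize_selectivity(fx$model, tri, direction = "anti_selective")
    grid <- grid_search_combo(fx$model, tri, n_grid = 21,
                              direction = "anti_selective")
    expect_lte(attr(opt, "objective"), grid$objective + 1e-4)
    # box and protected-line floor respected
    caps <- vapply(tri, function(d) fx$model$conc_cap[[d]], 1)
    expect_true(all(opt$conc >= -1e-12 & opt$conc <= caps + 1e-12))
    expect_gte(unname(opt$v["mutant"]), 0.8 - 1e-6)
  }
})

test_that("a drug hitting only one line's AKT is pushed to its cap", {
  fx <- combo_fixture()
  m <- fx$model
  dp <- m$dose_params
  # cripple IGF1Ri in the mutant entirely: no direct effect at any dose
  dp$Imax[dp$drug == "IGF1Ri" & dp$cell_line == "mutant"] <- -1e-9
  m2 <- combo_model(m$r, dp, m$K_M, conc_cap = m$conc_cap)
  opt <- optimize_selectivity(m2, c("IGF1Ri", "MEKi", "GSK3i"),
                              direction = "anti_selective")
  expect_equal(unname(opt$conc[["IGF1Ri"]]), m$conc_cap[["IGF1Ri"]],
               tolerance = 1e-6)
})

test_that("control selection matches its grid oracle; zero-effect edge case", {
  fx <- combo_fixture()
  tri <- c("EGFRi", "MEKi", "PI3Ki")
  ctrl <- select_controls(fx$model, tri)
  grid <- grid_search_combo(fx$model, tri, n_grid = 21, direction = "control")
  expect_lte(attr(ctrl, "objective"), grid$objective + 1e-4)

  dp <- fx$model$dose_params
  dp$Imax <- -1e-12 # drugs do essentially nothing
  m0 <- combo_model(fx$model$r, dp, fx$model$K_M, conc_cap = fx$model$conc_cap)
  c0 <- select_controls(m0, tri)
  expect_equal(attr(c0, "objective"), 2 * (1 - 0.8)^2, tolerance = 1e-6)
})

test_that("ranking evaluates every triple and applies the floor", {
  fx <- combo_fixture()
  ranked <- rank_all_triples(fx$model, direction = "anti_selective",
                             anti_selectivity_floor = 0.1)
  expect_equal(nrow(ranked), choose(9, 3))
  expect_true(all(ranked$status == "ok"))
  expect_true(!is.unsorted(rev(ranked$anti_selectivity)))
  # the planted anti-selective drug dominates the top of the list
  expect_true("IGF1Ri" %in% unlist(ranked[1, c("drug1", "drug2", "drug3")]))
  empty <- rank_all_triples(fx$model, direction = "anti_selective",
                            anti_selectivity_floor = Inf)
  expect_equal(nrow(attr(empty, "filtered")), 0)
})

test_that("power analysis is calibrated under the null and saturates", {
  zero <- rep(0, 30)
  p0 <- power_analysis(zero, rep(0, 44), noise_sd = 0.25, n_sims = 1000, seed = 3)
  expect_lt(abs(p0 - 0.05), 0.02)
  p1 <- power_analysis(rep(5 * 0.25, 30), rep(0, 44), noise_sd = 0.25,
                       n_sims = 200, seed = 3)
  expect_gte(p1, 0.99)
  expect_identical(power_analysis(zero, zero, n_sims = 50, seed = 9),
                   power_analysis(zero, zero, n_sims = 50, seed = 9))
  expect_error(power_analysis(numeric(0), zero), "non-empty")
})

test_that("search-space sizes match direct combinatorial computation", {
  expect_equal(search_space_size(89, 4, 1), 2441626)
  expect_equal(search_space_size(89, 4, 10), 24416260000)
  expect_equal(search_space_size(3, 3, 1), 1)
  expect_equal(search_space_size(9, 3, 1), 84)
})

test_that("validation statistics separate planted groups and die under permutation", {
  withr::with_seed(21, {
    combos <- paste0("combo", 1:12)
    truthy <- rep(c(0.25, 0), each = 6) # 6 anti-selective, 6 null combos
    rows <- list()
    for (i in seq_along(combos)) {
      for (rep in 1:8) {
        vp <- 0.7 + stats::rnorm(1, 0, 0.01)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = combos[i], cell_line = c("parental", "mutant"),
          replicate = rep, value = c(vp, vp + truthy[i] + stats::rnorm(1, 0, 0.01)))
      }
    }
    viab <- do.call(rbind, rows)
  })
  groups <- data.frame(condition = combos,
                       group = rep(c("anti", "control"), each = 6))
  st <- validation_stats(viab, groups, reference = 0.05)
  anti <- st$per_combo[st$per_combo$group == "anti", ]
  expect_true(all(anti$p_vs_zero < 0.05))
  expect_true(all(anti$p_vs_reference < 0.05))
  expect_lt(st$group_test$p.value, 0.01)
  # permuting group labels destroys the group difference
  withr::with_seed(4, {
    groups_perm <- groups
    groups_perm$group <- sample(groups_perm$group)
  })
  st_perm <- validation_stats(viab, groups_perm)
  expect_gt(st_perm$group_test$p.value, 0.05)
  # too few replicates -> warning, tests skipped
  tiny <- viab[viab$replicate == 1, ]
  warns <- testthat::capture_warnings(validation_stats(tiny, groups))
  expect_true(all(grepl("fewer than 2", warns)) && length(warns) > 0)
})
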