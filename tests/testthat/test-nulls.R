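# nulls: randomization ensembles and the empirical p value

test_that("empirical p value follows the add-one convention", {
  ens <- list(rms_values = rep(1, 1000), reference_rms = 0.5)
  expect_equal(empirical_pvalue(ens), 1 / 1001) # 0 of 1000 beat the reference
  expect_lt(empirical_pvalue(ens), 0.001)
  ens$reference_rms <- 2
  expect_equal(empirical_pvalue(ens), 1) # k = n
  # brute-force count oracle on a fixed list (ties count toward k)
  vals <- c(0.2, 0.5, 0.5, 0.9, 1.3)
  ref <- 0.5
  k <- sum(vals <= ref)
  expect_equal(empirical_pvalue(list(rms_values = vals, reference_rms = ref)),
               (k + 1) / (length(vals) + 1))
})

test_that("random-topology nulls are beaten by the true topology (noiseless)", {
  w <- small_world(seed = 8, n_diffs = 0, noise_sd = 0)
  ens <- null_ensemble(w$dataset$responses, w$prior, w$map,
                       mode = "random_topology", n_models = 30,
                       n_edges = nrow(w$prior), seed = 5)
  expect_length(ens$rms_values, 30)
  expect_lte(ens$reference_rms, min(ens$rms_values) + 1e-10)
  expect_lt(ens$reference_rms, 1e-7)
  # reproducibility
  ens2 <- null_ensemble(w$dataset$responses, w$prior, w$map,
                        mode = "random_topology", n_models = 30,
                        n_edges = nrow(w$prior), seed = 5)
  expect_identical(ens$rms_values, ens2$rms_values)
  expect_error(
    null_ensemble(w$dataset$responses, w$prior, w$map,
                  mode = "random_topology", n_models = 2, n_edges = 100),
    "exceeds")
})

test_that("single-model and identity-permutation degenerate cases", {
  w <- small_world(seed = 8, noise_sd = 0.1)
  ens <- null_ensemble(w$dataset$responses, w$prior, w$map,
                       mode = "random_topology", n_models = 1,
                       n_edges = nrow(w$prior), seed = 2)
  expect_length(ens$rms_values, 1)

  # a 1-node world admits only the identity permutation
  d1 <- make_study_design(nodes = "N1", drugs = "D1", combo_count = 0,
                          single_dose_drugs = character(0), seed = 1)
  t1 <- generate_ground_truth(d1, n_diffs = 0, seed = 1,
                              edges = data.frame(source = character(),
                                                 target = character()),
                              target_map = list(D1 = "N1"),
                              viability_nodes = c(AKT = "N1", ERK = "N1"))
  ds1 <- simulate_dataset(t1, d1, noise_sd = 0.1, seed = 2)
  e1 <- null_ensemble(ds1$responses, t1$edges, list(D1 = "N1"),
                      mode = "node_permutation", n_models = 5, seed = 3)
  expect_true(all(abs(e1$rms_values - e1$reference_rms) < 1e-12))
})

test_that("random-differences mode fixes exactly the requested indicators", {
  w <- small_world(seed = 8, n_diffs = 2, noise_sd = 0.05)
  ens <- null_ensemble(w$dataset$responses, w$prior, w$map,
                       mode = "random_differences", n_models = 10,
                       n_diffs = 2, theta = 1, seed = 4)
  expect_length(ens$rms_values, 10)
  expect_true(all(ens$rms_values >= 0))
  # the reference (no differences allowed) cannot beat a model granted
  # free differences on the true topology
  expect_gte(ens$reference_rms, min(ens$rms_values) - 1e-9)
})

test_that("node permutation of a label-symmetric world leaves RMS law unchanged", {
  # symmetric truth: empty topology and every drug perturbing every node with
  # the same strength, so the rows of the data are exchangeable and node
  # labels carry no information
  nodes <- c("N1", "N2", "N3")
  map <- list(D1 = nodes, D2 = nodes, D3 = nodes)
  design <- make_study_design(nodes = nodes, drugs = names(map),
                              combo_count = 0,
                              single_dose_drugs = character(0), seed = 1)
  empty <- data.frame(source = character(), target = character())
  base_truth <- generate_ground_truth(design, n_diffs = 0, seed = 1,
                                      edges = empty, target_map = map,
                                      viability_nodes = c(AKT = "N1", ERK = "N2"))
  # equalize perturbation strengths across drugs to make labels exchangeable
  sym <- base_truth
  for (l in c("IC50", "IC90")) {
    v <- sym$s_spec$value[sym$s_spec$dose == l][1]
    sym$s_spec$value[sym$s_spec$dose == l] <- v
  }
  n <- 200
  ref_rms <- perm_rms <- numeric(n)
  for (i in seq_len(n)) {
    ds <- simulate_dataset(sym, design, noise_sd = 0.1, seed = 1000 + i)
    ens <- null_ensemble(ds$responses, empty, map, mode = "node_permutation",
                         n_models = 1, seed = i)
    ref_rms[i] <- ens$reference_rms
    perm_rms[i] <- ens$rms_values[1]
  }
  ks <- suppressWarnings(stats::ks.test(ref_rms, perm_rms))
  expect_gt(ks$p.value, 0.01)
})

test_that("ensembles serialize to TSV + JSON", {
  w <- small_world(seed = 8, noise_sd = 0.1)
  ens <- null_ensemble(w$dataset$responses, w$prior, w$map,
                       mode = "random_topology", n_models = 3,
                       n_edges = 2, seed = 9)
  prefix <- file.path(withr::local_tempdir(), "ens")
  write_null_ensemble(ens, prefix)
  tab <- utils::read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(tab$rms, ens$rms_values, tolerance = 1e-12)
  js <- jsonlite::read_json(paste0(prefix, "_summary.json"))
  expect_equal(js$p_value, empirical_pvalue(ens), tolerance = 1e-12)
})
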