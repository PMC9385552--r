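# viability: the six signaling-to-viability model forms

# condition-level data generated exactly from the Michaelis-Menten-like model
eq1_data <- function(n = 34, K = c(AKT = 1.5, ERK = 2.0), noise_sd = 0,
                     seed = 1, cell_line = "x") {
  withr::with_seed(seed, {
    RA <- -stats::runif(n, 0, 3)
    RE <- -stats::runif(n, 0, 3)
    v <- predict_viability("4c", list(K = K), RA, RE) +
      stats::rnorm(n, 0, noise_sd)
  })
  data.frame(condition = paste0("c", seq_len(n)), cell_line = cell_line,
             v = v, R_AKT = RA, R_ERK = RE)
}

test_that("all six forms return v = 1 at zero response", {
  K <- list(K = c(AKT = 1.7, ERK = 0.9))
  for (form in c("4c", "4d", "4e", "4f")) {
    expect_equal(predict_viability(form, K, R_AKT = 0, R_ERK = 0), 1,
                 info = form)
  }
  expect_equal(predict_viability("4b", list(beta = c(AKT = 0.3, ERK = -0.2)),
                                 R_AKT = 0, R_ERK = 0), 1)
  Rn <- matrix(0, 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  expect_equal(predict_viability("4a", list(beta = c(A = 1, B = 2, C = 3)),
                                 R_nodes = Rn), 1)
})

test_that("half-effect semantics of the nonlinear forms", {
  K <- c(AKT = 2.3, ERK = 0.7) # arbitrary positive values
  expect_equal(predict_viability("4c", list(K = K), R_AKT = -K[["AKT"]],
                                 R_ERK = 0), 0.5)
  expect_equal(predict_viability("4d", list(K = K), R_AKT = -K[["AKT"]],
                                 R_ERK = 0), 0.5)
  expect_equal(predict_viability("4e", list(K = K), R_AKT = 0,
                                 R_ERK = -K[["ERK"]]), 0.75)
  expect_equal(predict_viability("4f", list(K = K), R_AKT = 0,
                                 R_ERK = -K[["ERK"]]), 2 / 3)
})

test_that("form-4c domain and monotonicity", {
  K <- list(K = c(AKT = 1, ERK = 1))
  expect_error(predict_viability("4c", K, R_AKT = 3, R_ERK = 0),
               "denominator")
  expect_error(predict_viability("4c", list(K = c(AKT = -1, ERK = 1)),
                                 R_AKT = 0, R_ERK = 0), "positive")
  R <- seq(-6, 0, length.out = 50)
  v <- predict_viability("4c", K, R_AKT = R, R_ERK = 0)
  expect_true(all(diff(v) > 0)) # strictly increasing toward vehicle
  expect_true(all(v > 0 & v <= 1))
})

test_that("noiseless generative data recover K_M to 1e-6", {
  dat <- eq1_data(noise_sd = 0)
  fit <- fit_viability_model("4c", dat, loocv = FALSE)
  expect_equal(unname(fit$params$x$K), c(1.5, 2.0), tolerance = 1e-6)
  expect_lt(fit$sigma, 1e-7)
})

test_that("flat data give zero coefficients for the linear form", {
  dat <- data.frame(condition = paste0("c", 1:10), cell_line = "x",
                    v = rep(1, 10), R_AKT = rep(0, 10), R_ERK = rep(0, 10))
  fit <- fit_viability_model("4b", dat, loocv = FALSE)
  expect_equal(unname(fit$params$x$beta), c(0, 0))
})

test_that("model comparison reproduces the expected ordering on generative data", {
  # two cell lines with slightly different K, modest noise
  dat <- rbind(eq1_data(34, c(AKT = 1.5, ERK = 2.0), 0.05, 11, "parental"),
               eq1_data(34, c(AKT = 1.8, ERK = 2.4), 0.05, 12, "mutant"))
  nodecols <- data.frame(R_CREB1 = stats::rnorm(nrow(dat), 0, 0.1))
  dat <- cbind(dat, nodecols)
  fits <- lapply(c("4b", "4c", "4d", "4e", "4f"), fit_viability_model,
                 data = dat, start_grid = c(1, 2))
  tab <- compare_viability_models(fits)
  expect_equal(nrow(tab), 5)
  loocv <- stats::setNames(tab$loocv_l2, tab$form)
  # the generative form beats the bivariate linear model...
  expect_lt(loocv[["4c"]], loocv[["4b"]])
  # ...and every nonlinear form outranks the linear ones
  expect_true(max(loocv[c("4c", "4d", "4e", "4f")]) < loocv[["4b"]])
  # nonlinear predictions are strongly correlated with each other
  cors <- attr(tab, "nonlinear_prediction_cor")
  expect_true(all(cors[upper.tri(cors)] > 0.9))
  # residual-vs-fitted curvature is weaker for the generative form
  f4b <- fits[[1]]; f4c <- fits[[2]]
  expect_lt(abs(f4c$resid_curvature), abs(f4b$resid_curvature))
  # single fit -> single-row table
  expect_equal(nrow(compare_viability_models(fits[2])), 1)
})

test_that("bootstrap CIs are reproducible, tight when noiseless, calibrated", {
  dat0 <- eq1_data(noise_sd = 0)
  fit0 <- fit_viability_model("4c", dat0, loocv = FALSE, start_grid = c(1, 2))
  ci0 <- bootstrap_ci(fit0, n_boot = 100, seed = 4)
  expect_lt(max(ci0$upper - ci0$lower), 1e-4) # degenerate: width ~ 0
  expect_identical(bootstrap_ci(fit0, n_boot = 100, seed = 4), ci0)
  expect_error(bootstrap_ci(fit0, n_boot = 10), "at least 100")

  # coverage, scaled down for runtime (60 replicates / 120 resamples instead
  # of the full 200; the acceptance band is the stated 95% +/- 5 points)
  K_true <- c(AKT = 1.5, ERK = 2.0)
  cover <- 0; reps <- 60
  for (i in seq_len(reps)) {
    dat <- eq1_data(noise_sd = 0.05, seed = 2000 + i)
    fit <- fit_viability_model("4c", dat, loocv = FALSE, start_grid = c(1, 2))
    ci <- bootstrap_ci(fit, n_boot = 120, seed = i)
    hit <- ci$lower[ci$parameter == "K.AKT"] <= K_true[["AKT"]] &&
      ci$upper[ci$parameter == "K.AKT"] >= K_true[["AKT"]]
    cover <- cover + hit
  }
  expect_gte(cover / reps, 0.90)
  expect_lte(cover / reps, 1.00)
})
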