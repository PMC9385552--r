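# Signaling-to-viability models.
#
# Six candidate forms relate the log2 fold changes of pAKT and pERK (all
# nodes for the first) to viability v relative to vehicle:
#   4a  1 - v = sum_i beta_i R_i                       (linear, all nodes)
#   4b  1 - v = beta_AKT R_AKT + beta_ERK R_ERK        (linear)
#   4c  v = 1 / (1 - R_AKT/K_AKT - R_ERK/K_ERK)        (Michaelis-Menten-like)
#   4d  v = 1 / ((1 - R_AKT/K_AKT) (1 - R_ERK/K_ERK))
#   4e  v = 3 / (1 + 2^(-R_ERK/K_ERK) + 2^(-R_AKT/K_AKT))
#   4f  v = 2/(1 + 2^(-R_ERK/K_ERK)) * 2/(1 + 2^(-R_AKT/K_AKT))
# K_M is the magnitude of log2FC producing half-maximal viability inhibition
# for 4c/4d (25% for 4e and 33% for 4f, at one node inhibited and the other
# at vehicle level). All forms give v = 1 at zero response.

viability_forms <- c("4a", "4b", "4c", "4d", "4e", "4f")
linear_forms <- c("4a", "4b")

#' Predict viability from signaling response
#'
#' @param form one of `"4a"`..`"4f"`.
#' @param params for nonlinear forms a list with `K = c(AKT=, ERK=)` (both
#'   positive); for linear forms a list with `beta` (named by predictor).
#' @param R_AKT,R_ERK numeric vectors of log2 fold changes.
#' @param R_nodes for form 4a: matrix/data frame of all node responses
#'   (columns named like `names(params$beta)`).
#' @return Numeric vector of predicted viabilities.
#' @export
predict_viability <- function(form, params, R_AKT = NULL, R_ERK = NULL,
                              R_nodes = NULL) {
  form <- match.arg(form, viability_forms)
  if (form %in% linear_forms) {
    beta <- params$beta
    X <- if (form == "4a") {
      as.matrix(R_nodes)[, names(beta), drop = FALSE]
    } else {
      cbind(AKT = R_AKT, ERK = R_ERK)[, names(beta), drop = FALSE]
    }
    return(as.numeric(1 - X %*% beta))
  }
  K <- params$K
  if (any(K <= 0)) stop("K_M parameters must be positive")
  a <- R_AKT / K[["AKT"]]; e <- R_ERK / K[["ERK"]]
  switch(form,
    "4c" = {
      den <- 1 - a - e
      if (any(den <= 0)) {
        stop("form 4c denominator non-positive (activation exceeding K_M)")
      }
      1 / den
    },
    "4d" = {
      d1 <- 1 - a; d2 <- 1 - e
      if (any(d1 <= 0) || any(d2 <= 0)) {
        stop("form 4d factor denominator non-positive")
      }
      1 / (d1 * d2)
    },
    "4e" = 3 / (1 + 2^(-e) + 2^(-a)),
    "4f" = (2 / (1 + 2^(-e))) * (2 / (1 + 2^(-a)))
  )
}

#' Assemble condition-level viability modeling data
#'
#' Averages viability replicates per (condition, cell line) and joins the
#' node responses.
#'
#' @param responses_by_line named list of response matrices.
#' @param viability long data frame (condition, cell_line, replicate, value).
#' @param viability_nodes named map of roles AKT/ERK to node names.
#' @return Data frame with columns condition, cell_line, v, v_sd, R_AKT,
#'   R_ERK and one `R_<node>` column per node.
#' @export
assemble_viability_data <- function(responses_by_line, viability,
                                    viability_nodes = c(AKT = "AKT1", ERK = "ERK1")) {
  agg <- stats::aggregate(value ~ condition + cell_line, viability, mean)
  sdv <- stats::aggregate(value ~ condition + cell_line, viability, stats::sd)
  agg$v_sd <- sdv$value[match(paste(agg$condition, agg$cell_line),
                              paste(sdv$condition, sdv$cell_line))]
  names(agg)[names(agg) == "value"] <- "v"
  out <- list()
  for (line in names(responses_by_line)) {
    Rm <- responses_by_line[[line]]
    sub <- agg[agg$cell_line == line, , drop = FALSE]
    sub <- sub[sub$condition %in% colnames(Rm), , drop = FALSE]
    node_cols <- t(Rm[, sub$condition, drop = FALSE])
    colnames(node_cols) <- paste0("R_", rownames(Rm))
    sub$R_AKT <- Rm[viability_nodes[["AKT"]], sub$condition]
    sub$R_ERK <- Rm[viability_nodes[["ERK"]], sub$condition]
    out[[line]] <- cbind(sub, node_cols)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# nonlinear SSR in log-K parameterization (guarantees K > 0)
nl_ssr <- function(logk, form, dat) {
  K <- c(AKT = unname(exp(logk[1])), ERK = unname(exp(logk[2])))
  v_hat <- tryCatch(
    predict_viability(form, list(K = K), dat$R_AKT, dat$R_ERK),
    error = function(e) NULL)
  if (is.null(v_hat)) return(1e10)
  sum((dat$v - v_hat)^2)
}

fit_group <- function(form, dat, start_grid) {
  n <- nrow(dat)
  if (form %in% linear_forms) {
    X <- if (form == "4a") {
      # all node columns; R_AKT / R_ERK are the role aliases, not nodes
      cols <- setdiff(grep("^R_", names(dat), value = TRUE), c("R_AKT", "R_ERK"))
      as.matrix(dat[, cols, drop = FALSE])
    } else {
      cbind(R_AKT = dat$R_AKT, R_ERK = dat$R_ERK)
    }
    fit <- stats::lm.fit(X, 1 - dat$v)
    beta <- stats::setNames(fit$coefficients, sub("^R_", "", colnames(X)))
    beta[is.na(beta)] <- 0
    ssr <- sum(fit$residuals^2)
    p <- ncol(X)
    list(params = list(beta = beta), ssr = ssr,
         sigma = sqrt(ssr / max(n - p, 1)))
  } else {
    starts <- as.matrix(expand.grid(log(start_grid), log(start_grid)))
    if (form == "4c") {
      # 1/v - 1 = -R_AKT/K_AKT - R_ERK/K_ERK is linear in the inverse Ks
      co <- tryCatch(stats::lm.fit(cbind(-dat$R_AKT, -dat$R_ERK), 1 / dat$v - 1)$coefficients,
                     error = function(e) c(NA, NA))
      if (all(is.finite(co)) && all(co > 0)) starts <- rbind(starts, -log(co))
    }
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(stats::optim(starts[i, ], nl_ssr, form = form, dat = dat,
                                 method = "Nelder-Mead",
                                 control = list(reltol = 1e-14, maxit = 2000)),
                    error = function(e) NULL)
      if (!is.null(o)) {
        o <- tryCatch(stats::optim(o$par, nl_ssr, form = form, dat = dat,
                                   method = "BFGS",
                                   control = list(reltol = 1e-14, maxit = 500)),
                      error = function(e) o)
      }
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("nonlinear viability fit failed to converge for form ",
                            form, " from every start")
    K <- c(AKT = unname(exp(best$par[1])), ERK = unname(exp(best$par[2])))
    list(params = list(K = K), ssr = best$value,
         sigma = sqrt(best$value / max(n - 2, 1)))
  }
}

predict_group <- function(form, params, dat) {
  predict_viability(form, params,
                    R_AKT = dat$R_AKT, R_ERK = dat$R_ERK,
                    R_nodes = stats::setNames(
                      dat[, paste0("R_", names(params$beta)), drop = FALSE],
                      names(params$beta)))
}

#' Fit a signaling-to-viability model
#'
#' Linear forms are fit by least squares on inhibition (1 - v); nonlinear
#' forms by multi-start nonlinear least squares on v in a log-K
#' parameterization (K > 0 by construction). By default separate parameters
#' are fit per cell line. The leave-one-out metric (one condition held out at
#' a time, per cell line) is the mean squared held-out residual.
#'
#' @param form one of `"4a"`..`"4f"`.
#' @param data condition-level data from [assemble_viability_data()].
#' @param per_cell_line fit separate parameters per line (default TRUE).
#' @param start_grid K starting values for the nonlinear multi-start.
#' @param loocv compute the cross-validated error (default TRUE).
#' @return An object of class `viability_fit`.
#' @export
fit_viability_model <- function(form, data, per_cell_line = TRUE,
                                start_grid = c(0.5, 1, 2, 4), loocv = TRUE) {
  form <- match.arg(form, viability_forms)
  groups <- if (per_cell_line) split(data, data$cell_line) else list(pooled = data)

  fits <- lapply(groups, fit_group, form = form, start_grid = start_grid)
  predictions <- data
  predictions$v_hat <- NA_real_
  for (g in names(groups)) {
    idx <- if (per_cell_line) data$cell_line == g else rep(TRUE, nrow(data))
    predictions$v_hat[idx] <- predict_group(form, fits[[g]]$params, data[idx, ])
  }
  resid <- predictions$v - predictions$v_hat
  sigma <- mean(vapply(fits, `[[`, 1, "sigma"))

  loocv_l2 <- NA_real_
  if (loocv) {
    errs <- c()
    for (g in names(groups)) {
      dat <- groups[[g]]
      for (i in seq_len(nrow(dat))) {
        f <- fit_group(form, dat[-i, , drop = FALSE], start_grid)
        v_hat <- predict_group(form, f$params, dat[i, , drop = FALSE])
        errs <- c(errs, (dat$v[i] - v_hat)^2)
      }
    }
    loocv_l2 <- mean(errs)
  }

  # curvature of the residual-vs-fitted trend (structure diagnostic)
  cfit <- stats::lm(resid ~ predictions$v_hat + I(predictions$v_hat^2))
  curvature <- unname(stats::coef(cfit)[3])

  structure(list(
    form = form,
    type = if (form %in% linear_forms) "linear" else "nonlinear",
    per_cell_line = per_cell_line,
    params = lapply(fits, `[[`, "params"),
    sigma = sigma, loocv_l2 = loocv_l2,
    resid_curvature = curvature,
    predictions = predictions, data = data,
    start_grid = start_grid
  ), class = "viability_fit")
}

#' @export
print.viability_fit <- function(x, ...) {
  cat("Viability model ", x$form, " (", x$type, "), ",
      if (x$per_cell_line) "per cell line" else "pooled", "\n", sep = "")
  for (g in names(x$params)) {
    p <- x$params[[g]]
    if (!is.null(p$K)) {
      cat("  ", g, ": K_M(AKT) = ", format(p$K[["AKT"]], digits = 4),
          ", K_M(ERK) = ", format(p$K[["ERK"]], digits = 4), "\n", sep = "")
    } else {
      cat("  ", g, ": ", paste(names(p$beta), format(p$beta, digits = 3),
                               sep = "=", collapse = ", "), "\n", sep = "")
    }
  }
  cat("  sigma = ", format(x$sigma, digits = 3),
      ", LOOCV error = ", format(x$loocv_l2, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Compare fitted viability models
#'
#' @param fits list of `viability_fit` objects on the same data.
#' @return Data frame (form, type, sigma, loocv_l2) ordered best to worst by
#'   cross-validated error, with the pairwise Pearson correlations among the
#'   nonlinear forms' predictions attached as attribute
#'   `"nonlinear_prediction_cor"`.
#' @export
compare_viability_models <- function(fits) {
  if (length(fits) == 0) stop("no fits to compare")
  key <- vapply(fits, function(f) paste(f$data$condition, f$data$cell_line,
                                        collapse = "|"), "")
  if (length(unique(key)) != 1L) stop("fits are not on the same data")
  tab <- data.frame(
    form = vapply(fits, `[[`, "", "form"),
    type = vapply(fits, `[[`, "", "type"),
    sigma = vapply(fits, `[[`, 1, "sigma"),
    loocv_l2 = vapply(fits, `[[`, 1, "loocv_l2"))
  tab <- tab[order(tab$loocv_l2), ]
  rownames(tab) <- NULL
  nl <- fits[vapply(fits, `[[`, "", "type") == "nonlinear"]
  if (length(nl) >= 2) {
    P <- vapply(nl, function(f) f$predictions$v_hat, numeric(nrow(fits[[1]]$data)))
    colnames(P) <- vapply(nl, `[[`, "", "form")
    attr(tab, "nonlinear_prediction_cor") <- stats::cor(P)
  }
  tab
}

#' Bootstrap confidence intervals for viability model parameters
#'
#' Nonparametric bootstrap: conditions are resampled with replacement within
#' each cell line and the model refit; percentile 95% intervals are reported.
#'
#' @param fit a `viability_fit`.
#' @param n_boot number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return Data frame (group, parameter, estimate, lower, upper).
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = 1L) {
  if (n_boot < 100) stop("n_boot must be at least 100")
  groups <- if (fit$per_cell_line) split(fit$data, fit$data$cell_line)
            else list(pooled = fit$data)
  rows <- list()
  withr::with_seed(seed, {
    for (g in names(groups)) {
      dat <- groups[[g]]
      draws <- matrix(NA_real_, n_boot,
                      length(unlist(fit$params[[g]], use.names = FALSE)))
      fails <- 0L
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nrow(dat), replace = TRUE)
        f <- tryCatch(fit_group(fit$form, dat[idx, , drop = FALSE], fit$start_grid),
                      error = function(e) NULL)
        if (is.null(f)) fails <- fails + 1L
        else draws[b, ] <- unlist(f$params, use.names = FALSE)
      }
      if (fails > 0.2 * n_boot) {
        stop("bootstrap refit failure rate above 20% (", fails, "/", n_boot, ")")
      }
      est <- unlist(fit$params[[g]], use.names = TRUE)
      qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
      rows[[g]] <- data.frame(group = g, parameter = names(est), estimate = unname(est),
                              lower = qs[1, ], upper = qs[2, ])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
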