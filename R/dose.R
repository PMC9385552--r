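# Drug-concentration to direct-target-inhibition interpolation.
#
# The direct effect of drug k on target node i at normalized concentration c
# (all concentrations expressed as fractions of the highest applied, the
# IC90) is modeled as
#     s(c) = Imax * c / (KI + c),
# fitted exactly through the two CNR-estimated anchors (c50, s50) and
# (1, s90). Only interpolation on [0, 1] is permitted.

#' Fit the two-point inhibition curve
#'
#' Closed-form solution of `s(c) = Imax c / (KI + c)` through the IC50 and
#' IC90 anchors; falls back to least squares (and flags the pair) when the
#' closed form gives a non-positive half-saturation constant.
#'
#' @param c50 normalized IC50 concentration (0 < c50 < 1).
#' @param s50 direct effect at IC50 (negative).
#' @param s90 direct effect at IC90 (more negative than `s50`).
#' @param c90 normalized IC90 concentration, 1 by construction.
#' @return List with `Imax`, `KI`, and `fallback` (TRUE when the closed form
#'   was invalid and least squares was used).
#' @export
fit_inhibition_curve <- function(c50, s50, s90, c90 = 1) {
  if (!(c50 > 0 && c50 < c90 && c90 == 1)) {
    stop("need 0 < c50 < c90 = 1 (normalized concentrations)")
  }
  if (s50 >= 0 || s90 >= 0) stop("anchor effects must be negative (inhibitors)")
  if (s50 <= s90) stop("non-monotone anchors: need 0 > s50 > s90")
  rho <- s50 / s90 # in (0, 1)
  KI <- c50 * (1 - rho) / (rho - c50)
  if (is.finite(KI) && KI > 0) {
    return(list(Imax = s90 * (KI + 1), KI = KI, fallback = FALSE))
  }
  # closed form invalid (rho <= c50): least-squares compromise on the anchors
  obj <- function(p) {
    KI <- exp(p[1]); Imax <- p[2]
    (Imax * c50 / (KI + c50) - s50)^2 + (Imax / (KI + 1) - s90)^2
  }
  o <- stats::optim(c(0, s90), obj, method = "BFGS",
                    control = list(reltol = 1e-14, maxit = 1000))
  list(Imax = o$par[2], KI = exp(o$par[1]), fallback = TRUE)
}

#' Evaluate the inhibition curve at a normalized concentration
#'
#' @param params list with `Imax` and `KI` (from [fit_inhibition_curve()]).
#' @param conc normalized concentration(s) in `[0, 1]`; values outside are an
#'   error (no extrapolation).
#' @return Direct effect `Imax * conc / (KI + conc)`.
#' @export
inhibition_at <- function(params, conc) {
  if (any(conc < 0 | conc > 1)) {
    stop("concentration outside [0, 1]: no extrapolation")
  }
  params$Imax * conc / (params$KI + conc)
}

#' Fit inhibition curves for every (drug, target, cell line) of a CNR result
#'
#' Two-dose drugs use the exact two-point solution anchored at the fitted
#' s(IC50) and s(IC90). Single-dose drugs (only IC90 measured) fix KI to the
#' median KI of the two-dose drugs in the same cell line and solve Imax from
#' the single anchor; such rows are flagged `single_dose`.
#'
#' @param cnr_result a `cnr_result` (or any object with an `s` table of
#'   columns drug, dose, target, cell_line, value).
#' @param design the `study_design` supplying normalized dose levels.
#' @return Data frame (drug, target, cell_line, Imax, KI, single_dose,
#'   fallback) of class `dose_params`.
#' @export
fit_dose_params <- function(cnr_result, design) {
  s <- cnr_result$s
  combos <- unique(s[, c("drug", "target", "cell_line")])
  rows <- list()
  for (k in seq_len(nrow(combos))) {
    d <- combos$drug[k]; tg <- combos$target[k]; ln <- combos$cell_line[k]
    sub <- s[s$drug == d & s$target == tg & s$cell_line == ln, ]
    vals <- stats::setNames(sub$value, sub$dose)
    c50 <- design$dose_levels[[d]][["IC50"]]
    if (all(c("IC50", "IC90") %in% names(vals))) {
      cf <- fit_inhibition_curve(c50, vals[["IC50"]], vals[["IC90"]])
      rows[[k]] <- data.frame(drug = d, target = tg, cell_line = ln,
                              Imax = cf$Imax, KI = cf$KI,
                              single_dose = FALSE, fallback = cf$fallback)
    } else {
      rows[[k]] <- data.frame(drug = d, target = tg, cell_line = ln,
                              Imax = NA_real_, KI = NA_real_,
                              single_dose = TRUE, fallback = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # single-dose drugs: borrow the median KI of the line's two-dose curves
  for (ln in unique(out$cell_line)) {
    med <- stats::median(out$KI[out$cell_line == ln & !out$single_dose], na.rm = TRUE)
    idx <- which(out$cell_line == ln & out$single_dose)
    for (i in idx) {
      d <- out$drug[i]; tg <- out$target[i]
      sub <- s[s$drug == d & s$target == tg & s$cell_line == ln, ]
      if (!is.finite(med)) stop("no two-dose curves to borrow KI from for ", d)
      s90 <- sub$value[sub$dose == "IC90"]
      if (length(s90) != 1L) stop("single-dose drug ", d, " lacks an IC90 estimate")
      out$KI[i] <- med
      out$Imax[i] <- s90 * (med + 1)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("dose_params", "data.frame")
  out
}

#' Write fitted dose-response parameters as TSV
#' @param params a `dose_params` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dose_params <- function(params, path) {
  utils::write.table(params, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
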