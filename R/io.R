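# Raw-readout normalization and tabular I/O.

#' Log2 fold changes relative to vehicle control
#'
#' `log2(treatment / mean(DMSO))` per node per condition.
#'
#' @param treatment nodes x conditions matrix of raw readouts (> 0).
#' @param dmso nodes x replicates matrix (or vector) of vehicle-control
#'   readouts (> 0), rows aligned with `treatment`.
#' @return Response matrix of log2 fold changes.
#' @export
compute_log2fc <- function(treatment, dmso) {
  if (!is.matrix(dmso)) dmso <- matrix(dmso, ncol = 1,
                                       dimnames = list(names(dmso), NULL))
  bad <- which(treatment <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive readout at node ", rownames(treatment)[bad[1, 1]],
         ", condition ", colnames(treatment)[bad[1, 2]])
  }
  if (any(dmso <= 0)) stop("non-positive DMSO readout")
  ref <- rowMeans(dmso)
  if (nrow(treatment) != length(ref)) stop("treatment and DMSO rows disagree")
  log2(sweep(treatment, 1, ref, "/"))
}

#' Normalize raw viability readouts against DMSO and kill controls
#'
#' Per cell line: `v = (treatment - mean(PAO)) / (mean(DMSO) - mean(PAO))`,
#' where PAO (phenylarsine oxide) wells define 0% and DMSO wells 100%
#' viability. Negative values are permitted but flagged.
#'
#' @param raw data frame (condition, cell_line, replicate, value); conditions
#'   named in `dmso_label` / `pao_label` are the controls.
#' @param dmso_label,pao_label control condition identifiers.
#' @return Data frame (condition, cell_line, replicate, value) of normalized
#'   viabilities (controls removed), with attribute `"n_negative"`.
#' @export
normalize_viability <- function(raw, dmso_label = "DMSO", pao_label = "PAO") {
  out <- list()
  n_neg <- 0L
  for (line in unique(raw$cell_line)) {
    sub <- raw[raw$cell_line == line, ]
    dmso <- sub$value[sub$condition == dmso_label]
    pao <- sub$value[sub$condition == pao_label]
    if (length(dmso) == 0 || length(pao) == 0) {
      stop("cell line ", line, " lacks DMSO and/or PAO control records")
    }
    dm <- mean(dmso); pm <- mean(pao)
    if (dm <= pm) stop("DMSO mean <= PAO mean for cell line ", line)
    keep <- sub[!sub$condition %in% c(dmso_label, pao_label), , drop = FALSE]
    keep$value <- (keep$value - pm) / (dm - pm)
    n_neg <- n_neg + sum(keep$value < 0)
    out[[line]] <- keep
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (n_neg > 0) {
    warning(n_neg, " normalized viability value(s) below 0 (kept, flagged)")
  }
  attr(res, "n_negative") <- n_neg
  res
}

#' Read a long viability table TSV
#' @param path TSV with columns condition, cell_line, replicate, value.
#' @return Data frame.
#' @export
read_viability_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
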