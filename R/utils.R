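#' @keywords internal
"_PACKAGE"

# Condition identifiers are strings like "EGFRi@IC50" or "AKTi@IC50+MEKi@IC50".

#' Parse a condition identifier
#'
#' Conditions are encoded as `"DRUG@DOSE"` treatments joined by `"+"`, e.g.
#' `"AKTi@IC50+MEKi@IC50"`.
#'
#' @param id character vector of condition identifiers.
#' @return A list (one element per id) of data frames with columns `drug` and
#'   `dose`.
#' @export
parse_condition <- function(id) {
  lapply(strsplit(id, "+", fixed = TRUE), function(parts) {
    bits <- strsplit(parts, "@", fixed = TRUE)
    bad <- vapply(bits, length, 1L) != 2L
    if (any(bad)) {
      stop("malformed condition treatment(s): ",
           paste(parts[bad], collapse = ", "))
    }
    data.frame(drug = vapply(bits, `[`, "", 1L),
               dose = vapply(bits, `[`, "", 2L))
  })
}

condition_id <- function(drugs, doses) {
  paste(paste0(drugs, "@", doses), collapse = "+")
}

stop_if_not_aligned <- function(a, b, what) {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    stop(what, ": dimensions or labels do not align")
  }
}

# Derive a 32-bit sub-seed from a base seed and a stage label, so every
# stochastic stage of a pipeline gets an independent but reproducible stream.
sub_seed <- function(seed, label) {
  h <- utils::head(utf8ToInt(paste0(label, ":", seed)), 20)
  as.integer((sum(h * seq_along(h) * 2654435761) + seed * 97) %% .Machine$integer.max)
}
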