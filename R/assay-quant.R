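#' Inhibitory activity from colony counts
#'
#' The plasmid-interference readout: inhibitory activity (%) is the
#' ratio of colony-forming units between the transformation with the
#' matching-spacer Cas9 plasmid and the mismatching-spacer control,
#' expressed as a percentage. Full Cas9 inhibition lets matching-spacer
#' transformants survive like the control (100%); no inhibition leaves
#' no survivors (0%). Sampling noise can push the raw ratio above 1;
#' such values are clamped to 100 and flagged via the `"clamped"`
#' attribute.
#'
#' @param cfu_matching,cfu_mismatching non-negative colony counts
#'   (vectorized).
#' @return Percent activity in `[0, 100]` with a logical `"clamped"`
#'   attribute.
#' @export
inhibitory_activity <- function(cfu_matching, cfu_mismatching) {
  if (any(cfu_matching < 0) || any(cfu_mismatching < 0)) {
    stop("inhibitory_activity: counts must be non-negative", call. = FALSE)
  }
  if (any(cfu_mismatching == 0)) {
    stop("inhibitory_activity: cfu_mismatching is zero; the cfu ratio is ",
         "undefined without control colonies", call. = FALSE)
  }
  raw <- 100 * cfu_matching / cfu_mismatching
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "clamped") <- raw > 100
  out
}

#' Indel percentage from a T7E1 cleaved fraction
#'
#' Genome-editing efficiency from the mismatch-nuclease assay:
#' indel(%) = 100 * (1 - sqrt(1 - fraction_cleaved)).
#'
#' @param fraction_cleaved cleaved band fraction in `[0, 1]`
#'   (vectorized).
#' @return Indel percentage in `[0, 100]`.
#' @seealso [indel_to_fraction()] for the exact inverse.
#' @export
indel_percent <- function(fraction_cleaved) {
  if (any(is.na(fraction_cleaved)) ||
      any(fraction_cleaved < 0 | fraction_cleaved > 1)) {
    stop("indel_percent: fraction_cleaved must lie in [0, 1]", call. = FALSE)
  }
  100 * (1 - sqrt(1 - fraction_cleaved))
}

#' @rdname indel_percent
#' @param indel indel percentage in `[0, 100]`.
#' @export
indel_to_fraction <- function(indel) {
  if (any(is.na(indel)) || any(indel < 0 | indel > 100)) {
    stop("indel_to_fraction: indel must lie in [0, 100]", call. = FALSE)
  }
  1 - (1 - indel / 100)^2
}

#' Classify mean inhibitory activity into summary symbols
#'
#' Reproduces the summary-table banding: activity at or below 20% is
#' "-", above 20 up to 50 is "+", above 50 up to 80 is "++", above 80 is
#' "+++". The printed legend leaves the exact boundaries open; bands are
#' closed on the right so the mapping is total and monotone. `NA` maps
#' to "ND" (not determined).
#'
#' @param mean_activity percent in `[0, 100]` (vectorized; `NA`
#'   allowed).
#' @return Character vector over `{-, +, ++, +++, ND}`.
#' @export
classify_activity <- function(mean_activity) {
  if (any(mean_activity < 0 | mean_activity > 100, na.rm = TRUE)) {
    stop("classify_activity: mean_activity must lie in [0, 100]",
         call. = FALSE)
  }
  out <- ifelse(is.na(mean_activity), "ND",
         ifelse(mean_activity <= 20, "-",
         ifelse(mean_activity <= 50, "+",
         ifelse(mean_activity <= 80, "++", "+++"))))
  out
}

#' Fold regulation of a chemically inducible inhibitor
#'
#' For 4-HT-switchable (intein) Acr variants: the editing efficiency
#' without inducer divided by the efficiency with inducer. The inhibitor
#' is active only upon 4-HT, so stronger regulation gives a larger
#' fold. The ratio orientation is this package's documented
#' interpretation of the reported fold changes.
#'
#' @param efficiency_no4HT,efficiency_4HT editing efficiencies (%) in
#'   the absence/presence of 4-hydroxytamoxifen (vectorized).
#' @param pseudo_efficiency optional floor added to both efficiencies
#'   when the denominator is zero; without it a zero denominator is an
#'   error.
#' @return Fold change (no-inducer / inducer).
#' @export
fold_regulation <- function(efficiency_no4HT, efficiency_4HT,
                            pseudo_efficiency = NULL) {
  if (any(efficiency_4HT == 0)) {
    if (is.null(pseudo_efficiency)) {
      stop("fold_regulation: efficiency_4HT is zero; the fold is undefined. ",
           "Supply pseudo_efficiency to report a floor-adjusted fold.",
           call. = FALSE)
    }
    efficiency_no4HT <- efficiency_no4HT + pseudo_efficiency
    efficiency_4HT <- efficiency_4HT + pseudo_efficiency
  }
  efficiency_no4HT / efficiency_4HT
}

#' Summarize an assay table into per-combination activity results
#'
#' Groups replicates by (acr, cas9, assay), computes the per-replicate
#' cfu-ratio activity, its mean and SEM, and the summary symbol.
#' Combinations listed in `expected` but absent from the table are
#' reported as "ND"; single-replicate groups get an `NA` SEM with a
#' warning.
#'
#' @param table assay table with columns `acr_label`, `cas9_label`,
#'   `assay`, `replicate_id`, `cfu_matching`, `cfu_mismatching`.
#' @param expected optional data.frame of `acr_label`, `cas9_label`,
#'   `assay` combinations that must appear in the output.
#' @return data.frame with `acr_label`, `cas9_label`, `assay`,
#'   `n_replicates`, `mean_activity`, `sem`, `symbol`.
#' @export
summarize_assays <- function(table, expected = NULL) {
  stopifnot(all(c("acr_label", "cas9_label", "assay", "cfu_matching",
                  "cfu_mismatching") %in% names(table)))
  if (nrow(table) > 0L) {
    table$activity <- as.numeric(inhibitory_activity(table$cfu_matching,
                                                     table$cfu_mismatching))
  }
  keys <- unique(table[, c("acr_label", "cas9_label", "assay"), drop = FALSE])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- table$acr_label == keys$acr_label[i] &
      table$cas9_label == keys$cas9_label[i] & table$assay == keys$assay[i]
    act <- table$activity[sel]
    if (length(act) == 1L) {
      warning("summarize_assays: single replicate for ",
              keys$acr_label[i], "/", keys$cas9_label[i],
              "; SEM not available", call. = FALSE)
    }
    m <- mean(act)
    data.frame(keys[i, , drop = FALSE],
               n_replicates = length(act),
               mean_activity = m,
               sem = if (length(act) > 1L)
                 stats::sd(act) / sqrt(length(act)) else NA_real_,
               symbol = classify_activity(m),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(acr_label = character(), cas9_label = character(),
               assay = character(), n_replicates = integer(),
               mean_activity = numeric(), sem = numeric(),
               symbol = character(), stringsAsFactors = FALSE)
  if (!is.null(expected)) {
    have <- paste(out$acr_label, out$cas9_label, out$assay)
    want <- paste(expected$acr_label, expected$cas9_label, expected$assay)
    miss <- expected[!(want %in% have), , drop = FALSE]
    if (nrow(miss) > 0L) {
      out <- rbind(out, data.frame(
        miss[, c("acr_label", "cas9_label", "assay")],
        n_replicates = 0L, mean_activity = NA_real_, sem = NA_real_,
        symbol = "ND", stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
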