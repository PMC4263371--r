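Y2H_PLATES <- c("his3", "his3_chx", "ade2", "ade2_chx")

#' Score a Y2H readout as interaction-positive
#'
#' Growth is recorded as integer 2-fold serial-dilution steps (0 = no
#' growth) on four selective plates: the His3 reporter (SC-Leu-Trp-His+3AT),
#' its cycloheximide control (SC-Leu-His+3AT+CHX), the Ade2 reporter
#' (SC-Leu-Trp-Ade) and its CHX control (SC-Leu-Ade+CHX). A pair is
#' positive when at least one reporter shows growth and neither CHX control
#' does; growth on a CHX control marks a spontaneous auto-activator and the
#' pair is scored negative.
#'
#' @param readout data.frame with integer columns `his3`, `his3_chx`,
#'   `ade2`, `ade2_chx` (one row per replicate), or a single named vector.
#' @return logical vector, one element per row.
#' @export
y2h_positive <- function(readout) {
  if (is.numeric(readout)) readout <- as.data.frame(as.list(readout))
  miss <- setdiff(Y2H_PLATES, names(readout))
  if (length(miss))
    stop("missing plate score(s): ", paste(miss, collapse = ", "))
  for (p in Y2H_PLATES)
    if (any(readout[[p]] < 0) || any(readout[[p]] != round(readout[[p]])))
      stop("growth scores must be non-negative integers (", p, ")")
  (readout$his3 > 0 | readout$ade2 > 0) &
    readout$his3_chx == 0 & readout$ade2_chx == 0
}

#' Call disruption of an interaction by a mutation
#'
#' With growth encoded in 2-fold dilution steps, a 50% growth reduction
#' corresponds to a drop of at least one step. A mutation disrupts an
#' interaction when both reporters drop by >= 1 step relative to wild type,
#' consistently in the majority of replicates.
#'
#' Disruption is only defined against a detectable wild-type interaction:
#' the wild-type pair must be Y2H-positive in at least 2 of 3 replicates.
#' Pairs whose wild type activates only a single reporter cannot satisfy
#' the both-reporter reduction rule and are flagged as
#' `"single_reporter"` with `disrupted = NA`.
#'
#' @param wt,mut data.frames of replicate readouts (columns as in
#'   [y2h_positive()]) for the wild-type and mutant pair; replicates are
#'   matched by row order.
#' @return list with `disrupted` (TRUE/FALSE/NA), `reason` (`"ok"`,
#'   `"wildtype_negative"` or `"single_reporter"`), and the per-replicate
#'   logical vector `replicate_calls`.
#' @export
call_disruption <- function(wt, mut) {
  if (nrow(wt) != nrow(mut))
    stop("wild-type and mutant replicate counts differ")
  pos <- y2h_positive(wt)
  if (sum(pos) <= nrow(wt) / 2)
    return(list(disrupted = NA, reason = "wildtype_negative",
                replicate_calls = logical(0)))
  both_rep <- wt$his3 > 0 & wt$ade2 > 0
  if (sum(both_rep) <= nrow(wt) / 2)
    return(list(disrupted = NA, reason = "single_reporter",
                replicate_calls = logical(0)))
  rep_calls <- (mut$his3 <= wt$his3 - 1) & (mut$ade2 <= wt$ade2 - 1)
  list(disrupted = sum(rep_calls) > length(rep_calls) / 2, reason = "ok",
       replicate_calls = rep_calls)
}

#' Build per-mutation interaction disruption profiles
#'
#' A mutation's profile is the ordered vector, over its protein's tested
#' partners, of which interactions it disrupts. Profiles are comparable
#' between mutations of the same gene only over an identical tested-partner
#' set.
#'
#' @param calls data.frame with columns `gene`, `mutation`, `partner`,
#'   `disrupted` (logical; `NA` rows are dropped with a message).
#' @return named list (one element per mutation) of named logical vectors
#'   over alphabetically ordered partners; each element carries the gene in
#'   attribute `gene`.
#' @export
build_profiles <- function(calls) {
  need <- c("gene", "mutation", "partner", "disrupted")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  if (anyNA(calls$disrupted)) {
    message("dropping ", sum(is.na(calls$disrupted)),
            " undefined disruption call(s)")
    calls <- calls[!is.na(calls$disrupted), ]
  }
  out <- lapply(split(calls, calls$mutation), function(d) {
    v <- setNames(d$disrupted, d$partner)[order(d$partner)]
    attr(v, "gene") <- d$gene[[1]]
    v
  })
  out[unique(calls$mutation)]
}
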