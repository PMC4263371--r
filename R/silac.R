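SILAC_EXPERIMENTS <- c("WT_Control", "Mutant_Control", "WT_Mutant",
                       "Mutant_WT")

geom_mean <- function(x) exp(mean(log(x)))

#' Read a SILAC peptide ratio table
#'
#' @param path TSV with columns `experiment` (one of WT_Control,
#'   Mutant_Control, WT_Mutant, Mutant_WT), `protein_id`, `peptide_id`,
#'   `xpress_ratio` (light/heavy, > 0), `is_bait` (logical).
#' @return validated data.frame.
#' @export
read_ratio_table <- function(path) {
  rec <- as.data.frame(data.table::fread(path, sep = "\t"))
  validate_ratio_records(rec)
}

validate_ratio_records <- function(records) {
  need <- c("experiment", "protein_id", "peptide_id", "xpress_ratio",
            "is_bait")
  if (!all(need %in% names(records)))
    stop("ratio records must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(records$experiment), SILAC_EXPERIMENTS)
  if (length(bad))
    stop("unknown experiment label(s): ", paste(bad, collapse = ", "))
  if (any(records$xpress_ratio <= 0))
    stop("xpress_ratio must be > 0")
  records$is_bait <- as.logical(records$is_bait)
  records
}

#' Aggregate SILAC peptide ratios into per-protein interaction scores
#'
#' Implements the four-experiment pull-down design (bait vs control in both
#' directions, and direct wild-type vs mutant swaps). With Xpress ratios
#' given as light/heavy:
#'
#' * `WT_p = 1 / GM(X_i)` over the `r_wc` peptides of the protein in the
#'   WT-bait (heavy) vs control (light) experiment -- enrichment over
#'   control;
#' * `Mut_p = 1 / GM(Y_i)` analogously from the mutant-bait experiment
#'   (`r_mc` peptides);
#' * `FC_wm = GM(P_i) / GM(C_j)`: mutant/wild-type fold change from the
#'   WT (heavy) vs mutant (light) experiment, bait-normalized by the
#'   `t_wm` bait peptides `C_j`;
#' * `FC_mw = GM(Q_j)^{-1} / GM(D_i)^{-1}`: the same fold change measured
#'   in the label-swapped mutant (heavy) vs wild-type (light) experiment,
#'   bait-normalized by the `t_mw` bait peptides `D_i`;
#' * `E = (r_wm log2 FC_wm + r_mw log2 FC_mw) / (r_wm + r_mw)`: the
#'   read-count-weighted combined log2 fold change (negative for weakened,
#'   positive for enhanced interactors).
#'
#' Bait normalization cancels global heavy/light mixing-ratio errors; GM
#' denotes the geometric mean.
#'
#' @param records data.frame of peptide ratio records (see
#'   [read_ratio_table()]).
#' @return data.frame with one row per non-bait protein: `protein_id`,
#'   `WT_p`, `Mut_p`, `FC_wm`, `FC_mw`, `E`, and counts `r_wc`, `r_mc`,
#'   `r_wm`, `r_mw`, `t_wm`, `t_mw`. Fields for experiments in which a
#'   protein was not observed are `NA` with count 0.
#' @export
silac_aggregate <- function(records) {
  records <- validate_ratio_records(records)
  ratio_of <- function(exp, prot) {
    records$xpress_ratio[records$experiment == exp &
                           records$protein_id == prot & !records$is_bait]
  }
  C <- records$xpress_ratio[records$experiment == "WT_Mutant" &
                              records$is_bait]
  D <- records$xpress_ratio[records$experiment == "Mutant_WT" &
                              records$is_bait]
  if ("WT_Mutant" %in% records$experiment && !length(C))
    stop("no bait peptides in the WT_Mutant experiment")
  if ("Mutant_WT" %in% records$experiment && !length(D))
    stop("no bait peptides in the Mutant_WT experiment")

  prots <- sort(unique(records$protein_id[!records$is_bait]))
  out <- do.call(rbind, lapply(prots, function(pr) {
    X <- ratio_of("WT_Control", pr)
    Y <- ratio_of("Mutant_Control", pr)
    P <- ratio_of("WT_Mutant", pr)
    Q <- ratio_of("Mutant_WT", pr)
    wt_p <- if (length(X)) 1 / geom_mean(X) else NA_real_
    mut_p <- if (length(Y)) 1 / geom_mean(Y) else NA_real_
    fc_wm <- if (length(P)) geom_mean(P) / geom_mean(C) else NA_real_
    fc_mw <- if (length(Q)) (1 / geom_mean(Q)) / (1 / geom_mean(D))
             else NA_real_
    num <- 0
    den <- length(P) + length(Q)
    if (length(P)) num <- num + length(P) * log2(fc_wm)
    if (length(Q)) num <- num + length(Q) * log2(fc_mw)
    e <- if (den > 0) num / den else NA_real_
    data.frame(protein_id = pr, WT_p = wt_p, Mut_p = mut_p, FC_wm = fc_wm,
               FC_mw = fc_mw, E = e, r_wc = length(X), r_mc = length(Y),
               r_wm = length(P), r_mw = length(Q), t_wm = length(C),
               t_mw = length(D), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

na_false <- function(x) !is.na(x) & x

#' Classify interactors as lost, gained or unchanged
#'
#' Threshold rules on the aggregated scores:
#' * lost: interactor of the wild-type bait (`WT_p > 2`, `r_wc >= 5`) and
#'   at least 2-fold weaker with the mutant in both swap experiments
#'   (`FC_wm < 0.5`, `r_wm >= 5`; `FC_mw < 0.5`, `r_mw >= 5`);
#' * gained: interactor of the mutant bait (`Mut_p > 2`, `r_mc >= 5`) and
#'   at least 2-fold stronger in both swaps (`FC_wm > 2`, `FC_mw > 2`,
#'   counts >= 5);
#' * unchanged: interactor of both baits with both fold changes strictly
#'   between 0.5 and 2 (counts >= 5);
#' * anything else: unclassified.
#'
#' @param scores data.frame from [silac_aggregate()].
#' @return `scores` with an added `classification` column.
#' @export
silac_classify <- function(scores) {
  wt_int <- na_false(scores$WT_p > 2) & scores$r_wc >= 5
  mut_int <- na_false(scores$Mut_p > 2) & scores$r_mc >= 5
  counts_ok <- scores$r_wm >= 5 & scores$r_mw >= 5
  lost <- wt_int & na_false(scores$FC_wm < 0.5) &
    na_false(scores$FC_mw < 0.5) & counts_ok
  gained <- mut_int & na_false(scores$FC_wm > 2) &
    na_false(scores$FC_mw > 2) & counts_ok
  unchanged <- wt_int & mut_int &
    na_false(scores$FC_wm > 0.5 & scores$FC_wm < 2) &
    na_false(scores$FC_mw > 0.5 & scores$FC_mw < 2) & counts_ok
  scores$classification <- ifelse(lost, "lost",
                           ifelse(gained, "gained",
                           ifelse(unchanged, "unchanged", "unclassified")))
  scores
}

# two-sample Kolmogorov-Smirnov statistic, sort-based, ties allowed
ks_statistic <- function(x, y) {
  n <- length(x)
  m <- length(y)
  v <- c(x, y)
  o <- order(v)
  step <- ifelse(o <= n, 1 / n, -1 / m)
  z <- cumsum(step)
  vs <- v[o]
  # evaluate only at the last occurrence of each tied value
  keep <- c(vs[-1] != vs[-(n + m)], TRUE)
  max(abs(z[keep]))
}

#' Bootstrap Kolmogorov-Smirnov P value against a background distribution
#'
#' Two-sided KS statistic between a protein's per-peptide log ratios and a
#' background distribution (the pooled normalized log ratios of unchanged
#' proteins); the P value is the bootstrap fraction of same-size background
#' resamples whose KS statistic is at least the observed one (with the
#' usual +1 continuity correction, so P is in (0, 1]).
#'
#' @param x numeric vector of the protein's log2 normalized ratios
#'   (>= 3 values required).
#' @param background numeric vector of background log2 ratios.
#' @param n_boot number of bootstrap resamples (> 0).
#' @param seed optional integer seed for reproducibility.
#' @return P value, or `NA` (with a warning) when `x` has fewer than 3
#'   values.
#' @export
ks_bootstrap_p <- function(x, background, n_boot = 10000L, seed = NULL) {
  if (n_boot <= 0) stop("n_boot must be positive")
  if (!length(background)) stop("empty background distribution")
  if (length(x) < 3) {
    warning("fewer than 3 peptide ratios; P value undefined")
    return(NA_real_)
  }
  if (!is.null(seed)) set.seed(seed)
  d_obs <- ks_statistic(x, background)
  n <- length(x)
  d_boot <- vapply(seq_len(n_boot), function(i)
    ks_statistic(sample(background, n, replace = TRUE), background),
    numeric(1))
  (1 + sum(d_boot >= d_obs)) / (n_boot + 1)
}

#' Per-protein pooled normalized log ratios
#'
#' Bait-normalized per-peptide log2 mutant/wild-type ratios pooled across
#' the two swap experiments; the inputs to the KS bootstrap test.
#'
#' @param records peptide ratio records.
#' @return named list of numeric vectors, one per non-bait protein.
#' @export
silac_peptide_logratios <- function(records) {
  records <- validate_ratio_records(records)
  C <- records$xpress_ratio[records$experiment == "WT_Mutant" &
                              records$is_bait]
  D <- records$xpress_ratio[records$experiment == "Mutant_WT" &
                              records$is_bait]
  prots <- sort(unique(records$protein_id[!records$is_bait]))
  lapply(setNames(prots, prots), function(pr) {
    P <- records$xpress_ratio[records$experiment == "WT_Mutant" &
                                records$protein_id == pr & !records$is_bait]
    Q <- records$xpress_ratio[records$experiment == "Mutant_WT" &
                                records$protein_id == pr & !records$is_bait]
    c(if (length(P) && length(C)) log2(P) - log2(geom_mean(C)),
      if (length(Q) && length(D)) log2(geom_mean(D)) - log2(Q))
  })
}

#' KS bootstrap P values for all classified proteins
#'
#' @param records peptide ratio records.
#' @param scores classified scores from [silac_classify()].
#' @param n_boot,seed passed to [ks_bootstrap_p()].
#' @return `scores` with an added `p_value` column (`NA` for proteins with
#'   fewer than 3 pooled peptide ratios).
#' @export
silac_ks_pvalues <- function(records, scores, n_boot = 1000L, seed = NULL) {
  lr <- silac_peptide_logratios(records)
  background <- unlist(lr[scores$protein_id[
    scores$classification == "unchanged"]], use.names = FALSE)
  if (!is.null(seed)) set.seed(seed)
  scores$p_value <- vapply(scores$protein_id, function(pr) {
    x <- lr[[pr]]
    if (is.null(x) || length(x) < 3 || !length(background)) return(NA_real_)
    suppressWarnings(ks_bootstrap_p(x, background, n_boot, seed = NULL))
  }, numeric(1))
  scores
}
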