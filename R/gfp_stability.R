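#' GFP plate-reader stability calls
#'
#' Converts raw fluorescence intensities into per-allele protein stability
#' calls. Per plate, the background intensity `I_background` is the mean of
#' the empty-vector control wells and `K` is their range (maximum -
#' minimum). Each well's normalized intensity is
#' `I_norm = I - I_background` (per plate, so alleles split across plates
#' are normalized within each plate before combining). An allele is called
#' stably expressed when its mean `I_norm` across replicates exceeds `K`;
#' for alleles measured on several plates the largest involved `K` is used
#' (the conservative choice).
#'
#' @param readouts data.frame with columns `plate_id`, `allele_id`,
#'   `intensity`, `replicate`. Empty-vector control wells carry
#'   `allele_id == "EMPTY_VECTOR"`; every plate needs at least two of them.
#' @return data.frame with one row per allele: `allele_id`, `mean_I_norm`,
#'   `K`, `n_replicates`, `stable`.
#' @export
call_stability <- function(readouts) {
  need <- c("plate_id", "allele_id", "intensity", "replicate")
  if (!all(need %in% names(readouts)))
    stop("readouts must have columns: ", paste(need, collapse = ", "))
  if (any(readouts$intensity < 0)) stop("negative fluorescence intensity")

  plates <- unique(readouts$plate_id)
  bg <- lapply(setNames(plates, plates), function(p) {
    ev <- readouts$intensity[readouts$plate_id == p &
                               readouts$allele_id == "EMPTY_VECTOR"]
    if (length(ev) < 2)
      stop("plate ", p, " has fewer than 2 empty-vector control wells")
    list(i_background = mean(ev), K = max(ev) - min(ev))
  })

  alleles <- setdiff(unique(readouts$allele_id), "EMPTY_VECTOR")
  out <- do.call(rbind, lapply(alleles, function(a) {
    rows <- readouts[readouts$allele_id == a, ]
    i_norm <- rows$intensity -
      vapply(rows$plate_id, function(p) bg[[as.character(p)]]$i_background,
             numeric(1))
    K <- max(vapply(unique(rows$plate_id),
                    function(p) bg[[as.character(p)]]$K, numeric(1)))
    data.frame(allele_id = a, mean_I_norm = mean(i_norm), K = K,
               n_replicates = nrow(rows), stable = mean(i_norm) > K,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare mutant stability calls to wild type
#'
#' A mutant's expression is `diminished` when the wild-type allele is stably
#' expressed but the mutant is not. When the wild-type protein itself gives
#' no signal above background, the comparison is inconclusive (reported as
#' `NA`).
#'
#' @param calls data.frame from [call_stability()].
#' @param allele_map data.frame with columns `mutant`, `wildtype` mapping
#'   each mutant allele to its wild-type allele.
#' @return data.frame: `mutant`, `wildtype`, `diminished` (logical, `NA`
#'   when inconclusive), `inconclusive`.
#' @export
compare_to_wildtype <- function(calls, allele_map) {
  stopifnot(all(c("mutant", "wildtype") %in% names(allele_map)))
  st <- setNames(calls$stable, calls$allele_id)
  missing_wt <- setdiff(allele_map$wildtype, names(st))
  if (length(missing_wt))
    stop("no stability call for wild-type allele(s): ",
         paste(missing_wt, collapse = ", "))
  missing_mut <- setdiff(allele_map$mutant, names(st))
  if (length(missing_mut))
    stop("no stability call for mutant allele(s): ",
         paste(missing_mut, collapse = ", "))
  wt_stable <- st[allele_map$wildtype]
  mut_stable <- st[allele_map$mutant]
  diminished <- ifelse(wt_stable, wt_stable & !mut_stable, NA)
  data.frame(mutant = allele_map$mutant, wildtype = allele_map$wildtype,
             diminished = diminished, inconclusive = !wt_stable,
             stringsAsFactors = FALSE)
}
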