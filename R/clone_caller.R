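act_depth <- function(counts) {
  counts$A + counts$C + counts$G + counts$T + counts$other
}

# normalize a counts table to always carry a pool_id column
ensure_pool_column <- function(counts, manifest) {
  if (!"pool_id" %in% names(counts)) {
    pools <- unique(manifest$pool_id)
    if (length(pools) != 1)
      stop("counts lack a pool_id column but the manifest has ",
           length(pools), " pools")
    counts <- cbind(pool_id = pools, counts)
  }
  counts
}

#' Score attempted mutations with the normalized S statistic
#'
#' For each attempted mutation in each pool, the fraction of reads carrying
#' the desired alternative allele at the target site is normalized by `k`,
#' the number of distinct mutations attempted for the same gene in that pool
#' (colonies of one gene share the site's coverage under DNA-normalized
#' pooling):
#' \deqn{S = k \, R_{mut} / R_{all}}
#' where `R_all` is the read depth at the site and `R_mut` the count of
#' reads carrying the desired alternative base. A successful colony scores
#' near 1 regardless of `k`; a failed one near 0. A colony is called
#' mutation-positive when `S > s_threshold` (0.8).
#'
#' @param counts allele count table with a `pool_id` column (see
#'   [count_sim_pools()]), or a single-pool table.
#' @param manifest pool manifest data.frame (see [simulate_pools()]).
#' @param s_threshold calling threshold on S.
#' @return data.frame with one row per (mutation, pool): `colony_id`,
#'   `mutation_id`, `gene_id`, `position`, `ref`, `alt`, `pool_id`, `R_mut`,
#'   `R_all`, `k`, `S`, `called`. Sites with no coverage get `S = NA` and
#'   `called = FALSE` with a warning.
#' @export
score_mutations <- function(counts, manifest, s_threshold = 0.8) {
  counts <- ensure_pool_column(counts, manifest)
  key_m <- paste(manifest$pool_id, manifest$gene_id, manifest$position)
  key_c <- paste(counts$pool_id, counts$gene_id, counts$pos)
  ix <- match(key_m, key_c)
  base_cols <- as.matrix(counts[, DNA_BASES])
  r_all <- ifelse(is.na(ix), 0L, act_depth(counts)[ix])
  r_mut <- ifelse(is.na(ix), 0L,
                  base_cols[cbind(ix, match(manifest$alt, DNA_BASES))])
  k <- as.integer(stats::ave(seq_len(nrow(manifest)),
                             manifest$gene_id, manifest$pool_id,
                             FUN = length))
  s <- ifelse(r_all > 0, k * r_mut / r_all, NA_real_)
  if (anyNA(s))
    warning(sum(is.na(s)), " target site(s) with zero coverage; S undefined")
  out <- manifest
  out$R_mut <- as.integer(r_mut)
  out$R_all <- as.integer(r_all)
  out$k <- k
  out$S <- s
  out$called <- !is.na(s) & s > s_threshold
  out
}

#' Estimate the per-pool sequencing-error background rate
#'
#' The background is the unweighted mean, over all covered non-target
#' positions of a pool, of the fraction of non-reference alleles. Target
#' positions of every mutation attempted in the pool are excluded.
#'
#' @param counts allele count table with `pool_id` column.
#' @param manifest pool manifest.
#' @param min_positions minimum number of covered non-target positions
#'   required per pool.
#' @param rate_floor lower floor applied to the estimate so that downstream
#'   binomial tails are never degenerate on noise-free data.
#' @return data.frame with `pool_id`, `b_hat`, `n_positions`.
#' @export
estimate_background <- function(counts, manifest, min_positions = 100L,
                                rate_floor = 1e-6) {
  counts <- ensure_pool_column(counts, manifest)
  depth <- act_depth(counts)
  refcnt <- as.matrix(counts[, DNA_BASES])[
    cbind(seq_len(nrow(counts)), match(counts$ref, DNA_BASES))]
  nonref <- depth - refcnt
  target <- paste(counts$pool_id, counts$gene_id, counts$pos) %in%
    paste(manifest$pool_id, manifest$gene_id, manifest$position)
  out <- do.call(rbind, lapply(unique(manifest$pool_id), function(p) {
    use <- counts$pool_id == p & !target & depth > 0
    n <- sum(use)
    if (n < min_positions)
      stop("pool ", p, ": only ", n, " covered non-target positions (need >= ",
           min_positions, ")")
    data.frame(pool_id = p,
               b_hat = max(mean(nonref[use] / depth[use]), rate_floor),
               n_positions = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Detect unwanted PCR-introduced mutations
#'
#' Flags every covered non-target position whose non-reference allele count
#' is significantly higher than the pool's sequencing-error background, via
#' an upper-tail cumulative binomial test \eqn{P(X \ge nonref \mid depth,
#' \hat b) < \alpha}. The lenient default cutoff (0.2) deliberately trades
#' type I for type II errors: clones with any plausible unwanted mutation
#' are discarded rather than risked.
#'
#' Attribution: if the flagged gene has a single colony in the pool the flag
#' is attributed to it; with k > 1 co-pooled colonies of the gene, 100 nt
#' reads cannot phase the unwanted site to a colony and the flag is
#' `"ambiguous"` (disqualifying all of the gene's colonies in that pool).
#'
#' @param counts allele count table with `pool_id` column.
#' @param manifest pool manifest.
#' @param background data.frame from [estimate_background()]; computed on
#'   the fly when `NULL`.
#' @param alpha binomial tail P-value cutoff.
#' @param colony_level if `TRUE`, additionally require the non-reference
#'   fraction to be consistent with a mutation carried by at least one whole
#'   colony, i.e. fraction >= 1/(2k) for a gene with k co-pooled colonies.
#'   Used when counting true PCR mutation events (see
#'   [estimate_pcr_error_rate()]); the default (`FALSE`) is the pure
#'   statistical screen.
#' @return data.frame of flags: `pool_id`, `gene_id`, `pos`, `ref`,
#'   `nonref_count`, `depth`, `fraction`, `p_value`, `attributed_colony`.
#' @export
detect_unwanted <- function(counts, manifest, background = NULL, alpha = 0.2,
                            colony_level = FALSE) {
  counts <- ensure_pool_column(counts, manifest)
  if (is.null(background))
    background <- estimate_background(counts, manifest)
  depth <- act_depth(counts)
  refcnt <- as.matrix(counts[, DNA_BASES])[
    cbind(seq_len(nrow(counts)), match(counts$ref, DNA_BASES))]
  nonref <- depth - refcnt
  target <- paste(counts$pool_id, counts$gene_id, counts$pos) %in%
    paste(manifest$pool_id, manifest$gene_id, manifest$position)

  out <- lapply(unique(manifest$pool_id), function(p) {
    b <- background$b_hat[background$pool_id == p]
    if (!length(b)) stop("no background estimate for pool ", p)
    use <- which(counts$pool_id == p & !target & depth > 0)
    pv <- pbinom(nonref[use] - 1L, depth[use], b, lower.tail = FALSE)
    keep <- pv < alpha & nonref[use] > 0
    man_p <- manifest[manifest$pool_id == p, ]
    k_gene <- table(man_p$gene_id)
    if (colony_level) {
      kk <- as.integer(k_gene[counts$gene_id[use]])
      kk[is.na(kk)] <- 1L
      keep <- keep & (nonref[use] / depth[use] >= 1 / (2 * kk))
    }
    use <- use[keep]
    pv <- pv[keep]
    if (!length(use)) return(NULL)
    attrib <- vapply(counts$gene_id[use], function(g) {
      rows <- man_p$colony_id[man_p$gene_id == g]
      if (length(rows) == 1) rows else "ambiguous"
    }, character(1))
    data.frame(pool_id = p, gene_id = counts$gene_id[use],
               pos = counts$pos[use], ref = counts$ref[use],
               nonref_count = nonref[use], depth = depth[use],
               fraction = nonref[use] / depth[use], p_value = pv,
               attributed_colony = attrib, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(pool_id = character(), gene_id = character(),
                      pos = integer(), ref = character(),
                      nonref_count = integer(), depth = integer(),
                      fraction = numeric(), p_value = numeric(),
                      attributed_colony = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Estimate the per-base PCR error rate from flagged unwanted mutations
#'
#' Counts colony-level unwanted mutation events (binomial screen at `alpha`
#' plus the 1/(2k) colony-fraction condition of [detect_unwanted()]) and
#' divides by the total number of cloned bases in each pool (the summed
#' lengths of all colony inserts), the quantity reported as the PCR
#' polymerase error rate.
#'
#' @param counts allele count table with `pool_id` column.
#' @param manifest pool manifest.
#' @param genes named character vector of reference sequences (for insert
#'   lengths).
#' @param background optional precomputed [estimate_background()] result.
#' @param alpha binomial tail cutoff passed to [detect_unwanted()].
#' @return data.frame per pool: `n_flagged`, `cloned_bases`, `rate`,
#'   `percent`.
#' @export
estimate_pcr_error_rate <- function(counts, manifest, genes,
                                    background = NULL, alpha = 0.2) {
  assert_genes(genes)
  flags <- detect_unwanted(counts, manifest, background, alpha,
                           colony_level = TRUE)
  glen <- nchar(genes)
  out <- do.call(rbind, lapply(unique(manifest$pool_id), function(p) {
    nb <- sum(glen[manifest$gene_id[manifest$pool_id == p]])
    nf <- sum(flags$pool_id == p)
    data.frame(pool_id = p, n_flagged = nf, cloned_bases = nb,
               rate = nf / nb, percent = 100 * nf / nb,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Resolve usable clones across pools
#'
#' A colony is usable in a pool when its mutation is called (`S > 0.8`) and
#' no unwanted-mutation flag on its gene in that pool disqualifies it (a
#' flag attributed to the colony itself, or an `"ambiguous"` flag which
#' disqualifies every co-pooled colony of that gene). Each mutation's
#' `chosen_pool` is the first pool, in manifest order, with a usable colony.
#'
#' @param scores output of [score_mutations()].
#' @param flags output of [detect_unwanted()].
#' @param manifest pool manifest.
#' @return data.frame with one row per mutation: `mutation_id`, `gene_id`,
#'   `chosen_pool` (NA if none) and `status` in `usable`,
#'   `disqualified_unwanted`, `failed_mutagenesis`, `unresolved`. The
#'   per-(mutation, pool) detail table is attached as attribute
#'   `pool_table` (columns `called`, `disqualified`, `usable`).
#' @export
resolve_clones <- function(scores, flags, manifest) {
  disq <- logical(nrow(scores))
  if (nrow(flags)) {
    for (i in seq_len(nrow(flags))) {
      hit <- scores$pool_id == flags$pool_id[i] &
        scores$gene_id == flags$gene_id[i]
      if (flags$attributed_colony[i] != "ambiguous")
        hit <- hit & scores$colony_id == flags$attributed_colony[i]
      disq <- disq | hit
    }
  }
  pool_table <- data.frame(
    colony_id = scores$colony_id, mutation_id = scores$mutation_id,
    gene_id = scores$gene_id, pool_id = scores$pool_id, S = scores$S,
    called = scores$called, disqualified = disq,
    usable = scores$called & !disq, stringsAsFactors = FALSE)

  pool_order <- unique(manifest$pool_id)
  muts <- unique(manifest[, c("mutation_id", "gene_id")])
  verdict <- do.call(rbind, lapply(seq_len(nrow(muts)), function(i) {
    rows <- pool_table[pool_table$mutation_id == muts$mutation_id[i], ]
    rows <- rows[order(match(rows$pool_id, pool_order)), ]
    usable <- rows$pool_id[rows$usable]
    status <- if (length(usable)) "usable"
      else if (any(rows$called)) "disqualified_unwanted"
      else if (any(!is.na(rows$S))) "failed_mutagenesis"
      else "unresolved"
    data.frame(mutation_id = muts$mutation_id[i], gene_id = muts$gene_id[i],
               chosen_pool = if (length(usable)) usable[[1]] else NA_character_,
               status = status, stringsAsFactors = FALSE)
  }))
  rownames(verdict) <- NULL
  attr(verdict, "pool_table") <- pool_table
  verdict
}
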