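#' Canonical pooled-mutagenesis experiment layouts
#'
#' Reconstructs the three pooled site-directed mutagenesis experiments the
#' pipeline was validated on, as synthetic worlds with known ground truth:
#'
#' * `pilot39`: 39 mutations on 39 genes (500-2500 nt), 4 pools
#'   (156 colonies), per-colony success 0.80, ~2500x coverage;
#' * `exome113`: 113 mutations on 66 genes (so several genes carry k > 1
#'   co-pooled mutations), 4 pools (452 colonies), success 0.82, ~1000x
#'   coverage;
#' * `hiseq882`: 882 mutations across 300 genes including one gene carrying
#'   40 mutations (k up to 40), 4 pools (3528 colonies), success 0.84,
#'   coverage scaled down to ~100x so the experiment runs at desk scale.
#'
#' All use 1x100 bp reads, sequencing error 1e-3 and PCR error 1.3e-4.
#'
#' @param name experiment name.
#' @param seed integer seed controlling both the world construction and the
#'   simulation.
#' @param coverage optional override of the per-pool coverage.
#' @return list with `genes`, `mutations`, `n_pools`, `config`,
#'   `p_success`, `n_colonies`.
#' @export
experiment_spec <- function(name = c("pilot39", "exome113", "hiseq882"),
                            seed = 1L, coverage = NULL) {
  name <- match.arg(name)
  set.seed(seed)
  if (name == "pilot39") {
    genes <- sim_genes(39, 500L, 2500L)
    mutations <- sim_mutations(genes, 39)
    p <- 0.80
    cov <- coverage %||% 2500
  } else if (name == "exome113") {
    genes <- sim_genes(66, 500L, 2500L)
    gene_ids <- c(names(genes), sample(names(genes), 113 - 66,
                                       replace = TRUE))
    mutations <- sim_mutations(genes, 113, gene_ids = gene_ids)
    p <- 0.82
    cov <- coverage %||% 1000
  } else {
    lengths <- sample(seq.int(500L, 2500L), 300, replace = TRUE)
    lengths[1] <- 2400L  # the 40-mutation gene needs headroom
    genes <- sim_genes(300, lengths = lengths)
    gene_ids <- c(rep(names(genes)[1], 40),
                  names(genes)[-1],
                  sample(names(genes)[-1], 882 - 40 - 299, replace = TRUE))
    mutations <- sim_mutations(genes, 882, gene_ids = gene_ids)
    p <- 0.84
    cov <- coverage %||% 100
  }
  list(genes = genes, mutations = mutations, n_pools = 4L,
       config = sim_config(p_success = p, pcr_error_rate = 1.3e-4,
                           seq_error_rate = 1e-3, coverage = cov,
                           seed = seed + 7000L),
       p_success = p, n_colonies = 4L * nrow(mutations))
}

#' Run a pooled-mutagenesis experiment end to end
#'
#' Simulates the pools, maps every pool's reads with the built-in mapper,
#' scores all attempted mutations and compares the calls against the
#' planted truth. FASTQ files are deleted as each pool is mapped.
#'
#' @param spec result of [experiment_spec()] (or a hand-built list with the
#'   same fields).
#' @param keep_counts if `FALSE`, the (large) allele count table is dropped
#'   from the result.
#' @return list: `scores`, `truth`, `manifest`, `n_called` (colonies with
#'   S > 0.8), `n_true_success` (planted successes), `agreement` (fraction
#'   of colonies whose call equals the planted truth), `min_s_success`,
#'   `max_s_failure`, and optionally `counts`.
#' @export
run_experiment <- function(spec, keep_counts = FALSE) {
  sim <- simulate_pools(spec$genes, spec$mutations, spec$n_pools,
                        spec$config)
  counts <- count_sim_pools(sim, spec$genes, keep_fastq = FALSE)
  scores <- score_mutations(counts, sim$manifest)
  truth <- sim$truth$colonies
  stopifnot(identical(scores$colony_id, truth$colony_id))
  res <- list(scores = scores, truth = sim$truth, manifest = sim$manifest,
              n_called = sum(scores$called),
              n_true_success = sum(truth$success),
              agreement = mean(scores$called == truth$success),
              min_s_success = suppressWarnings(
                min(scores$S[truth$success], na.rm = TRUE)),
              max_s_failure = suppressWarnings(
                max(scores$S[!truth$success], na.rm = TRUE)))
  if (keep_counts) res$counts <- counts
  unlink(sim$out_dir, recursive = TRUE)
  res
}

#' One unwanted-mutation rate measurement
#'
#' Simulates a single pool of 39 single-mutation colonies on genes
#' averaging ~900 nt with PCR errors planted at `pcr_error_rate`, runs the
#' mapping, background-estimation and colony-level binomial flagging
#' pipeline, and returns the measured per-base unwanted-mutation rate.
#'
#' @param seed integer seed.
#' @param pcr_error_rate planted per-base PCR error probability.
#' @param coverage per-pool coverage.
#' @return list: `n_flagged`, `n_planted`, `cloned_bases`, `rate`,
#'   `percent`.
#' @export
pcr_rate_trial <- function(seed, pcr_error_rate = 1.3e-4, coverage = 2500) {
  set.seed(seed)
  genes <- sim_genes(39, 600L, 1200L)
  mutations <- sim_mutations(genes, 39)
  cfg <- sim_config(p_success = 0.8, pcr_error_rate = pcr_error_rate,
                    seq_error_rate = 1e-3, coverage = coverage,
                    seed = seed + 5000L)
  sim <- simulate_pools(genes, mutations, 1L, cfg)
  counts <- count_sim_pools(sim, genes, keep_fastq = FALSE)
  bg <- estimate_background(counts, sim$manifest)
  er <- estimate_pcr_error_rate(counts, sim$manifest, genes, bg)
  unlink(sim$out_dir, recursive = TRUE)
  list(n_flagged = er$n_flagged, n_planted = nrow(sim$truth$unwanted),
       cloned_bases = er$cloned_bases, rate = er$rate,
       percent = er$percent)
}
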