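#' Simulation configuration for synthetic Clone-seq pools
#'
#' Captures the stochastic model of a pooled mutagenesis sequencing
#' experiment: per-colony mutagenesis success probability, per-base PCR
#' (polymerase) error rate, per-base sequencing substitution error rate, mean
#' per-site read depth and read length.
#'
#' Defaults correspond to the experimental regime the pipeline was built
#' for: 80% PCR-mutagenesis success, a 0.013% per-base PCR error rate,
#' roughly 1e-3 flat Illumina substitution error, and >2500x coverage of
#' 1x100 bp reads.
#'
#' @param p_success probability that a picked colony carries the desired
#'   mutation.
#' @param pcr_error_rate per-base probability of an unwanted PCR mutation in
#'   a colony's plasmid.
#' @param seq_error_rate per-base sequencing substitution error rate.
#' @param coverage target mean per-site read depth contributed by one pool.
#' @param read_length read length in nt (1x100 bp by default).
#' @param seed integer seed for reproducible simulation, or `NULL`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(p_success = 0.8, pcr_error_rate = 1.3e-4,
                       seq_error_rate = 1e-3, coverage = 2500,
                       read_length = 100L, seed = NULL) {
  probs <- c(p_success = p_success, pcr_error_rate = pcr_error_rate,
             seq_error_rate = seq_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (coverage <= 0) stop("coverage must be > 0")
  if (read_length < 20) stop("read_length too short")
  structure(list(p_success = p_success, pcr_error_rate = pcr_error_rate,
                 seq_error_rate = seq_error_rate, coverage = coverage,
                 read_length = as.integer(read_length), seed = seed),
            class = "sim_config")
}

#' Generate random ORF reference sequences
#'
#' @param n number of genes.
#' @param min_len,max_len sequence length bounds in nt (sampled uniformly).
#' @param gc GC content of the random sequences.
#' @param prefix gene identifier prefix.
#' @param lengths optional explicit integer vector of lengths (overrides
#'   `min_len`/`max_len`).
#' @return named character vector of DNA sequences.
#' @export
sim_genes <- function(n, min_len = 500L, max_len = 2500L, gc = 0.5,
                      prefix = "gene", lengths = NULL) {
  if (is.null(lengths))
    lengths <- min_len + sample.int(max_len - min_len + 1L, n,
                                    replace = TRUE) - 1L
  stopifnot(length(lengths) == n, all(lengths >= 50))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lengths, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE, prob = p), collapse = ""),
    character(1))
  setNames(seqs, sprintf("%s%03d", prefix, seq_len(n)))
}

#' Draw desired single-nucleotide mutations on reference genes
#'
#' Mutation identifiers follow the `<gene>_<ref><pos><alt>` convention
#' (e.g. `geneIV_G511A`).
#'
#' @param genes named character vector of reference sequences.
#' @param n total number of mutations.
#' @param gene_ids optional character vector of length `n` assigning each
#'   mutation to a gene; by default genes are used round-robin.
#' @param min_edge minimum distance of a mutation site from either gene end
#'   (keeps sites fully covered by reads and leaves primer-design headroom).
#' @return data.frame with columns `mutation_id`, `gene_id`, `position`,
#'   `ref`, `alt`. Positions are distinct within each gene.
#' @export
sim_mutations <- function(genes, n, gene_ids = NULL, min_edge = 101L) {
  assert_genes(genes)
  if (is.null(gene_ids))
    gene_ids <- rep_len(names(genes), n)
  stopifnot(length(gene_ids) == n, all(gene_ids %in% names(genes)))
  pos <- integer(n)
  for (g in unique(gene_ids)) {
    idx <- which(gene_ids == g)
    L <- nchar(genes[[g]])
    lo <- min_edge
    hi <- L - min_edge + 1L
    if (hi - lo + 1L < length(idx))
      stop("gene ", g, " too short for ", length(idx), " distinct sites")
    pos[idx] <- sample(seq.int(lo, hi), length(idx))
  }
  ref <- substring(genes[gene_ids], pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1),
                character(1), USE.NAMES = FALSE)
  out <- data.frame(mutation_id = sprintf("%s_%s%d%s", gene_ids, ref, pos,
                                          alt),
                    gene_id = gene_ids, position = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a pooled Clone-seq experiment
#'
#' One colony is picked per desired mutation per pool. With probability
#' `p_success` the colony's plasmid carries the desired mutation (failed
#' colonies are pure wild type); unwanted PCR mutations are planted
#' independently per base at `pcr_error_rate` at non-target positions.
#' DNA concentrations are normalized across colonies, so every colony of a
#' pool contributes the same expected number of reads. Reads are ungapped
#' substrings drawn uniformly along the plasmid with substitution sequencing
#' errors at `seq_error_rate`, written as one FASTQ file per pool.
#'
#' @param genes named character vector of reference ORF sequences.
#' @param mutations data.frame as returned by [sim_mutations()].
#' @param n_pools number of pools (colonies picked per mutation).
#' @param config a [sim_config()] object.
#' @param out_dir directory for FASTQ/manifest/truth output (created if
#'   needed); defaults to a fresh temporary directory.
#' @return an object of class `cloneseq_sim`: list with `manifest`
#'   (colony_id, mutation_id, gene_id, position, ref, alt, pool_id),
#'   `fastq` (named vector of per-pool FASTQ paths), `truth` (list with
#'   `colonies` and `unwanted` data.frames recording every planted event),
#'   and `config`.
#' @export
simulate_pools <- function(genes, mutations, n_pools, config = sim_config(),
                           out_dir = tempfile("cloneseq_sim_")) {
  assert_genes(genes)
  assert_mutations(mutations, genes)
  stopifnot(n_pools >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  glen <- nchar(genes)
  lbar <- mean(glen[mutations$gene_id])
  reads_per_colony <- config$coverage * lbar / config$read_length
  exp_depth <- reads_per_colony * config$read_length / glen[mutations$gene_id]
  if (any(exp_depth < 1))
    warning("expected per-colony depth < 1 at some target sites; ",
            "calls there will be unreliable")

  pool_ids <- sprintf("pool%d", seq_len(n_pools))
  manifest <- do.call(rbind, lapply(pool_ids, function(p) {
    m <- mutations
    m$pool_id <- p
    m$colony_id <- paste(m$mutation_id, p, sep = ".")
    m[, c("colony_id", "mutation_id", "gene_id", "position", "ref", "alt",
          "pool_id")]
  }))
  rownames(manifest) <- NULL

  fastq <- setNames(file.path(out_dir, paste0(pool_ids, ".fastq")), pool_ids)
  success <- logical(nrow(manifest))
  n_reads <- integer(nrow(manifest))
  unw <- vector("list", nrow(manifest))

  for (p in pool_ids) {
    rows <- which(manifest$pool_id == p)
    append <- FALSE
    for (i in rows) {
      g <- manifest$gene_id[i]
      L <- glen[[g]]
      succ <- runif(1) < config$p_success
      cseq <- genes[[g]]
      if (succ)
        substr(cseq, manifest$position[i], manifest$position[i]) <-
          manifest$alt[i]
      n_unw <- rbinom(1, L, config$pcr_error_rate)
      if (n_unw > 0) {
        upos <- sample(seq_len(L)[-manifest$position[i]], n_unw)
        uref <- substring(genes[[g]], upos, upos)
        ualt <- vapply(uref, function(b) sample(setdiff(DNA_BASES, b), 1),
                       character(1), USE.NAMES = FALSE)
        for (j in seq_len(n_unw)) substr(cseq, upos[j], upos[j]) <- ualt[j]
        unw[[i]] <- data.frame(colony_id = manifest$colony_id[i],
                               pool_id = p, gene_id = g, position = upos,
                               ref = uref, alt = ualt,
                               stringsAsFactors = FALSE)
      }
      nr <- rpois(1, reads_per_colony)
      cpp_sim_reads(cseq, nr, config$read_length, config$seq_error_rate,
                    manifest$colony_id[i], fastq[[p]], append)
      append <- TRUE
      success[i] <- succ
      n_reads[i] <- nr
    }
  }

  colonies <- manifest
  colonies$success <- success
  colonies$n_reads <- n_reads
  unwanted <- if (all(vapply(unw, is.null, logical(1)))) {
    data.frame(colony_id = character(), pool_id = character(),
               gene_id = character(), position = integer(),
               ref = character(), alt = character(), stringsAsFactors = FALSE)
  } else do.call(rbind, unw[!vapply(unw, is.null, logical(1))])
  rownames(unwanted) <- NULL

  sim <- structure(list(manifest = manifest, fastq = fastq,
                        truth = list(colonies = colonies, unwanted = unwanted),
                        config = config, out_dir = out_dir),
                   class = "cloneseq_sim")
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  sim
}

#' @export
print.cloneseq_sim <- function(x, ...) {
  cat("Clone-seq simulation:", length(unique(x$manifest$mutation_id)),
      "mutations x", length(x$fastq), "pools =", nrow(x$manifest),
      "colonies\n")
  cat("  planted successes:", sum(x$truth$colonies$success),
      " unwanted mutations:", nrow(x$truth$unwanted), "\n")
  cat("  FASTQ dir:", x$out_dir, "\n")
  invisible(x)
}

#' Write / read a pool manifest
#'
#' @param manifest data.frame with columns `colony_id`, `mutation_id`,
#'   `gene_id`, `position`, `ref`, `alt`, `pool_id`.
#' @param path TSV path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(manifest, path, sep = "\t")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t"))
  need <- c("colony_id", "mutation_id", "gene_id", "position", "ref", "alt",
            "pool_id")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m
}
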