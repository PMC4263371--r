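#' Melting temperature of a mutagenesis primer
#'
#' The QuikChange-protocol estimate
#' \deqn{T_m = 81.5 + 0.41\,(\%GC) - 675/N - \%mismatch}
#' where `N` is the primer length in bases, `%GC` the percentage of G or C
#' nucleotides and `%mismatch` the percentage of mismatched bases relative
#' to the template. Following the protocol's integer-percent convention,
#' `%GC` and `%mismatch` are rounded half-up to whole numbers before use.
#'
#' @param n primer length in bases.
#' @param pct_gc GC percentage (any numeric; rounded to a whole number).
#' @param pct_mismatch mismatch percentage (rounded to a whole number).
#' @return melting temperature in degrees Celsius.
#' @examples
#' primer_tm(45, 50, 2)  # 81.5 + 20.5 - 15 - 2 = 85
#' @export
primer_tm <- function(n, pct_gc, pct_mismatch = 0) {
  stopifnot(all(n > 0))
  81.5 + 0.41 * round_half_up(pct_gc) - 675 / n - round_half_up(pct_mismatch)
}

# enumerate all candidate primers for one mutation: lengths 30-50,
# mutation at the primer center or one base off
enumerate_primer_candidates <- function(gene, position, alt,
                                        min_len = 30L, max_len = 50L) {
  L <- nchar(gene)
  grid <- expand.grid(N = seq.int(min_len, max_len), offset = c(-1L, 0L, 1L))
  centre <- ifelse(grid$N %% 2L == 0L, grid$N %/% 2L, (grid$N + 1L) %/% 2L)
  relpos <- centre + grid$offset
  start <- position - relpos + 1L
  end <- start + grid$N - 1L
  ok <- start >= 1L & end <= L
  grid <- grid[ok, , drop = FALSE]
  relpos <- relpos[ok]
  start <- start[ok]
  end <- end[ok]
  seqs <- substring(gene, start, end)
  substr(seqs, relpos, relpos) <- alt
  n_gc <- nchar(gsub("[AT]", "", seqs))
  pct_gc <- round_half_up(100 * n_gc / grid$N)
  pct_mm <- round_half_up(100 * 1 / grid$N)  # single-nt substitution
  data.frame(sequence = seqs, start = start, end = end, N = grid$N,
             mutation_offset = grid$offset, pct_gc = pct_gc,
             pct_mismatch = pct_mm,
             tm = 81.5 + 0.41 * pct_gc - 675 / grid$N - pct_mm,
             gc_clamp = grepl("^[GC]", seqs) & grepl("[GC]$", seqs),
             stringsAsFactors = FALSE)
}

#' Design a QuikChange-style mutagenesis primer pair
#'
#' Enumerates every candidate primer of length 30-50 bp containing the
#' desired mutation at the center or one base away, and keeps candidates
#' that (1) start and end with G or C, (2) have GC content >= 40%
#' (>= 30% under relaxation) and (3) have a melting temperature
#' [primer_tm()] >= 78 degrees C. Among passing candidates the best is the
#' one with highest Tm, then shortest length, then central mutation
#' placement, then leftmost start. The reverse primer is the exact reverse
#' complement of the forward primer.
#'
#' @param genes named character vector of template sequences.
#' @param mutation a one-row data.frame or list with `gene_id`, `position`,
#'   `ref`, `alt` (and optionally `mutation_id`).
#' @param relax if `TRUE` (default), fall back to the relaxed GC bound when
#'   no candidate satisfies all strict criteria.
#' @param min_gc,relaxed_gc strict and relaxed GC-content bounds (percent).
#' @param min_tm melting-temperature bound (degrees C).
#' @return list of class `primer_pair`: `forward` and `reverse` candidate
#'   lists (sequence, start, end, N, pct_gc, pct_mismatch, tm,
#'   mutation_offset), plus `relaxed` flag and `mutation_id`.
#' @export
design_primer_pair <- function(genes, mutation, relax = TRUE, min_gc = 40,
                               relaxed_gc = 30, min_tm = 78) {
  mutation <- as.list(mutation)
  gene <- genes[[mutation$gene_id]]
  if (is.null(gene)) stop("unknown gene: ", mutation$gene_id)
  L <- nchar(gene)
  pos <- mutation$position
  if (pos < 26L || pos > L - 25L)
    stop("mutation site less than 25 nt from a template end (position ",
         pos, ", length ", L, ")")
  if (substring(gene, pos, pos) != mutation$ref)
    stop("ref base does not match template at position ", pos)

  cand <- enumerate_primer_candidates(gene, pos, mutation$alt)
  cand <- cand[cand$tm >= min_tm & cand$gc_clamp, , drop = FALSE]
  strict <- cand[cand$pct_gc >= min_gc, , drop = FALSE]
  relaxed_used <- FALSE
  if (nrow(strict) == 0 && relax) {
    strict <- cand[cand$pct_gc >= relaxed_gc, , drop = FALSE]
    relaxed_used <- TRUE
  }
  if (nrow(strict) == 0) {
    all_cand <- enumerate_primer_candidates(gene, pos, mutation$alt)
    stop("no primer for ", mutation$gene_id, ":", pos,
         " satisfies the design criteria",
         if (relax) " even after GC relaxation" else "",
         " (", sum(!all_cand$gc_clamp), "/", nrow(all_cand),
         " fail the G/C-ends rule, ",
         sum(all_cand$pct_gc < relaxed_gc), " fail GC >= ", relaxed_gc,
         "%, ", sum(all_cand$tm < min_tm), " fail Tm >= ", min_tm, ")")
  }
  best <- strict[order(-strict$tm, strict$N, abs(strict$mutation_offset),
                       strict$start), , drop = FALSE][1, ]
  fwd <- as.list(best[, c("sequence", "start", "end", "N", "pct_gc",
                          "pct_mismatch", "tm", "mutation_offset")])
  rev <- fwd
  rev$sequence <- revcomp(fwd$sequence)
  structure(list(forward = fwd, reverse = rev, relaxed = relaxed_used,
                 mutation_id = mutation$mutation_id %||%
                   sprintf("%s_%s%d%s", mutation$gene_id, mutation$ref,
                           pos, mutation$alt)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("primer pair for %s (N=%d, GC=%d%%, Tm=%.1f C%s)\n",
              x$mutation_id, x$forward$N, x$forward$pct_gc, x$forward$tm,
              if (x$relaxed) ", relaxed GC" else ""))
  cat("  fwd 5'-", x$forward$sequence, "-3'\n", sep = "")
  cat("  rev 5'-", x$reverse$sequence, "-3'\n", sep = "")
  invisible(x)
}

#' Design mutagenesis primers in batch
#'
#' Independent per-mutation design; failures are collected in a report, not
#' fatal, and input order is preserved.
#'
#' @param genes named character vector of template sequences.
#' @param mutations data.frame of mutations (see [sim_mutations()] for the
#'   column convention).
#' @param relax passed to [design_primer_pair()].
#' @return list with `primers` (data.frame: mutation_id, fwd_seq, rev_seq,
#'   N, pct_gc, pct_mismatch, tm, mutation_offset, relaxed), `pairs` (list
#'   of `primer_pair` objects) and `failures` (data.frame: mutation_id,
#'   error).
#' @export
design_primer_batch <- function(genes, mutations, relax = TRUE) {
  pairs <- list()
  rows <- list()
  fails <- list()
  for (i in seq_len(nrow(mutations))) {
    mut <- mutations[i, ]
    res <- tryCatch(design_primer_pair(genes, mut, relax = relax),
                    error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(mutation_id = mut$mutation_id, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      pairs[[res$mutation_id]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        mutation_id = res$mutation_id, fwd_seq = res$forward$sequence,
        rev_seq = res$reverse$sequence, N = res$forward$N,
        pct_gc = res$forward$pct_gc, pct_mismatch = res$forward$pct_mismatch,
        tm = res$forward$tm, mutation_offset = res$forward$mutation_offset,
        relaxed = res$relaxed, stringsAsFactors = FALSE)
    }
  }
  empty_primers <- data.frame(
    mutation_id = character(), fwd_seq = character(), rev_seq = character(),
    N = integer(), pct_gc = numeric(), pct_mismatch = numeric(),
    tm = numeric(), mutation_offset = integer(), relaxed = logical(),
    stringsAsFactors = FALSE)
  list(primers = if (length(rows)) do.call(rbind, rows) else empty_primers,
       pairs = pairs,
       failures = if (length(fails)) do.call(rbind, fails) else
         data.frame(mutation_id = character(), error = character(),
                    stringsAsFactors = FALSE))
}

#' Write a primer batch to TSV
#'
#' @param batch result of [design_primer_batch()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_primers <- function(batch, path) {
  data.table::fwrite(batch$primers, path, sep = "\t")
  invisible(path)
}
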