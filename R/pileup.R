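#' Map reads and tabulate per-position allele counts
#'
#' Minimal built-in ungapped mapper for the substitution-only reads produced
#' by pooled plasmid sequencing (and by [simulate_pools()]). Each read is
#' assigned to the (gene, offset, strand) minimizing Hamming distance over
#' exact k-mer seed hits; both the read and its reverse complement are tried
#' (plasmid sequencing carries no strand semantics). Reads whose best
#' distance exceeds `max_mm_frac` of the read length, or whose best
#' assignment is ambiguous, are discarded and tallied.
#'
#' @param reads path to a FASTQ file, or a character vector of read
#'   sequences (written to a temporary FASTQ internally).
#' @param genes named character vector of reference ORF sequences.
#' @param kmer seed k-mer length.
#' @param step seed spacing along the read in nt.
#' @param max_mm_frac maximum mismatch fraction for a read to be kept.
#' @return an allele count table: data.frame with columns `gene_id`, `pos`
#'   (1-based), `ref`, `A`, `C`, `G`, `T`, `other`, one row per reference
#'   position, with a `stats` attribute (n_total, n_mapped, n_ambiguous,
#'   n_unmapped).
#' @export
map_and_count <- function(reads, genes, kmer = 15L, step = 10L,
                          max_mm_frac = 0.10) {
  assert_genes(genes)
  if (length(reads) == 1 && file.exists(reads)) {
    path <- reads
  } else {
    path <- tempfile(fileext = ".fastq")
    on.exit(unlink(path))
    writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n",
                      vapply(nchar(reads), function(n)
                        strrep("I", n), character(1))), path, sep = "\n")
  }
  res <- cpp_map_fastq(path, names(genes), unname(genes), as.integer(kmer),
                       as.integer(step), max_mm_frac)
  out <- allele_counts_from_matrices(res$counts, genes)
  if (res$n_unmapped > 0 || res$n_ambiguous > 0)
    message(sprintf("map_and_count: %d/%d reads discarded (%d unmappable, %d ambiguous)",
                    res$n_unmapped + res$n_ambiguous, res$n_total,
                    res$n_unmapped, res$n_ambiguous))
  attr(out, "stats") <- list(n_total = res$n_total, n_mapped = res$n_mapped,
                             n_ambiguous = res$n_ambiguous,
                             n_unmapped = res$n_unmapped)
  out
}

allele_counts_from_matrices <- function(mats, genes) {
  pieces <- lapply(names(mats), function(g) {
    m <- mats[[g]]
    L <- ncol(m)
    data.table::data.table(
      gene_id = g, pos = seq_len(L),
      ref = strsplit(genes[[g]], "", fixed = TRUE)[[1]],
      A = m["A", ], C = m["C", ], G = m["G", ], T = m["T", ],
      other = m["other", ])
  })
  as.data.frame(data.table::rbindlist(pieces))
}

#' Allele counts for every pool of a simulated experiment
#'
#' Maps each pool's FASTQ with [map_and_count()] and stacks the results with
#' a `pool_id` column, the input format expected by [score_mutations()].
#'
#' @param sim a `cloneseq_sim` object from [simulate_pools()].
#' @param genes the reference sequences used in the simulation.
#' @param keep_fastq if `FALSE`, each pool's FASTQ is deleted after mapping
#'   (keeps disk usage flat for large simulations).
#' @param ... passed to [map_and_count()].
#' @return allele count data.frame with an extra leading `pool_id` column;
#'   per-pool mapping stats in the `stats` attribute.
#' @export
count_sim_pools <- function(sim, genes, keep_fastq = TRUE, ...) {
  stopifnot(inherits(sim, "cloneseq_sim"))
  stats <- list()
  pieces <- lapply(names(sim$fastq), function(p) {
    ct <- map_and_count(sim$fastq[[p]], genes, ...)
    stats[[p]] <<- attr(ct, "stats")
    if (!keep_fastq) unlink(sim$fastq[[p]])
    cbind(pool_id = p, ct)
  })
  out <- as.data.frame(data.table::rbindlist(pieces))
  attr(out, "stats") <- stats
  out
}

#' Read allele counts from samtools-mpileup-dialect text
#'
#' Parses the classic 6-column `samtools mpileup` text output (chrom, pos,
#' ref, depth, base string, qualities). Match symbols `.`/`,` count toward
#' the reference base, `ACGTacgt` toward the respective alternative;
#' read-start (`^X`), read-end (`$`) markers and indel blocks (`+n`/`-n`
#' followed by n bases) are stripped without being counted. Any other symbol
#' (e.g. `*`, `N`) falls into `other`.
#'
#' @param path path to an mpileup-dialect text file.
#' @param genes named character vector of reference sequences the pileup was
#'   computed against.
#' @return allele count data.frame (`gene_id`, `pos`, `ref`, `A`, `C`, `G`,
#'   `T`, `other`); depth-0 rows are retained with zero counts.
#' @export
read_mpileup <- function(path, genes) {
  assert_genes(genes)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  out <- data.frame(gene_id = character(n), pos = integer(n),
                    ref = character(n), A = integer(n), C = integer(n),
                    G = integer(n), T = integer(n), other = integer(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1) f <- strsplit(lines[[i]], "[[:space:]]+")[[1]]
    if (length(f) < 5)
      stop("malformed mpileup line ", i, ": expected >= 5 fields")
    g <- f[[1]]
    if (!g %in% names(genes))
      stop("mpileup line ", i, ": unknown gene_id '", g, "'")
    p <- suppressWarnings(as.integer(f[[2]]))
    depth <- suppressWarnings(as.integer(f[[4]]))
    if (is.na(p) || is.na(depth))
      stop("malformed mpileup line ", i, ": non-numeric pos/depth")
    if (p < 1 || p > nchar(genes[[g]]))
      stop("mpileup line ", i, ": position outside gene ", g)
    ref <- toupper(f[[3]])
    ref_at <- substring(genes[[g]], p, p)
    if (ref %in% DNA_BASES && ref != ref_at)
      stop("mpileup line ", i, ": reference base mismatch for ", g, ":", p)
    cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L, other = 0L)
    if (depth > 0)
      cnt <- parse_pileup_bases(f[[5]], ref_at, i)
    out$gene_id[i] <- g
    out$pos[i] <- p
    out$ref[i] <- ref_at
    out$A[i] <- cnt[["A"]]
    out$C[i] <- cnt[["C"]]
    out$G[i] <- cnt[["G"]]
    out$T[i] <- cnt[["T"]]
    out$other[i] <- cnt[["other"]]
  }
  out
}

parse_pileup_bases <- function(bases, ref, line_no) {
  cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L, other = 0L)
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "^") {          # read start; next char is mapping quality
      if (i + 1L > n)
        stop("malformed mpileup line ", line_no, ": dangling '^'")
      i <- i + 2L
    } else if (ch == "$") {   # read end marker
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {  # indel block: [+-]<n><bases>
      j <- i + 1L
      num <- ""
      while (j <= n && chars[[j]] >= "0" && chars[[j]] <= "9") {
        num <- paste0(num, chars[[j]])
        j <- j + 1L
      }
      if (!nzchar(num))
        stop("malformed mpileup line ", line_no, ": indel without length")
      i <- j + as.integer(num)
    } else if (ch == "." || ch == ",") {
      cnt[ref] <- cnt[ref] + 1L
      i <- i + 1L
    } else {
      up <- toupper(ch)
      if (up %in% DNA_BASES) cnt[up] <- cnt[up] + 1L
      else cnt["other"] <- cnt["other"] + 1L
      i <- i + 1L
    }
  }
  cnt
}

#' Write / read an allele count table
#'
#' @param counts allele count data.frame (optionally with `pool_id`).
#' @param path TSV path.
#' @return `write_allele_counts` returns `path` invisibly;
#'   `read_allele_counts` returns the data.frame.
#' @export
write_allele_counts <- function(counts, path) {
  data.table::fwrite(counts, path, sep = "\t")
  invisible(path)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
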