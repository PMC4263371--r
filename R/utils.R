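DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' @param x character vector of sequences over A/C/G/T (N allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# round half up (protocol integer-percent convention; R's round() is
# round-half-even)
round_half_up <- function(x) floor(x + 0.5)

assert_genes <- function(genes) {
  if (!is.character(genes) || is.null(names(genes)) || length(genes) == 0)
    stop("genes must be a non-empty named character vector of DNA sequences")
  if (anyDuplicated(names(genes)))
    stop("duplicated gene_id in reference set")
  bad <- grepl("[^ACGT]", genes)
  if (any(bad))
    stop("gene sequence with characters outside ACGT: ",
         paste(names(genes)[bad], collapse = ", "))
  invisible(genes)
}

assert_mutations <- function(mutations, genes) {
  need <- c("mutation_id", "gene_id", "position", "ref", "alt")
  if (!all(need %in% names(mutations)))
    stop("mutations must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(mutations$gene_id, names(genes))
  if (length(unknown))
    stop("mutation references unknown gene: ", paste(unknown, collapse = ", "))
  len <- nchar(genes)[mutations$gene_id]
  if (any(mutations$position < 1 | mutations$position > len))
    stop("mutation position outside gene length")
  at <- substring(genes[mutations$gene_id], mutations$position,
                  mutations$position)
  if (any(at != mutations$ref))
    stop("ref base does not match reference sequence at mutation position")
  if (any(mutations$ref == mutations$alt))
    stop("ref and alt base must differ")
  invisible(mutations)
}

#' Read an ORF reference FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; sequences are
#' upper-cased and identifiers taken as the first whitespace-delimited
#' token of each header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_gene_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write an ORF reference FASTA
#'
#' @param genes named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_fasta <- function(genes, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genes), path)
  invisible(path)
}

# internal: hand-rolled --flag value parser used by the CLI and scripts
parse_cli_args <- function(args, defaults) {
  out <- defaults
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3L))
    if (!key %in% names(defaults)) stop("unknown option: ", a)
    if (is.logical(defaults[[key]])) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("missing value for option: ", a)
      val <- args[[i + 1L]]
      out[[key]] <- if (is.numeric(defaults[[key]])) as.numeric(val) else val
      i <- i + 2L
    }
  }
  out
}
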