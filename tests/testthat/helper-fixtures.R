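# shared fixtures, all built in code

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# plant specific reference bases into a random backbone
plant_bases <- function(seq, positions, bases) {
  for (i in seq_along(positions))
    substr(seq, positions[i], positions[i]) <- bases[i]
  seq
}

# The worked five-gene pooled example: genes I-V (600 nt each), desired
# mutations I_T116A, II_G298T, III_A41T, III_C194T, IV_C74T, IV_G511A,
# V_T53G, V_G272A, plus an unwanted C436G on gene V in pool 1.
fig2a_world <- function() {
  set.seed(424242)
  genes <- setNames(vapply(1:5, function(i) random_dna(600), character(1)),
                    c("I", "II", "III", "IV", "V"))
  genes[["I"]] <- plant_bases(genes[["I"]], 116, "T")
  genes[["II"]] <- plant_bases(genes[["II"]], 298, "G")
  genes[["III"]] <- plant_bases(genes[["III"]], c(41, 194), c("A", "C"))
  genes[["IV"]] <- plant_bases(genes[["IV"]], c(74, 511), c("C", "G"))
  genes[["V"]] <- plant_bases(genes[["V"]], c(53, 272, 436),
                              c("T", "G", "C"))
  mutations <- data.frame(
    gene_id = c("I", "II", "III", "III", "IV", "IV", "V", "V"),
    position = c(116L, 298L, 41L, 194L, 74L, 511L, 53L, 272L),
    ref = c("T", "G", "A", "C", "C", "G", "T", "G"),
    alt = c("A", "T", "T", "T", "T", "A", "G", "A"),
    stringsAsFactors = FALSE)
  mutations$mutation_id <- sprintf("%s_%s%d%s", mutations$gene_id,
                                   mutations$ref, mutations$position,
                                   mutations$alt)
  mutations <- mutations[, c("mutation_id", "gene_id", "position", "ref",
                             "alt")]
  list(genes = genes, mutations = mutations)
}

# noise-free allele count table for one pool: uniform depth, desired
# mutations present in `successes` at fraction 1/k, plus optional extra
# non-reference events list(gene_id=, position=, alt=, fraction=)
build_counts <- function(genes, manifest_pool, successes, extras = list(),
                         depth = 1000L) {
  stopifnot(length(unique(manifest_pool$pool_id)) == 1)
  k_of <- table(manifest_pool$gene_id)
  rows <- lapply(names(genes), function(g) {
    L <- nchar(genes[[g]])
    refs <- strsplit(genes[[g]], "", fixed = TRUE)[[1]]
    m <- matrix(0L, nrow = L, ncol = 5,
                dimnames = list(NULL, c("A", "C", "G", "T", "other")))
    m[cbind(seq_len(L), match(refs, c("A", "C", "G", "T")))] <- depth
    df <- data.frame(pool_id = manifest_pool$pool_id[[1]], gene_id = g,
                     pos = seq_len(L), ref = refs, stringsAsFactors = FALSE)
    cbind(df, as.data.frame(m))
  })
  counts <- do.call(rbind, rows)
  bump <- function(counts, g, pos, alt, frac) {
    i <- which(counts$gene_id == g & counts$pos == pos)
    n_alt <- as.integer(round(depth * frac))
    counts[i, counts$ref[i]] <- depth - n_alt
    counts[i, alt] <- counts[i, alt] + n_alt
    counts
  }
  for (mid in successes) {
    r <- manifest_pool[manifest_pool$mutation_id == mid, ]
    counts <- bump(counts, r$gene_id, r$position, r$alt,
                   1 / as.integer(k_of[[r$gene_id]]))
  }
  for (e in extras)
    counts <- bump(counts, e$gene_id, e$position, e$alt, e$fraction)
  counts
}

make_manifest <- function(mutations, pool_id) {
  m <- mutations
  m$pool_id <- pool_id
  m$colony_id <- paste(m$mutation_id, pool_id, sep = ".")
  m[, c("colony_id", "mutation_id", "gene_id", "position", "ref", "alt",
        "pool_id")]
}

# linear chain of CA-only residues along x, spaced to avoid self-overlap
toy_chain <- function(chain, n_res, spacing = 7, y = 0, z = 0, start_res = 1) {
  structure_model(chain = chain, resseq = seq(start_res,
                                              start_res + n_res - 1),
                  x = spacing * (seq_len(n_res) - 1),
                  y = rep(y, n_res), z = rep(z, n_res))
}
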