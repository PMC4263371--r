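# independent brute-force designer: iterates over every (length, start)
# window rather than (length, offset); used as the oracle
brute_force_design <- function(gene, position, alt, relax = TRUE) {
  L <- nchar(gene)
  for (gc_bound in if (relax) c(40, 30) else 40) {
    cands <- list()
    for (N in 30:50) {
      for (s in max(1, position - N + 1):min(position, L - N + 1)) {
        rel <- position - s + 1
        centre <- if (N %% 2 == 0) N / 2 else (N + 1) / 2
        if (abs(rel - centre) > 1) next
        sq <- substring(gene, s, s + N - 1)
        substr(sq, rel, rel) <- alt
        gcp <- floor(100 * nchar(gsub("[AT]", "", sq)) / N + 0.5)
        mmp <- floor(100 / N + 0.5)
        tm <- 81.5 + 0.41 * gcp - 675 / N - mmp
        if (!grepl("^[GC].*[GC]$", sq)) next
        if (gcp < gc_bound || tm < 78) next
        cands[[length(cands) + 1]] <-
          data.frame(seq = sq, s = s, N = N, off = rel - centre, tm = tm,
                     gc = gcp, stringsAsFactors = FALSE)
      }
    }
    if (length(cands)) {
      d <- do.call(rbind, cands)
      d <- d[order(-d$tm, d$N, abs(d$off), d$s), ]
      return(list(best = d[1, ], relaxed = gc_bound == 30))
    }
  }
  NULL
}

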