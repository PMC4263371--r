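LOCUS_CLASSES <- c("interface_residue", "interface_domain", "away")

#' Fraction of mutations disrupting their interaction, by structural locus
#'
#' @param phenotypes data.frame with one row per mutation: `mutation`,
#'   `gene`, `locus_class` (see [classify_locus()]), `disrupts` (logical:
#'   does the mutation disrupt the structure-supported interaction under
#'   consideration), and `stable` (logical, `NA` allowed) when
#'   `stable_only` is used.
#' @param stable_only restrict to mutations with `stable == TRUE`.
#' @return data.frame per class: `locus_class`, `n_disrupting`, `n`,
#'   `fraction`, `se` (binomial standard error `sqrt(p (1 - p) / n)`).
#'   Empty classes are omitted with a warning.
#' @export
disruption_fraction_by_class <- function(phenotypes, stable_only = FALSE) {
  need <- c("locus_class", "disrupts")
  if (!all(need %in% names(phenotypes)))
    stop("phenotypes must have columns: ", paste(need, collapse = ", "))
  d <- phenotypes[!is.na(phenotypes$disrupts), ]
  if (stable_only) d <- d[!is.na(d$stable) & d$stable, ]
  out <- do.call(rbind, lapply(LOCUS_CLASSES, function(cl) {
    rows <- d[d$locus_class == cl, ]
    if (!nrow(rows)) {
      warning("no mutations in class '", cl, "'; omitted")
      return(NULL)
    }
    p <- mean(rows$disrupts)
    data.frame(locus_class = cl, n_disrupting = sum(rows$disrupts),
               n = nrow(rows), fraction = p,
               se = sqrt(p * (1 - p) / nrow(rows)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare two disruption fractions
#'
#' Two-sided Fisher's exact test on the 2x2 table of disrupting /
#' non-disrupting counts. The choice of test is a documented default: the
#' original cohort analyses do not name their test, so these P values are
#' an alternative, not a replica.
#'
#' @param x1,n1 disrupting count and total in class A.
#' @param x2,n2 disrupting count and total in class B.
#' @return P value.
#' @export
compare_fractions <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 <= n1, x2 <= n2)
  fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2,
                     byrow = TRUE))$p.value
}

parse_diseases <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(d) unique(tolower(trimws(d[nzchar(trimws(d))]))))
}

# profiles are encoded "partner1:0;partner2:1" (1 = disrupted)
parse_profile <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  setNames(vapply(parts, function(p) p[[2]] == "1", logical(1)),
           vapply(parts, `[[`, character(1), 1))
}

#' Encode a disruption profile as a string
#'
#' @param profile named logical vector over partners (see
#'   [build_profiles()]).
#' @return canonical `"partner:0/1;..."` string encoding (partners sorted).
#' @export
profile_string <- function(profile) {
  profile <- profile[order(names(profile))]
  paste(sprintf("%s:%d", names(profile), as.integer(profile)),
        collapse = ";")
}

#' Same-disease concordance of same-gene mutation pairs
#'
#' Enumerates every unordered pair of mutations on the same gene for which
#' both members carry disease annotations, buckets the pairs by molecular
#' phenotype concordance, and reports the fraction of pairs whose members
#' cause the same disease (non-empty intersection of case-folded disease
#' label sets).
#'
#' Modes:
#' * `stability`: buckets `both_stable`, `both_unstable`, `discordant`
#'   (pairs with an `NA` stability call are dropped);
#' * `profile`: buckets `same_profile` / `different_profile`, compared
#'   over the pair's shared tested-partner set (pairs without shared
#'   partners are incomparable and dropped).
#'
#' The P value is a two-sided Fisher's exact test comparing same-disease
#' counts between concordant and discordant pairs. Pairs sharing a
#' mutation are not independent; the test is reported with that caveat.
#'
#' @param phenotypes data.frame with columns `gene`, `mutation`, `diseases`
#'   (";"-separated labels), plus `stable` (mode `stability`) or `profile`
#'   (mode `profile`, encoded as by [profile_string()]).
#' @param mode `"stability"` or `"profile"`.
#' @return list with `buckets` (data.frame: bucket, n_pairs,
#'   n_same_disease, fraction, se), `concordant_fraction`,
#'   `discordant_fraction` and `p_value`.
#' @export
pair_concordance <- function(phenotypes, mode = c("stability", "profile")) {
  mode <- match.arg(mode)
  diseases <- parse_diseases(phenotypes$diseases)
  pairs <- list()
  for (g in unique(phenotypes$gene)) {
    idx <- which(phenotypes$gene == g & lengths(diseases) > 0)
    if (length(idx) < 2) next
    cmb <- utils::combn(idx, 2)
    for (c_i in seq_len(ncol(cmb))) {
      i <- cmb[1, c_i]
      j <- cmb[2, c_i]
      same_dis <- length(intersect(diseases[[i]], diseases[[j]])) > 0
      if (mode == "stability") {
        si <- phenotypes$stable[i]
        sj <- phenotypes$stable[j]
        if (is.na(si) || is.na(sj)) next
        bucket <- if (si && sj) "both_stable"
          else if (!si && !sj) "both_unstable" else "discordant"
        concordant <- si == sj
      } else {
        pi_ <- parse_profile(phenotypes$profile[i])
        pj <- parse_profile(phenotypes$profile[j])
        shared <- intersect(names(pi_), names(pj))
        if (!length(shared)) next
        concordant <- all(pi_[shared] == pj[shared])
        bucket <- if (concordant) "same_profile" else "different_profile"
      }
      pairs[[length(pairs) + 1L]] <-
        data.frame(bucket = bucket, concordant = concordant,
                   same_disease = same_dis, stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs))
    return(list(buckets = data.frame(bucket = character(),
                                     n_pairs = integer(),
                                     n_same_disease = integer(),
                                     fraction = numeric(), se = numeric(),
                                     stringsAsFactors = FALSE),
                concordant_fraction = NA_real_,
                discordant_fraction = NA_real_, p_value = NA_real_))
  pr <- do.call(rbind, pairs)
  buckets <- do.call(rbind, lapply(unique(pr$bucket), function(b) {
    rows <- pr[pr$bucket == b, ]
    p <- mean(rows$same_disease)
    data.frame(bucket = b, n_pairs = nrow(rows),
               n_same_disease = sum(rows$same_disease), fraction = p,
               se = sqrt(p * (1 - p) / nrow(rows)), stringsAsFactors = FALSE)
  }))
  conc <- pr[pr$concordant, ]
  disc <- pr[!pr$concordant, ]
  p_value <- if (nrow(conc) && nrow(disc))
    compare_fractions(sum(conc$same_disease), nrow(conc),
                      sum(disc$same_disease), nrow(disc)) else NA_real_
  list(buckets = buckets,
       concordant_fraction = if (nrow(conc)) mean(conc$same_disease)
         else NA_real_,
       discordant_fraction = if (nrow(disc)) mean(disc$same_disease)
         else NA_real_,
       p_value = p_value)
}

#' Simulate a mutation cohort with a planted phenotype-disease association
#'
#' Each gene carries two candidate diseases; each mutation draws a latent
#' molecular type (stable/disruption-profile 1 vs unstable/profile 2) and
#' is annotated with the type-matched disease with probability
#' `disease_fidelity`, otherwise the other one. Concordant same-gene pairs
#' are then same-disease with probability
#' `fidelity^2 + (1 - fidelity)^2` and discordant pairs with probability
#' `2 fidelity (1 - fidelity)`, which [pair_concordance()] should recover.
#'
#' @param n_genes number of genes.
#' @param muts_per_gene mutations per gene.
#' @param p_type1 probability of the stable (type-1) latent phenotype.
#' @param disease_fidelity probability that the annotated disease matches
#'   the latent type.
#' @param n_partners tested interaction partners per gene.
#' @param seed optional seed.
#' @return phenotype data.frame suitable for [pair_concordance()]: `gene`,
#'   `mutation`, `stable`, `profile`, `diseases`.
#' @export
sim_cohort <- function(n_genes = 25, muts_per_gene = 4, p_type1 = 0.5,
                       disease_fidelity = 0.9, n_partners = 3,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in seq_len(n_genes)) {
    gene <- sprintf("g%03d", g)
    partners <- sprintf("%s_p%d", gene, seq_len(n_partners))
    prof1 <- setNames(runif(n_partners) < 0.3, partners)
    prof2 <- !prof1
    for (m in seq_len(muts_per_gene)) {
      type1 <- runif(1) < p_type1
      match_dis <- runif(1) < disease_fidelity
      disease <- if (type1 == match_dis) paste0(gene, "_D1")
        else paste0(gene, "_D2")
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, mutation = sprintf("%s_m%d", gene, m),
        stable = type1,
        profile = profile_string(if (type1) prof1 else prof2),
        diseases = disease, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
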