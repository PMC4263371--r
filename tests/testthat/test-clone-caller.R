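test_that("S score matches the pooled half-read arithmetic", {
  w <- fig2a_world()
  man <- make_manifest(w$mutations, "pool1")
  counts <- build_counts(w$genes, man,
                         successes = setdiff(man$mutation_id, "IV_C74T"))
  sc <- score_mutations(counts, man)
  s_of <- setNames(sc$S, sc$mutation_id)
  # k = 2 gene, half the reads carry the mutation -> S = 1.0
  expect_equal(unname(s_of["III_A41T"]), 1.0)
  expect_equal(unname(s_of["III_C194T"]), 1.0)
  # failed attempt: all reads wild type -> S = 0
  expect_equal(unname(s_of["IV_C74T"]), 0)
  expect_false(sc$called[sc$mutation_id == "IV_C74T"])
  # k = 1 pure mutant clone -> S = 1
  expect_equal(unname(s_of["I_T116A"]), 1.0)
  expect_true(all(sc$k == c(1, 1, 2, 2, 2, 2, 2, 2)))
})

test_that("removing a co-pooled mutation rescales S exactly (k oracle)", {
  w <- fig2a_world()
  man <- make_manifest(w$mutations, "pool1")
  counts <- build_counts(w$genes, man, successes = man$mutation_id)
  s2 <- score_mutations(counts, man)
  man1 <- man[man$mutation_id != "III_C194T", ]
  s1 <- score_mutations(counts, man1)
  # same counts, k drops 2 -> 1 for gene III: S halves
  expect_equal(s1$S[s1$mutation_id == "III_A41T"],
               s2$S[s2$mutation_id == "III_A41T"] / 2)
})

test_that("zero-coverage target sites yield S = NA, called = FALSE, with warning", {
  w <- fig2a_world()
  man <- make_manifest(w$mutations, "pool1")
  counts <- build_counts(w$genes, man, successes = man$mutation_id)
  counts <- counts[!(counts$gene_id == "I" & counts$pos == 116), ]
  expect_warning(sc <- score_mutations(counts, man), "zero coverage")
  expect_true(is.na(sc$S[sc$mutation_id == "I_T116A"]))
  expect_false(sc$called[sc$mutation_id == "I_T116A"])
})

test_that("background estimation recovers a planted error rate and applies the floor", {
  set.seed(51)
  w <- fig2a_world()
  man <- make_manifest(w$mutations, "pool1")
  # noise-free counts -> b_hat at the 1e-6 floor
  counts0 <- build_counts(w$genes, man, successes = man$mutation_id)
  bg0 <- estimate_background(counts0, man)
  expect_equal(bg0$b_hat, 1e-6)
  # plant ~1e-3 noise at every non-target site
  counts <- counts0
  depth <- counts$A + counts$C + counts$G + counts$T + counts$other
  is_target <- paste(counts$gene_id, counts$pos) %in%
    paste(man$gene_id, man$position)
  idx <- which(!is_target)
  err <- rbinom(length(idx), depth[idx], 1e-3)
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (err[j] == 0) next
    alt <- setdiff(c("A", "C", "G", "T"), counts$ref[i])[1]
    counts[i, counts$ref[i]] <- counts[i, counts$ref[i]] - err[j]
    counts[i, alt] <- counts[i, alt] + err[j]
  }
  bg <- estimate_background(counts, man)
  n <- bg$n_positions
  se <- sqrt(1e-3 / (1000 * n))  # SE of the mean of n Binomial(1000,1e-3)/1000
  expect_lt(abs(bg$b_hat - 1e-3), 3 * se)
  # insufficient covered positions -> error
  expect_error(estimate_background(counts[1:50, ], man),
               "non-target positions")
})

test_that("binomial flagging matches exact tail arithmetic", {
  w <- fig2a_world()
  man <- make_manifest(w$mutations, "pool1")
  counts <- build_counts(w$genes, man, successes = man$mutation_id,
                         extras = list(
                           # C436G at half the reads of the k=2 gene V
                           list(gene_id = "V", position = 436, alt = "G",
                                fraction = 0.5),
                           # 3 of 1000 non-reference: not significant at b=1e-3
                           list(gene_id = "I", position = 300, alt = "C",
                                fraction = 0.003)),
                         depth = 1000L)
  bg <- data.frame(pool_id = "pool1", b_hat = 1e-3, n_positions = 3000)
  flags <- detect_unwanted(counts, man, bg, alpha = 0.2)
  # the planted colony-level event is flagged and ambiguous (k = 2)
  v_flag <- flags[flags$gene_id == "V" & flags$pos == 436, ]
  expect_equal(nrow(v_flag), 1)
  expect_equal(v_flag$attributed_colony, "ambiguous")
  # upper-tail P(X >= 500 | 1000, 1e-3) is effectively 0
  expect_lt(v_flag$p_value, 1e-100)
  # the 3/1000 site: exact upper tail ~= 0.08 at depth 1000... compute both ways
  p_exact <- 1 - pbinom(2, 1000, 1e-3)
  i_flag <- flags[flags$gene_id == "I" & flags$pos == 300, ]
  if (p_exact < 0.2) {
    expect_equal(i_flag$p_value, p_exact)
  } else {
    expect_equal(nrow(i_flag), 0)
  }
  # spec arithmetic at depth 2500: P(X >= 3 | 2500, 1e-3) ~= 0.46 > 0.2
  expect_gt(1 - pbinom(2, 2500, 1e-3), 0.2)
})

test_that("with floored noise-free background any non-reference read is flagged", {
  w <- fig2a_world()
  man <- make_manifest(w$mutations, "pool1")
  counts <- build_counts(w$genes, man, successes = man$mutation_id,
                         extras = list(list(gene_id = "II", position = 100,
                                            alt = "A", fraction = 0.001)))
  bg <- estimate_background(counts, man)
  flags <- detect_unwanted(counts, man, bg, alpha = 0.2)
  expect_true(any(flags$gene_id == "II" & flags$pos == 100))
})

test_that("detect_unwanted has >= 99% recall on colony-level events at depth >= 300", {
  set.seed(52)
  w <- fig2a_world()
  man <- make_manifest(w$mutations, "pool1")
  depths <- sample(c(300L, 600L, 1200L, 2500L), 150, replace = TRUE)
  fracs <- sample(c(0.25, 0.5, 1), 150, replace = TRUE)
  genes_hit <- sample(names(w$genes), 150, replace = TRUE)
  planted <- 0
  found <- 0
  counts <- build_counts(w$genes, man, successes = man$mutation_id)
  pos_used <- paste(man$gene_id, man$position)
  for (i in 1:150) {
    L <- nchar(w$genes[[genes_hit[i]]])
    repeat {
      p <- sample(L, 1)
      if (!paste(genes_hit[i], p) %in% pos_used) break
    }
    pos_used <- c(pos_used, paste(genes_hit[i], p))
    row <- which(counts$gene_id == genes_hit[i] & counts$pos == p)
    alt <- setdiff(c("A", "C", "G", "T"), counts$ref[row])[1]
    n_alt <- rbinom(1, depths[i], fracs[i])
    counts[row, c("A", "C", "G", "T", "other")] <- 0L
    counts[row, counts$ref[row]] <- depths[i] - n_alt
    counts[row, alt] <- n_alt
    planted <- planted + 1
  }
  bg <- data.frame(pool_id = "pool1", b_hat = 2e-3, n_positions = 3000)
  flags <- detect_unwanted(counts, man, bg, alpha = 0.2)
  key_f <- paste(flags$gene_id, flags$pos)
  found <- sum(tail(pos_used, 150) %in% key_f)
  expect_gte(found / planted, 0.99)
})

test_that("the five-gene worked example resolves to the printed verdicts", {
  w <- fig2a_world()
  man1 <- make_manifest(w$mutations, "pool1")
  mann <- make_manifest(w$mutations, "pooln")
  manifest <- rbind(man1, mann)
  # pool 1: IV_C74T fails; gene V carries the extra C436G on half the reads
  counts1 <- build_counts(w$genes, man1,
                          successes = setdiff(man1$mutation_id, "IV_C74T"),
                          extras = list(list(gene_id = "V", position = 436,
                                             alt = "G", fraction = 0.5)))
  # pool n: the seven listed clones succeed (II fails here), nothing unwanted
  countsn <- build_counts(w$genes, mann,
                          successes = setdiff(mann$mutation_id, "II_G298T"))
  countsn$pool_id <- "pooln"
  counts <- rbind(counts1, countsn)
  scores <- score_mutations(counts, manifest)
  bg <- estimate_background(counts, manifest)
  flags <- detect_unwanted(counts, manifest, bg, alpha = 0.2)
  verdicts <- resolve_clones(scores, flags, manifest)
  pt <- attr(verdicts, "pool_table")
  usable1 <- sort(pt$mutation_id[pt$pool_id == "pool1" & pt$usable])
  expect_equal(usable1, sort(c("I_T116A", "II_G298T", "III_A41T",
                               "III_C194T", "IV_G511A")))
  # IV_C74T failed; both V clones disqualified by the ambiguous flag
  expect_false(pt$usable[pt$pool_id == "pool1" &
                           pt$mutation_id == "IV_C74T"])
  expect_true(all(pt$disqualified[pt$pool_id == "pool1" &
                                    pt$gene_id == "V"]))
  usablen <- sort(pt$mutation_id[pt$pool_id == "pooln" & pt$usable])
  expect_equal(usablen, sort(c("I_T116A", "III_A41T", "III_C194T",
                               "IV_C74T", "IV_G511A", "V_T53G",
                               "V_G272A")))
  # cross-pool resolution: everything usable somewhere, first pool preferred
  expect_true(all(verdicts$status == "usable"))
  chosen <- setNames(verdicts$chosen_pool, verdicts$mutation_id)
  expect_equal(unname(chosen[c("I_T116A", "II_G298T", "III_A41T")]),
               rep("pool1", 3))
  expect_equal(unname(chosen[c("IV_C74T", "V_T53G", "V_G272A")]),
               rep("pooln", 3))
})

test_that("mutations called nowhere resolve to failed_mutagenesis", {
  w <- fig2a_world()
  man <- make_manifest(w$mutations, "pool1")
  counts <- build_counts(w$genes, man,
                         successes = setdiff(man$mutation_id, "I_T116A"))
  scores <- score_mutations(counts, man)
  verdicts <- resolve_clones(scores,
                             detect_unwanted(counts, man,
                                             estimate_background(counts, man)),
                             man)
  expect_equal(verdicts$status[verdicts$mutation_id == "I_T116A"],
               "failed_mutagenesis")
  expect_true(is.na(verdicts$chosen_pool[verdicts$mutation_id == "I_T116A"]))
})
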