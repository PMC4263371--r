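# build a ratio record table; ratios are light/heavy
rr <- function(experiment, protein, ratios, bait = FALSE) {
  data.frame(experiment = experiment, protein_id = protein,
             peptide_id = paste0(protein, "_", experiment,
                                 seq_along(ratios)),
             xpress_ratio = ratios, is_bait = bait, stringsAsFactors = FALSE)
}

null_experiment <- function(prot = "p1", n = 6) {
  rbind(rr("WT_Control", prot, rep(1, n)),
        rr("Mutant_Control", prot, rep(1, n)),
        rr("WT_Mutant", "bait", rep(1, 4), bait = TRUE),
        rr("WT_Mutant", prot, rep(1, n)),
        rr("Mutant_WT", "bait", rep(1, 4), bait = TRUE),
        rr("Mutant_WT", prot, rep(1, n)))
}

test_that("the all-ratios-1 null experiment scores to unity and E = 0", {
  sc <- silac_aggregate(null_experiment())
  expect_equal(sc$WT_p, 1)
  expect_equal(sc$Mut_p, 1)
  expect_equal(sc$FC_wm, 1)
  expect_equal(sc$FC_mw, 1)
  expect_equal(sc$E, 0)
  expect_equal(sc$r_wc, 6)
  expect_equal(sc$t_wm, 4)
})

test_that("E is the read-weighted mean of log2 fold changes", {
  # FC_wm = FC_mw = 0.25 with equal counts -> E = -2
  rec <- rbind(rr("WT_Control", "p1", rep(0.4, 8)),
               rr("WT_Mutant", "bait", rep(1, 5), bait = TRUE),
               rr("WT_Mutant", "p1", rep(0.25, 6)),
               rr("Mutant_WT", "bait", rep(1, 5), bait = TRUE),
               rr("Mutant_WT", "p1", rep(4, 6)))
  sc <- silac_aggregate(rec)
  expect_equal(sc$FC_wm, 0.25)
  expect_equal(sc$FC_mw, 0.25)
  expect_equal(sc$E, -2)
  # unequal counts: weighted combination
  rec2 <- rbind(rr("WT_Mutant", "bait", rep(1, 5), bait = TRUE),
                rr("WT_Mutant", "p1", rep(0.25, 9)),   # log2 FC = -2
                rr("Mutant_WT", "bait", rep(1, 5), bait = TRUE),
                rr("Mutant_WT", "p1", rep(2, 3)))      # log2 FC = -1
  sc2 <- silac_aggregate(rec2)
  expect_equal(sc2$E, (9 * -2 + 3 * -1) / 12)
})

test_that("geometric means equal the brute-force product form and are order-invariant", {
  set.seed(91)
  x <- runif(11, 0.2, 5)
  rec <- rbind(rr("WT_Control", "p1", x),
               rr("WT_Mutant", "bait", rep(1, 4), bait = TRUE),
               rr("Mutant_WT", "bait", rep(1, 4), bait = TRUE))
  sc <- silac_aggregate(rec)
  expect_equal(sc$WT_p, 1 / prod(x)^(1 / length(x)))
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(silac_aggregate(shuf)$WT_p, sc$WT_p)
})

test_that("bait normalization cancels global mixing-ratio errors", {
  set.seed(92)
  rec <- rbind(rr("WT_Mutant", "bait", runif(5, 0.8, 1.2), bait = TRUE),
               rr("WT_Mutant", "p1", runif(7, 0.1, 0.6)),
               rr("Mutant_WT", "bait", runif(5, 0.8, 1.2), bait = TRUE),
               rr("Mutant_WT", "p1", runif(7, 2, 6)))
  sc <- silac_aggregate(rec)
  rec2 <- rec
  scale_rows <- rec2$experiment == "WT_Mutant"
  rec2$xpress_ratio[scale_rows] <- rec2$xpress_ratio[scale_rows] * 3.7
  sc2 <- silac_aggregate(rec2)
  expect_equal(sc2$FC_wm, sc$FC_wm)
  expect_equal(sc2$FC_mw, sc$FC_mw)
})

test_that("classification thresholds reproduce the lost/gained/unchanged rules", {
  mk <- function(WT_p = NA, r_wc = 0, Mut_p = NA, r_mc = 0, FC_wm = NA,
                 r_wm = 0, FC_mw = NA, r_mw = 0)
    data.frame(protein_id = "x", WT_p = WT_p, Mut_p = Mut_p, FC_wm = FC_wm,
               FC_mw = FC_mw, E = NA_real_, r_wc = r_wc, r_mc = r_mc,
               r_wm = r_wm, r_mw = r_mw, t_wm = 5, t_mw = 5,
               stringsAsFactors = FALSE)
  # Pms2-like weakened interactor of the wild type
  expect_equal(silac_classify(mk(WT_p = 4, r_wc = 10, FC_wm = 0.3, r_wm = 8,
                                 FC_mw = 0.3, r_mw = 8))$classification,
               "lost")
  # Hspa8-like enhanced interactor of the mutant
  expect_equal(silac_classify(mk(Mut_p = 5, r_mc = 12, FC_wm = 4, r_wm = 8,
                                 FC_mw = 4, r_mw = 8))$classification,
               "gained")
  # unchanged requires interactor of both and both FCs in (0.5, 2)
  expect_equal(silac_classify(mk(WT_p = 3, r_wc = 9, Mut_p = 3, r_mc = 9,
                                 FC_wm = 1.2, r_wm = 7, FC_mw = 0.9,
                                 r_mw = 7))$classification,
               "unchanged")
  # cross-experiment confirmation fails -> unclassified
  expect_equal(silac_classify(mk(WT_p = 4, r_wc = 10, FC_wm = 0.4, r_wm = 8,
                                 FC_mw = 0.8, r_mw = 8))$classification,
               "unclassified")
  # read-count gates
  expect_equal(silac_classify(mk(WT_p = 4, r_wc = 4, FC_wm = 0.3, r_wm = 8,
                                 FC_mw = 0.3, r_mw = 8))$classification,
               "unclassified")
})

test_that("swapping wild-type and mutant labels negates E and swaps lost/gained", {
  set.seed(93)
  rec <- rbind(rr("WT_Control", "p1", rep(0.25, 8)),
               rr("Mutant_Control", "p1", rep(0.9, 8)),
               rr("WT_Mutant", "bait", rep(1, 5), bait = TRUE),
               rr("WT_Mutant", "p1", runif(7, 0.2, 0.4)),
               rr("Mutant_WT", "bait", rep(1, 5), bait = TRUE),
               rr("Mutant_WT", "p1", runif(7, 2.5, 5)))
  sc <- silac_classify(silac_aggregate(rec))
  expect_equal(sc$classification, "lost")
  expect_lt(sc$E, 0)  # weakened interactors have negative E
  swapped <- rec
  map <- c(WT_Control = "Mutant_Control", Mutant_Control = "WT_Control",
           WT_Mutant = "Mutant_WT", Mutant_WT = "WT_Mutant")
  swapped$experiment <- unname(map[swapped$experiment])
  sc2 <- silac_classify(silac_aggregate(swapped))
  expect_equal(sc2$E, -sc$E)
  expect_equal(sc2$classification, "gained")
  expect_gt(sc2$E, 0)  # enhanced interactors have positive E
})

test_that("KS bootstrap is calibrated under the null and powered against a shift", {
  set.seed(94)
  background <- rnorm(200)
  pvals <- vapply(1:100, function(i)
    ks_bootstrap_p(sample(background, 8, replace = TRUE), background,
                   n_boot = 400), numeric(1))
  # null p values approximately uniform on (0, 1]
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.05)
  # 3-log2-unit shift, n = 10: decisive rejection
  shifted <- sample(background, 10, replace = TRUE) + 3
  expect_lt(ks_bootstrap_p(shifted, background, n_boot = 10000, seed = 7),
            0.01)
  expect_error(ks_bootstrap_p(shifted, background, n_boot = 0), "n_boot")
  expect_warning(p <- ks_bootstrap_p(c(1, 2), background, n_boot = 10),
                 "fewer than 3")
  expect_true(is.na(p))
})

test_that("per-protein p values use the unchanged-protein background", {
  set.seed(95)
  recs <- list(rr("WT_Mutant", "bait", rep(1, 5), bait = TRUE),
               rr("Mutant_WT", "bait", rep(1, 5), bait = TRUE))
  # 6 unchanged proteins forming the background, one strongly shifted
  for (p in paste0("u", 1:6)) {
    recs[[length(recs) + 1]] <- rr("WT_Control", p, rep(0.4, 6))
    recs[[length(recs) + 1]] <- rr("Mutant_Control", p, rep(0.4, 6))
    recs[[length(recs) + 1]] <- rr("WT_Mutant", p, exp(rnorm(6, 0, 0.2)))
    recs[[length(recs) + 1]] <- rr("Mutant_WT", p, exp(rnorm(6, 0, 0.2)))
  }
  recs[[length(recs) + 1]] <- rr("WT_Control", "lostP", rep(0.3, 8))
  recs[[length(recs) + 1]] <- rr("WT_Mutant", "lostP", rep(0.1, 6))
  recs[[length(recs) + 1]] <- rr("Mutant_WT", "lostP", rep(10, 6))
  rec <- do.call(rbind, recs)
  sc <- silac_ks_pvalues(rec, silac_classify(silac_aggregate(rec)),
                         n_boot = 500, seed = 11)
  expect_true(all(sc$classification[grepl("^u", sc$protein_id)] ==
                    "unchanged"))
  expect_lt(sc$p_value[sc$protein_id == "lostP"], 0.02)
  expect_true(all(sc$p_value[grepl("^u", sc$protein_id)] > 0.001))
})
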