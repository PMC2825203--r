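classify_protein <- function(p, criteria = lea_criteria()) {
  prof <- suppressWarnings(physchem_profile(p))
  uv <- uversky_classify(prof$mean_scaled_hydropathy, prof$mean_net_charge)
  classify_lea(prof, uv, foldindex_profile(p), k11_summary(p), criteria)
}

test_that("the rule cascade assigns the expected labels", {
  lea <- paste0("M", make_lea_like_protein(90, n_k11_runs = 2, seed = 7))
  expect_identical(classify_protein(lea)$label, "group3_lea")

  # cysteine/tryptophan demote an otherwise perfect candidate
  cw <- paste0("M", make_lea_like_protein(90, n_k11_runs = 2,
                                          include_cys_trp = TRUE, seed = 7))
  expect_identical(classify_protein(cw)$label, "lea_like")
  # ... unless the C/W rule is disabled
  relaxed <- lea_criteria(forbid_cys_trp = FALSE)
  expect_identical(classify_protein(cw, relaxed)$label, "group3_lea")

  # hydrophilic + unfolded but no K11 runs
  nok11 <- paste0("M", make_lea_like_protein(90, n_k11_runs = 0, seed = 7))
  expect_identical(classify_protein(nok11)$label, "lea_like")

  glob <- paste0("M", make_globular_protein(90, seed = 7))
  expect_identical(classify_protein(glob)$label, "not_lea_like")
})

test_that("exactly one cascade label applies and evidence is recorded", {
  set.seed(77)
  labels <- c("group3_lea", "lea_like", "hydrophilic_novel", "not_lea_like")
  for (i in 1:20) {
    p <- random_protein(60)
    cls <- classify_protein(p)
    expect_true(cls$label %in% labels)
    ev <- cls$evidence
    expect_true("compositional_clustering" %in% ev$criterion)
    expect_identical(ev$note[ev$criterion == "compositional_clustering"],
                     "not evaluated")
    # cascade consistency: group3 implies the lea_like conditions
    hydro <- ev$satisfied[ev$criterion == "gravy_below_threshold"]
    unf <- ev$satisfied[ev$criterion == "uversky_unfolded"]
    if (cls$label == "group3_lea") expect_true(hydro && unf)
    if (cls$label == "not_lea_like") expect_false(hydro)
  }
})

test_that("the hydrophilic-novel flag uses strict inequalities", {
  crit <- lea_criteria()
  expect_false(flag_hydrophilic_novel(-0.43, 50, crit))
  expect_true(flag_hydrophilic_novel(-0.431, 50, crit))
  expect_true(flag_hydrophilic_novel(-0.43, 50.1, crit))
  expect_false(flag_hydrophilic_novel(0.99, 0, crit))
})

test_that("the printed novel-EST parameters flag exactly six records", {
  t2 <- novel_est_profiles()
  expect_identical(nrow(t2), 12L)
  flags <- flag_hydrophilic_novel(t2$gravy, t2$percent_disorder)
  expect_identical(sum(flags), 6L)
})

test_that("classification recovers generator ground truth exactly", {
  set.seed(101)
  for (i in 1:100) {
    if (i %% 2 == 0) {
      p <- paste0("M", make_lea_like_protein(sample(60:110, 1),
                                             n_k11_runs = sample(1:3, 1)))
      expect_identical(classify_protein(p)$label, "group3_lea")
    } else {
      p <- paste0("M", make_globular_protein(sample(60:110, 1)))
      expect_identical(classify_protein(p)$label, "not_lea_like")
    }
  }
})

test_that("characterise reports per-record rows and never aborts", {
  set.seed(3)
  lea <- make_est(paste0("M", make_lea_like_protein(80)), sl_name = "SL1c")
  glob <- make_est(paste0("M", make_globular_protein(90)), sl_name = "SL1a")
  seqs <- c(lea1 = lea$sequence, glob1 = glob$sequence,
            dud = strrep("C", 120))
  rep_ <- characterise(seqs)
  expect_identical(nrow(rep_), 3L)
  expect_identical(rep_$id, c("lea1", "glob1", "dud"))
  expect_identical(rep_$label[1], "group3_lea")
  expect_identical(rep_$label[2], "not_lea_like")
  expect_identical(rep_$status[3], "no ORF")
  expect_identical(rep_$sl_name[1:2], c("SL1c", "SL1a"))

  # empty input: header-only table
  empty <- characterise(character(0))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("id", "status", "label") %in% names(empty)))

  # determinism
  expect_identical(characterise(seqs), rep_)
})
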