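psm_df <- function(peptide, score, is_decoy = FALSE,
                   matched_entry = NA_character_) {
  data.frame(spectrum_id = sprintf("sp%03d", seq_along(peptide)),
             sample_id = "S01", dataset_id = "DS1", peptide = peptide,
             score = score, is_decoy = is_decoy,
             matched_entry = matched_entry, stringsAsFactors = FALSE)
}

test_that("q-values match the worked target/decoy example", {
  t <- psm_df(c("A", "B", "C", "D"), c(10, 9, 8, 7))
  d <- psm_df(c("X", "Y"), c(8.5, 6), is_decoy = TRUE)
  v <- class_specific_fdr(t, d, alpha = 0.01)
  q <- setNames(v$q_value, v$peptide)
  expect_equal(unname(q[c("A", "B", "C", "D")]), c(0, 0, 0.25, 0.25))
})

test_that("decoys above all targets give q-values of one", {
  t <- psm_df(c("A", "B"), c(1, 2))
  d <- psm_df(c("X", "Y"), c(3, 4), is_decoy = TRUE)
  v <- class_specific_fdr(t, d)
  expect_true(all(v$q_value == 1))
})

test_that("absent decoys yield zero q-values with a warning", {
  t <- psm_df(c("A", "B"), c(1, 2))
  d <- t[0, ]
  expect_warning(v <- class_specific_fdr(t, d), "no decoys")
  expect_true(all(v$q_value == 0))
  expect_equal(nrow(class_specific_fdr(t[0, ], d)), 0L)
})

test_that("peptide classification handles tryptic, I/L and variant cases", {
  idx <- known_peptide_index(c(P1 = "MAKRPEITIDEKGGR"),
                             variant_proteins = "MAKRPEITIDEKGGW")
  expect_equal(unname(classify_peptides("MAK", idx)), "known")
  # L in the query matches I in the known protein
  expect_equal(unname(classify_peptides("PELTIDEK", idx)), "known")
  expect_equal(unname(classify_peptides("TLDEKGGW", idx)), "variant")
  expect_equal(unname(classify_peptides("WWWWFFFF", idx)), "novel")
  expect_error(classify_peptides("", idx), "empty")
})

test_that("prefilter discards known targets, variant targets and
          known-tryptic decoys", {
  idx <- known_peptide_index(c(P1 = "MAKRPEITIDEKGGR"),
                             variant_proteins = "MAKRPEITIDEKGGW")
  psms <- rbind(psm_df("WWWWFFFK", 5),              # novel target
                psm_df("PELTIDEK", 6),              # known target
                psm_df("TLDEKGGW", 4),              # variant target
                psm_df("RPELTLDEK", 1, TRUE),       # known tryptic decoy
                psm_df("QQWWFFYK", 0.5, TRUE))      # novel-space decoy
  parts <- prefilter_for_fdr(psms, idx)
  expect_equal(parts$novel_targets$peptide, "WWWWFFFK")
  expect_equal(parts$novel_decoys$peptide, "QQWWFFYK")
  expect_equal(nrow(parts$discarded), 3L)

  clean <- rbind(psm_df("WWWWFFFK", 5), psm_df("QQWWFFYK", 0.5, TRUE))
  parts2 <- prefilter_for_fdr(clean, idx)
  expect_equal(nrow(parts2$novel_targets) + nrow(parts2$novel_decoys),
               nrow(clean))
  expect_equal(nrow(parts2$discarded), 0L)
})

test_that("decoys are partitioned by origin class when the database is
          supplied", {
  w <- get_small_world(); db <- get_small_db()
  idx <- get_small_index()
  psms <- simulate_psms(w, db, small_config(), seed = 2)
  parts <- prefilter_for_fdr(psms, idx, db)
  origin <- db$entries$origin_class[match(parts$novel_decoys$matched_entry,
                                          db$entries$entry_id)]
  expect_true(all(origin == "noncoding"))
})

test_that("q-values agree with the exhaustive threshold oracle", {
  withr::with_seed(17, {
    for (i in 1:50) {
      nt <- sample(2:50, 1L); nd <- sample(1:50, 1L)
      ts <- round(rnorm(nt), 2)  # rounding forces ties
      ds <- round(rnorm(nd), 2)
      t <- psm_df(sprintf("T%03d", seq_len(nt)), ts)
      d <- psm_df(sprintf("D%03d", seq_len(nd)), ds, is_decoy = TRUE)
      v <- class_specific_fdr(t, d)
      expect_equal(setNames(v$q_value, v$peptide)[t$peptide],
                   setNames(oracle_qvalues(ts, ds), t$peptide))
    }
  })
})

test_that("q-values are monotone and acceptance grows with alpha", {
  withr::with_seed(19, {
    for (i in 1:20) {
      t <- psm_df(sprintf("T%03d", 1:40), rnorm(40))
      d <- psm_df(sprintf("D%03d", 1:40), rnorm(40), is_decoy = TRUE)
      v <- class_specific_fdr(t, d)
      v <- v[order(v$best_score, decreasing = TRUE), ]
      expect_true(all(diff(v$q_value) >= 0))
      a1 <- v$peptide[v$q_value <= 0.01]
      a2 <- v$peptide[v$q_value <= 0.05]
      a3 <- v$peptide[v$q_value <= 0.20]
      expect_true(all(a1 %in% a2) && all(a2 %in% a3))
    }
  })
})

test_that("PSM-level mode scores every PSM independently", {
  t <- psm_df(c("A", "A", "B"), c(10, 2, 5))
  d <- psm_df(c("X", "Y"), c(3, 1), is_decoy = TRUE)
  v_pep <- class_specific_fdr(t, d, level = "peptide")
  v_psm <- class_specific_fdr(t, d, level = "psm")
  expect_equal(nrow(v_pep), 2L)
  expect_equal(nrow(v_psm), 3L)
})
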