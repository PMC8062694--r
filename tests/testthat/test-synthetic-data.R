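test_that("world generation is byte-identical under a fixed seed", {
  w1 <- generate_world(small_config())
  w2 <- generate_world(small_config())
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
})

test_that("element counts pass through and pseudogenes track parents", {
  w <- generate_world(sim_config(seed = 1, n_coding_genes = 6,
                                 n_pseudogenes = 5, n_lncrnas = 2,
                                 n_repeat_copies = 3))
  psg <- Filter(function(tx) tx$biotype == "pseudogene", w$transcripts)
  expect_length(psg, 5L)
  expect_true(all(vapply(psg, `[[`, character(1), "parent_gene") %in%
                    names(w$known_proteome)))
})

test_that("zero divergence copies the parental CDS exactly", {
  w <- generate_world(sim_config(seed = 2, n_coding_genes = 4,
                                 n_pseudogenes = 3, n_lncrnas = 1,
                                 n_repeat_copies = 2,
                                 pseudogene_divergence = 0))
  for (tx in Filter(function(t) t$biotype == "pseudogene", w$transcripts)) {
    parent_prot <- w$known_proteome[[tx$parent_gene]]
    expect_equal(sub("\\*$", "", translate_frame(tx$spliced, 0L)),
                 parent_prot)
  }
})

test_that("transcript coordinates are consistent with the genome", {
  w <- get_small_world()
  chrom_len <- nchar(w$genome[["chr1"]])
  for (tx in w$transcripts) {
    expect_true(all(tx$exons$start >= 1L & tx$exons$end <= chrom_len))
    expect_equal(darkpep:::tx_spliced_from_genome(tx, w$genome), tx$spliced)
  }
})

test_that("true novel peptides are absent from the known proteome and
          recoverable by digesting the translated entries", {
  w <- get_small_world()
  idx <- get_small_index()
  truth <- w$truth$novel_peptides
  expect_gt(nrow(truth), 0L)
  expect_true(all(classify_peptides(unique(truth$peptide), idx) == "novel"))
  entries <- darkpep:::noncoding_entries(w, w$config$min_segment_len)
  for (i in sample.int(nrow(truth), min(25L, nrow(truth)))) {
    prot <- entries$protein[entries$entry_id == truth$entry_id[i]]
    expect_true(truth$peptide[i] %in% digest_tryptic(prot, 0L))
  }
})

test_that("oversized worlds raise a sizing error", {
  expect_error(generate_world(sim_config(seed = 1, max_chrom_length = 5000)),
               "capacity")
})

test_that("PSM class counts pass through exactly", {
  w <- get_small_world(); db <- get_small_db()
  cfg <- small_config()
  cfg$psm_counts <- list(known = 200L, novel_true = 50L, novel_false = 50L,
                         decoy = 250L)
  psms <- simulate_psms(w, db, cfg, seed = 7)
  truth <- attr(psms, "truth")
  expect_equal(nrow(psms), 550L)
  expect_equal(unname(table(truth$sim_class)[c("known", "novel_true",
                                               "novel_false", "decoy")]),
               c(200L, 50L, 50L, 250L), ignore_attr = TRUE)
  expect_equal(sum(psms$is_decoy), 250L)
})

test_that("with no false matches every novel PSM is flagged correct", {
  w <- get_small_world(); db <- get_small_db()
  cfg <- small_config()
  cfg$psm_counts <- list(known = 20L, novel_true = 30L, novel_false = 0L,
                         decoy = 0L)
  psms <- simulate_psms(w, db, cfg, seed = 3)
  truth <- attr(psms, "truth")
  novel <- truth[truth$sim_class %in% c("novel_true", "novel_false"), ]
  expect_true(all(novel$correct))
})

test_that("configured score separation appears in the simulated scores", {
  w <- get_small_world(); db <- get_small_db()
  cfg <- small_config()
  cfg$psm_counts <- list(known = 1000L, novel_true = 1000L,
                         novel_false = 0L, decoy = 0L)
  cfg$score_distributions$known <- c(mean = 4.5, sd = 1)
  cfg$score_distributions$novel <- c(mean = 2.5, sd = 1)
  psms <- simulate_psms(w, db, cfg, seed = 5)
  truth <- attr(psms, "truth")
  m_known <- mean(psms$score[truth$sim_class == "known"])
  m_novel <- mean(psms$score[truth$sim_class == "novel_true"])
  expect_gt(m_known, m_novel)
  expect_equal(m_known - m_novel, 2, tolerance = 0.15)
})

test_that("an empty database is rejected", {
  w <- get_small_world()
  empty_db <- list(entries = get_small_db()$entries[0, ])
  expect_error(simulate_psms(w, empty_db, small_config()), "empty")
})

test_that("planted quantification effects have the configured size", {
  cfg <- sim_config(seed = 3, quant_noise_sd = 0.1, missingness_rate = 0)
  design <- make_paired_design(8)
  qs <- simulate_quant(sprintf("L%02d", 1:10), design, cfg,
                       planted = data.frame(locus_id = "L01",
                                            log2_effect = 1.0),
                       seed = 3)
  lmat <- summarize_labelfree(qs$peptide_mat, qs$locus_map)
  tum <- design$sample_id[design$condition == "tumor"]
  nor <- design$sample_id[design$condition == "normal"]
  npep <- sum(qs$locus_map$locus_id == "L01")
  d <- mean(lmat["L01", tum]) - mean(lmat["L01", nor])
  expect_gt(d / npep, 0.8)
  expect_lt(d / npep, 1.2)
  expect_false(anyNA(qs$peptide_mat))
})

test_that("quantification requires a non-empty design", {
  expect_error(simulate_quant("L1", make_paired_design(1)[0, ],
                              sim_config()), "zero samples")
})

test_that("simulated reads respect depth and the edit-distance model", {
  loc <- make_location("chr1", "+",
                       data.frame(start = 500L, end = 560L))
  sam <- simulate_reads(loc, depth = 10L, mismatch_rate = 0, seed = 1,
                        seqlengths = c(chr1 = 5000L))
  aln <- parse_sam(sam)
  expect_equal(nrow(aln), 10L)
  expect_true(all(aln$edit_distance == 0L))

  header_only <- simulate_reads(loc, depth = 0L, mismatch_rate = 0,
                                seed = 1, seqlengths = c(chr1 = 5000L))
  expect_true(all(startsWith(header_only, "@")))

  sam2 <- simulate_reads(loc, depth = 2000L, mismatch_rate = 0.005,
                         seed = 11, seqlengths = c(chr1 = 5000L))
  aln2 <- parse_sam(sam2)
  frac <- mean(aln2$edit_distance >= 1L)
  expected <- 1 - (1 - 0.005)^100
  expect_lt(abs(frac - expected), 0.03)
})

test_that("planted tissue classes are consistent with their detections", {
  panel <- simulate_tissue_panel(sprintf("L%02d", 1:40), seed = 4)
  n <- rowSums(panel$detection)
  expect_equal(unname(n), panel$truth$n_tissues)
  expect_true(all(n[panel$truth$class == "specific"] == 1L))
  expect_true(all(n[panel$truth$class == "nonspecific"] %in% 2:14))
  expect_true(all(n[panel$truth$class == "ubiquitous"] >= 15L))
})
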