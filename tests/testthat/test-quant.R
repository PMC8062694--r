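lf_fixture <- function() {
  mat <- matrix(c(20, 21, NA, 19,
                  21, NA, NA, 18,
                  22, 23, NA, NA), nrow = 3, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"),
                                c("s1", "s2", "s3", "s4")))
  map <- data.frame(peptide = c("p1", "p2", "p3"),
                    locus_id = c("L1", "L1", "L2"),
                    stringsAsFactors = FALSE)
  list(mat = mat, map = map)
}

test_that("label-free locus values sum non-missing member peptides", {
  f <- lf_fixture()
  lmat <- summarize_labelfree(f$mat, f$map)
  expect_equal(lmat["L1", "s1"], 41)           # 20 + 21
  expect_equal(lmat["L1", "s2"], 21)           # one of two present
  expect_true(is.na(lmat["L1", "s3"]))         # all members missing
  expect_equal(lmat["L2", "s2"], 23)
  expect_equal(attr(lmat, "provenance"), "summed_log2_ms1")
})

test_that("isobaric locus values take the median peptide log2 ratio", {
  rep_mat <- matrix(c(0.5, 1, 1,
                      1, 1, 1,
                      4, 0, 1), nrow = 3, byrow = TRUE,
                    dimnames = list(c("p1", "p2", "p3"),
                                    c("c1", "c2", "ref")))
  map <- data.frame(peptide = c("p1", "p2", "p3"), locus_id = "L1",
                    stringsAsFactors = FALSE)
  # p1 and p2 ratios at c1: log2(0.5), log2(1); p3 ref usable
  lmat <- summarize_isobaric(rep_mat, "ref", map)
  expect_equal(lmat["L1", "c1"], median(c(log2(0.5), 0, 2)))

  rep_bad <- rep_mat
  rep_bad["p3", "ref"] <- 0
  expect_warning(l2 <- summarize_isobaric(rep_bad, "ref", map),
                 "non-positive")
  expect_equal(l2["L1", "c1"], median(c(log2(0.5), 0)))

  one <- summarize_isobaric(rep_mat[1, , drop = FALSE], "ref",
                            map[1, , drop = FALSE])
  expect_equal(one["L1", "c1"], log2(0.5))
  # worked example: linear ratios 0.5, 1, 2 have median log2 ratio 0
  expect_equal(median(log2(c(0.5, 1, 2))), 0)
})

test_that("paired tests flag degenerate loci and identical groups", {
  design <- make_paired_design(4)
  tum <- design$sample_id[design$condition == "tumor"]
  nor <- design$sample_id[design$condition == "normal"]
  mat <- matrix(NA_real_, 2, 8, dimnames = list(c("const", "ident"),
                                                design$sample_id))
  mat["const", tum] <- c(21, 22, 23, 24); mat["const", nor] <- c(20, 21,
                                                                 22, 23)
  mat["ident", tum] <- c(20, 21, 22, 23); mat["ident", nor] <- c(20, 21,
                                                                 22, 23)
  res <- test_differential(mat, design, mode = "paired")
  const <- res[res$locus_id == "const", ]
  expect_true(const$degenerate)
  expect_equal(const$effect, 1)
  expect_lte(const$p_value, .Machine$double.xmin)
  ident <- res[res$locus_id == "ident", ]
  expect_equal(ident$effect, 0)
  expect_equal(ident$p_value, 1)
})

test_that("loci with too few complete pairs are reported untested", {
  design <- make_paired_design(3)
  mat <- matrix(rnorm(6), 1, 6, dimnames = list("L1", design$sample_id))
  mat[1, design$sample_id[design$condition == "normal"][2:3]] <- NA
  res <- test_differential(mat, design, mode = "paired")
  expect_false(res$tested)
  expect_true(is.na(res$p_value))
})

test_that("BH adjustment never decreases p-values", {
  design <- make_paired_design(6)
  mat <- matrix(rnorm(20 * 12, 20, 0.5), 20, 12,
                dimnames = list(sprintf("L%02d", 1:20), design$sample_id))
  res <- test_differential(mat, design, mode = "paired", adjust = "BH")
  expect_true(all(res$adjusted_p >= res$p_value - 1e-12, na.rm = TRUE))
})

test_that("fold change is two to the mean log2 difference", {
  design <- make_paired_design(2)
  mat <- matrix(c(21, 21, 20, 20,
                  20, 20, 20, 20,
                  19, 19, 20, 20), 3, byrow = TRUE,
                dimnames = list(c("up", "flat", "down"), design$sample_id))
  fc <- fold_change(mat, design)
  expect_equal(unname(fc), c(2, 1, 0.5))
})

test_that("tissue classes follow the detection-count bands", {
  det <- matrix(FALSE, 3, 31, dimnames = list(c("ubi", "non", "spec"),
                                              sprintf("t%02d", 1:31)))
  det["ubi", 1:20] <- TRUE
  det["non", 1:5] <- TRUE
  det["spec", 7] <- TRUE
  cls <- classify_tissue_specificity(det)
  expect_equal(cls$class, c("ubiquitous", "nonspecific", "tissue_specific"))
  # boundary: exactly 15 tissues is ubiquitous, 14 is nonspecific
  det2 <- matrix(FALSE, 2, 31)
  rownames(det2) <- c("a", "b")
  det2["a", 1:15] <- TRUE; det2["b", 1:14] <- TRUE
  expect_equal(classify_tissue_specificity(det2)$class,
               c("ubiquitous", "nonspecific"))
})

test_that("recurrence bins use half-open missingness intervals", {
  det <- matrix(FALSE, 3, 10, dimnames = list(c("all", "one", "half"),
                                              sprintf("s%02d", 1:10)))
  det["all", ] <- TRUE
  det["one", 1] <- TRUE
  det["half", 1:5] <- TRUE
  bins <- recurrence_bins(det)
  expect_equal(bins$bin[match(c("all", "one", "half"), bins$locus_id)],
               c("0-25", "75-100", "50-75"))
})

test_that("cross-dataset overlap splits recurrence by pseudogene status", {
  det <- matrix(FALSE, 10, 13,
                dimnames = list(sprintf("L%02d", 1:10), sprintf("D%02d",
                                                                1:13)))
  det[1:4, 1:2] <- TRUE          # pseudogene loci seen in 2 datasets
  det[5:10, 1] <- TRUE           # rest seen once
  categories <- setNames(c(rep("pseudogene", 4), rep("pseudogene", 6)),
                         rownames(det))
  categories[5:10] <- "lncRNA"
  res <- cross_dataset_overlap(det, categories)
  expect_equal(unname(res$share["pseudogene"]), 1)
  expect_equal(unname(res$share["non_pseudogene"]), 0)

  det[5, 2] <- TRUE
  res2 <- cross_dataset_overlap(det, categories)
  expect_equal(unname(res2$share["non_pseudogene"]), 1 / 6)
  expect_true(all(res2$per_locus$recurrent[res2$per_locus$n_datasets >= 2]))
})
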