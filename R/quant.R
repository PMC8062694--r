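# Locus-level quantification and statistics.
#
# Label-free: the log2 MS1 intensities of a locus's member peptides are
# summed per sample (missing iff all members are missing). Isobaric: the
# peptide log2 ratio against the internal reference channel is summarized
# to the locus by the median. Tumor/normal comparisons use the paired t
# test for matched designs and a two-sided t test otherwise; missing
# values are never imputed.

#' Sum peptide log2 MS1 intensities to locus level
#'
#' @param peptide_log2 peptide x sample matrix of log2 MS1 intensities
#'   (NA = missing).
#' @param locus_map data.frame with `peptide`, `locus_id`.
#' @return locus x sample matrix (attribute `provenance` =
#'   `"summed_log2_ms1"`); a locus is missing in a sample iff all member
#'   peptides are missing there.
#' @export
summarize_labelfree <- function(peptide_log2, locus_map) {
  loci <- unique(locus_map$locus_id)
  out <- matrix(NA_real_, length(loci), ncol(peptide_log2),
                dimnames = list(loci, colnames(peptide_log2)))
  for (l in loci) {
    rows <- locus_map$peptide[locus_map$locus_id == l]
    sub <- peptide_log2[rows, , drop = FALSE]
    s <- colSums(sub, na.rm = TRUE)
    s[colSums(!is.na(sub)) == 0L] <- NA_real_
    out[l, ] <- s
  }
  attr(out, "provenance") <- "summed_log2_ms1"
  out
}

#' Median peptide log2 ratios to locus level (isobaric designs)
#'
#' Peptide log2 ratio = log2(channel) - log2(reference); peptides with a
#' missing or non-positive reference are excluded with a warning. Locus
#' value = median over member peptides.
#'
#' @param reporter peptide x channel matrix of linear reporter intensities.
#' @param reference_channel column name of the internal reference channel.
#' @param locus_map data.frame with `peptide`, `locus_id`.
#' @return locus x channel matrix of log2 ratios (reference column
#'   dropped; attribute `provenance` = `"median_log2_ratio"`).
#' @export
summarize_isobaric <- function(reporter, reference_channel, locus_map) {
  stopifnot(reference_channel %in% colnames(reporter))
  ref <- reporter[, reference_channel]
  bad <- is.na(ref) | ref <= 0
  if (any(bad)) {
    warning(sum(bad), " peptide(s) excluded: reference channel missing or",
            " non-positive")
  }
  keep <- rownames(reporter)[!bad]
  chans <- setdiff(colnames(reporter), reference_channel)
  ratios <- log2(reporter[keep, chans, drop = FALSE]) -
    log2(reporter[keep, reference_channel])
  lm2 <- locus_map[locus_map$peptide %in% keep, , drop = FALSE]
  loci <- unique(lm2$locus_id)
  out <- matrix(NA_real_, length(loci), length(chans),
                dimnames = list(loci, chans))
  for (l in loci) {
    sub <- ratios[lm2$peptide[lm2$locus_id == l], , drop = FALSE]
    out[l, ] <- apply(sub, 2L, function(v) {
      if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
    })
  }
  attr(out, "provenance") <- "median_log2_ratio"
  out
}

#' Tumor-vs-normal differential tests per locus
#'
#' Paired mode uses only pairs with both conditions observed and requires
#' at least `min_n` complete pairs; unpaired mode requires `min_n` observed
#' samples per group. Degenerate loci (zero-variance differences) are
#' flagged: identical values give effect 0 and p = 1, a constant non-zero
#' difference gives a p below the machine-representable threshold.
#'
#' @param mat locus x sample log2 matrix.
#' @param design design data.frame (`sample_id`, `condition`, `pair_id`).
#' @param mode `"paired"` or `"unpaired"`.
#' @param adjust `"BH"` (Benjamini-Hochberg across tested loci) or
#'   `"none"`.
#' @param min_n minimum complete pairs / per-group samples (default 2).
#' @return data.frame: `locus_id`, `effect` (mean tumor - normal log2
#'   difference), `p_value`, `adjusted_p`, `test`, `n_used`, `tested`,
#'   `degenerate`.
#' @export
test_differential <- function(mat, design, mode = c("paired", "unpaired"),
                              adjust = c("BH", "none"), min_n = 2L) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  tum <- design$sample_id[design$condition == "tumor"]
  nor <- design$sample_id[design$condition == "normal"]
  res <- lapply(rownames(mat), function(l) {
    row <- mat[l, ]
    if (mode == "paired") {
      pairs <- unique(design$pair_id)
      tv <- row[design$sample_id[match(paste(pairs, "tumor"),
                                       paste(design$pair_id,
                                             design$condition))]]
      nv <- row[design$sample_id[match(paste(pairs, "normal"),
                                       paste(design$pair_id,
                                             design$condition))]]
      ok <- !is.na(tv) & !is.na(nv)
      tv <- tv[ok]; nv <- nv[ok]
      n_used <- sum(ok)
      if (n_used < min_n) {
        return(data.frame(locus_id = l, effect = NA_real_,
                          p_value = NA_real_, adjusted_p = NA_real_,
                          test = "paired_t", n_used = n_used,
                          tested = FALSE, degenerate = FALSE))
      }
      d <- tv - nv
      if (isTRUE(all.equal(stats::var(d), 0)) || stats::var(d) == 0) {
        eff <- mean(d)
        p <- if (eff == 0) 1 else .Machine$double.xmin
        return(data.frame(locus_id = l, effect = eff, p_value = p,
                          adjusted_p = NA_real_, test = "paired_t",
                          n_used = n_used, tested = TRUE,
                          degenerate = TRUE))
      }
      tt <- t.test(tv, nv, paired = TRUE)
      data.frame(locus_id = l, effect = unname(tt$estimate),
                 p_value = tt$p.value, adjusted_p = NA_real_,
                 test = "paired_t", n_used = n_used, tested = TRUE,
                 degenerate = FALSE)
    } else {
      tv <- row[tum]; nv <- row[nor]
      tv <- tv[!is.na(tv)]; nv <- nv[!is.na(nv)]
      n_used <- min(length(tv), length(nv))
      if (length(tv) < min_n || length(nv) < min_n) {
        return(data.frame(locus_id = l, effect = NA_real_,
                          p_value = NA_real_, adjusted_p = NA_real_,
                          test = "two_sided_t", n_used = n_used,
                          tested = FALSE, degenerate = FALSE))
      }
      if (stats::var(c(tv, nv)) == 0) {
        return(data.frame(locus_id = l, effect = 0, p_value = 1,
                          adjusted_p = NA_real_, test = "two_sided_t",
                          n_used = n_used, tested = TRUE,
                          degenerate = TRUE))
      }
      if (stats::var(tv) == 0 && stats::var(nv) == 0) {
        eff <- mean(tv) - mean(nv)
        return(data.frame(locus_id = l, effect = eff,
                          p_value = .Machine$double.xmin,
                          adjusted_p = NA_real_, test = "two_sided_t",
                          n_used = n_used, tested = TRUE,
                          degenerate = TRUE))
      }
      tt <- t.test(tv, nv)
      data.frame(locus_id = l, effect = mean(tv) - mean(nv),
                 p_value = tt$p.value, adjusted_p = NA_real_,
                 test = "two_sided_t", n_used = n_used, tested = TRUE,
                 degenerate = FALSE)
    }
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") {
    sel <- out$tested
    out$adjusted_p[sel] <- p.adjust(out$p_value[sel], method = "BH")
  } else {
    out$adjusted_p <- out$p_value
  }
  rownames(out) <- NULL
  out
}

#' Linear-scale tumor/normal fold change per locus
#'
#' `2 ^ (mean tumor log2 - mean normal log2)` over non-missing values.
#'
#' @param mat locus x sample log2 matrix.
#' @param design design data.frame.
#' @return named numeric vector of linear fold changes (NA where a group
#'   has no observations).
#' @export
fold_change <- function(mat, design) {
  tum <- design$sample_id[design$condition == "tumor"]
  nor <- design$sample_id[design$condition == "normal"]
  mt <- rowMeans(mat[, tum, drop = FALSE], na.rm = TRUE)
  mn <- rowMeans(mat[, nor, drop = FALSE], na.rm = TRUE)
  fc <- 2^(mt - mn)
  fc[is.nan(mt) | is.nan(mn)] <- NA_real_
  fc
}

#' Classify tissue specificity of novel loci
#'
#' Detection in one tissue is tissue-specific; in 2 to `ubiquitous_min` - 1
#' tissues nonspecific; in at least `ubiquitous_min` tissues ubiquitous.
#' Loci detected nowhere are returned with class NA.
#'
#' @param detection logical locus x tissue matrix (TRUE = at least one
#'   quantified member peptide in at least one sample of that tissue).
#' @param ubiquitous_min ubiquitous threshold, default 15.
#' @return data.frame: `locus_id`, `n_tissues_detected`, `class`.
#' @export
classify_tissue_specificity <- function(detection, ubiquitous_min = 15L) {
  n <- rowSums(detection)
  cls <- rep(NA_character_, length(n))
  cls[n == 1L] <- "tissue_specific"
  cls[n >= 2L & n < ubiquitous_min] <- "nonspecific"
  cls[n >= ubiquitous_min] <- "ubiquitous"
  data.frame(locus_id = rownames(detection), n_tissues_detected = n,
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Bin loci by their per-dataset missing fraction
#'
#' Missing fraction = share of the dataset's samples in which the locus is
#' not detected, binned on half-open intervals [0, .25), [.25, .5),
#' [.5, .75) and closed [.75, 1].
#'
#' @param detection logical locus x sample matrix.
#' @param dataset character vector of dataset IDs per sample (column).
#' @return data.frame: `locus_id`, `dataset_id`, `missing_fraction`, `bin`.
#' @export
recurrence_bins <- function(detection, dataset = rep("DS1",
                                                     ncol(detection))) {
  bins <- c("0-25", "25-50", "50-75", "75-100")
  out <- lapply(unique(dataset), function(ds) {
    sub <- detection[, dataset == ds, drop = FALSE]
    miss <- 1 - rowMeans(sub)
    data.frame(locus_id = rownames(sub), dataset_id = ds,
               missing_fraction = miss,
               bin = bins[findInterval(miss, c(0.25, 0.5, 0.75)) + 1L],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-dataset recurrence of novel loci
#'
#' Counts in how many datasets each locus is detected and summarizes the
#' share detected in at least `k` datasets, split into pseudogene versus
#' non-pseudogene loci.
#'
#' @param detection logical locus x dataset matrix.
#' @param categories named character vector of locus categories.
#' @param k recurrence threshold (default 2 datasets).
#' @return list with `per_locus` (data.frame `locus_id`, `n_datasets`,
#'   `recurrent`) and `share` (named numeric: recurrent share within
#'   pseudogene and non-pseudogene loci).
#' @export
cross_dataset_overlap <- function(detection, categories, k = 2L) {
  n <- rowSums(detection)
  per_locus <- data.frame(locus_id = rownames(detection), n_datasets = n,
                          recurrent = n >= k, row.names = NULL,
                          stringsAsFactors = FALSE)
  is_psg <- categories[per_locus$locus_id] == "pseudogene"
  share <- c(
    pseudogene = if (any(is_psg)) mean(per_locus$recurrent[is_psg]) else
      NA_real_,
    non_pseudogene = if (any(!is_psg)) mean(per_locus$recurrent[!is_psg])
      else NA_real_)
  list(per_locus = per_locus, share = share)
}
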