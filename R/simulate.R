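# Seeded simulators for PSM tables, quantification matrices and RNA-seq
# alignments. These emulate the statistical structure of the study inputs:
# class-dependent search-score distributions (correct known-class matches
# score higher than correct novel-class matches; incorrect matches and
# decoys share one null distribution), planted tumor effects with missing
# values, and single-end reads over peptide regions with substitution
# errors recorded in the edit-distance tag.

random_tryptic_like <- function(n, len_range = c(8L, 12L)) {
  vapply(seq_len(n), function(i) {
    L <- sample(len_range[1]:len_range[2], 1L)
    paste0(paste(sample(setdiff(AA20, c("K", "R")), L - 1L, replace = TRUE),
                 collapse = ""), sample(c("K", "R"), 1L))
  }, character(1L))
}

#' Simulate peptide-spectrum matches with ground-truth labels
#'
#' Emits target PSMs to known, novel (correct and incorrect) entries and
#' decoy PSMs. Scores are drawn from the per-class distributions of the
#' config; incorrect target matches and decoys share the `incorrect`
#' distribution. When `psm_counts$decoy` is `NA`, the decoy count is
#' balanced: noncoding-origin decoys equal the number of incorrect novel
#' targets, and as many known-origin decoys are added (incorrect matches
#' land with equal density in target and decoy space).
#'
#' @param world a [generate_world()] object.
#' @param db the [build_search_db()] result for that world.
#' @param config a [sim_config()]; defaults to the world's.
#' @param seed root seed for this simulation; defaults to the config seed.
#' @return data.frame of PSMs (`spectrum_id`, `sample_id`, `dataset_id`,
#'   `peptide`, `score`, `is_decoy`, `matched_entry`) with a `truth`
#'   attribute: data.frame `spectrum_id`, `sim_class` (known / novel_true /
#'   novel_false / decoy), `correct`.
#' @export
simulate_psms <- function(world, db, config = world$config,
                          seed = config$seed) {
  if (!nrow(db$entries)) stop("empty search database")
  counts <- config$psm_counts
  dist <- config$score_distributions
  with_substream(seed, "psms", {
    nc_entries <- db$entries[db$entries$class == "noncoding", , drop = FALSE]
    nc_decoys <- db$entries[db$entries$class == "decoy" &
                              db$entries$origin_class == "noncoding", ,
                            drop = FALSE]
    kn_decoys <- db$entries[db$entries$class == "decoy" &
                              db$entries$origin_class == "known", ,
                            drop = FALSE]
    known_pool <- do.call(rbind, lapply(names(world$known_proteome),
                                        function(pid) {
      peps <- digest_tryptic(world$known_proteome[[pid]], 0L)
      peps <- peps[nchar(peps) >= 7L & nchar(peps) <= 45L]
      if (!length(peps)) return(NULL)
      data.frame(peptide = peps, entry = pid, stringsAsFactors = FALSE)
    }))
    truth_pool <- world$truth$novel_peptides

    n_known <- counts$known
    n_true <- counts$novel_true
    n_false <- counts$novel_false
    n_decoy <- counts$decoy
    if (is.null(n_decoy) || is.na(n_decoy)) {
      n_decoy_nc <- n_false
      n_decoy_kn <- n_false
    } else {
      # explicit total: origins follow the decoy database composition
      n_decoy_nc <- rbinom(1L, n_decoy,
                           nrow(nc_decoys) / (nrow(nc_decoys) +
                                                nrow(kn_decoys)))
      n_decoy_kn <- n_decoy - n_decoy_nc
    }

    draw <- function(n, cls) rnorm(n, dist[[cls]]["mean"],
                                   dist[[cls]]["sd"])
    rows <- list()
    if (n_known > 0L) {
      ii <- sample.int(nrow(known_pool), n_known, replace = TRUE)
      rows$known <- data.frame(peptide = known_pool$peptide[ii],
                               matched_entry = known_pool$entry[ii],
                               score = draw(n_known, "known"),
                               is_decoy = FALSE, sim_class = "known",
                               correct = TRUE, stringsAsFactors = FALSE)
    }
    if (n_true > 0L) {
      if (!nrow(truth_pool)) stop("world has no true novel peptides")
      ii <- sample.int(nrow(truth_pool), n_true, replace = TRUE)
      rows$novel_true <- data.frame(peptide = truth_pool$peptide[ii],
                                    matched_entry = truth_pool$entry_id[ii],
                                    score = draw(n_true, "novel"),
                                    is_decoy = FALSE,
                                    sim_class = "novel_true", correct = TRUE,
                                    stringsAsFactors = FALSE)
    }
    if (n_false > 0L) {
      idx <- known_peptide_index(world$known_proteome,
                                 variant_proteins = variant_proteins(world))
      peps <- character(0)
      while (length(peps) < n_false) {
        cand <- unique(random_tryptic_like(2L * (n_false - length(peps))))
        cand <- setdiff(cand, c(peps, truth_pool$peptide))
        cand <- cand[classify_peptides(cand, idx) == "novel"]
        peps <- c(peps, cand)
      }
      peps <- peps[seq_len(n_false)]
      rows$novel_false <- data.frame(
        peptide = peps,
        matched_entry = sample(nc_entries$entry_id, n_false, replace = TRUE),
        score = draw(n_false, "incorrect"), is_decoy = FALSE,
        sim_class = "novel_false", correct = FALSE, stringsAsFactors = FALSE)
    }
    n_decoy_total <- n_decoy_nc + n_decoy_kn
    if (n_decoy_total > 0L) {
      dpep <- unique(random_tryptic_like(ceiling(1.2 * n_decoy_total)))
      while (length(dpep) < n_decoy_total) {
        dpep <- unique(c(dpep, random_tryptic_like(n_decoy_total)))
      }
      dpep <- dpep[seq_len(n_decoy_total)]
      dent <- c(sample(nc_decoys$entry_id, n_decoy_nc, replace = TRUE),
                sample(kn_decoys$entry_id, n_decoy_kn, replace = TRUE))
      rows$decoy <- data.frame(peptide = dpep, matched_entry = dent,
                               score = draw(n_decoy_total, "incorrect"),
                               is_decoy = TRUE, sim_class = "decoy",
                               correct = FALSE, stringsAsFactors = FALSE)
    }
    psms <- do.call(rbind, rows)
    rownames(psms) <- NULL
    n <- nrow(psms)
    psms$spectrum_id <- sprintf("sp%06d", seq_len(n))
    psms$sample_id <- sample(sprintf("S%02d", 1:8), n, replace = TRUE)
    psms$dataset_id <- "DS1"
    truth <- psms[, c("spectrum_id", "sim_class", "correct")]
    out <- psms[, c("spectrum_id", "sample_id", "dataset_id", "peptide",
                    "score", "is_decoy", "matched_entry")]
    attr(out, "truth") <- truth
    out
  })
}

#' Paired tumor/normal sample design
#'
#' @param n_pairs number of tumor/normal pairs.
#' @param dataset_id dataset label.
#' @param quant_mode `"labelfree_ms1"` or `"isobaric_ratio"`.
#' @return design data.frame (`sample_id`, `dataset_id`, `condition`,
#'   `pair_id`, `quant_mode`).
#' @export
make_paired_design <- function(n_pairs, dataset_id = "CRC",
                               quant_mode = "labelfree_ms1") {
  stopifnot(n_pairs >= 1L)
  data.frame(
    sample_id = c(sprintf("T%02d", seq_len(n_pairs)),
                  sprintf("N%02d", seq_len(n_pairs))),
    dataset_id = dataset_id,
    condition = rep(c("tumor", "normal"), each = n_pairs),
    pair_id = rep(sprintf("P%02d", seq_len(n_pairs)), 2L),
    quant_mode = quant_mode, stringsAsFactors = FALSE)
}

#' Simulate peptide-level quantification with planted tumor effects
#'
#' Generates per-peptide log2 intensities around a peptide-specific
#' baseline, adds the planted log2 effect to tumor samples of planted
#' loci, and injects missing values completely at random.
#'
#' @param loci character vector of locus IDs (or a locus data.frame with a
#'   `locus_id` column).
#' @param design a [make_paired_design()]-style data.frame; must have at
#'   least one sample.
#' @param config a [sim_config()].
#' @param planted data.frame (`locus_id`, `log2_effect`) or NULL to sample
#'   `config$n_planted_upregulated` loci at `config$planted_effect`.
#' @param seed root seed; defaults to the config seed.
#' @return object of class `quant_simulation`: list with `peptide_mat`
#'   (peptide x sample log2 matrix, NA = missing), `locus_map` (peptide ->
#'   locus), `design`, `planted`.
#' @export
simulate_quant <- function(loci, design, config = sim_config(),
                           planted = NULL, seed = config$seed) {
  if (!is.character(loci)) loci <- loci$locus_id
  if (!nrow(design)) stop("design has zero samples")
  with_substream(seed, "quant", {
    if (is.null(planted)) {
      n_pl <- min(config$n_planted_upregulated, length(loci))
      planted <- data.frame(
        locus_id = sample(loci, n_pl),
        log2_effect = rep(config$planted_effect, n_pl),
        stringsAsFactors = FALSE)
    }
    rng <- config$peptides_per_locus
    npep <- sample(rng[1]:rng[2], length(loci), replace = TRUE)
    locus_map <- data.frame(
      peptide = sprintf("%s_pep%d", rep(loci, npep),
                        unlist(lapply(npep, seq_len))),
      locus_id = rep(loci, npep), stringsAsFactors = FALSE)
    n_p <- nrow(locus_map); n_s <- nrow(design)
    base <- rnorm(n_p, config$baseline_log2, 1)
    eff <- planted$log2_effect[match(locus_map$locus_id, planted$locus_id)]
    eff[is.na(eff)] <- 0
    tumor <- design$condition == "tumor"
    mat <- matrix(rnorm(n_p * n_s, 0, config$quant_noise_sd), n_p, n_s,
                  dimnames = list(locus_map$peptide, design$sample_id))
    mat <- mat + base + outer(eff, as.numeric(tumor))
    if (config$missingness_rate > 0) {
      mat[runif(n_p * n_s) < config$missingness_rate] <- NA
    }
    structure(list(peptide_mat = mat, locus_map = locus_map,
                   design = design, planted = planted),
              class = "quant_simulation")
  })
}

#' Simulate a tissue-detection panel with planted expression classes
#'
#' Plants each locus as tissue-specific (detected in exactly 1 tissue),
#' nonspecific (2 to `ubiquitous_min` - 1 tissues) or ubiquitous (at least
#' `ubiquitous_min` tissues) and emits the locus-by-tissue detection
#' matrix.
#'
#' @param loci character vector of locus IDs.
#' @param n_tissues number of tissues in the panel (default 31).
#' @param class_probs sampling probabilities for (specific, nonspecific,
#'   ubiquitous).
#' @param ubiquitous_min tissue count at which a locus counts as ubiquitous.
#' @param seed integer seed.
#' @return list with `detection` (logical locus x tissue matrix) and
#'   `truth` (data.frame `locus_id`, `class`, `n_tissues`).
#' @export
simulate_tissue_panel <- function(loci, n_tissues = 31L,
                                  class_probs = c(specific = 0.5,
                                                  nonspecific = 0.4,
                                                  ubiquitous = 0.1),
                                  ubiquitous_min = 15L, seed = 1L) {
  with_substream(seed, "tissue", {
    cls <- sample(names(class_probs), length(loci), replace = TRUE,
                  prob = class_probs)
    n_det <- vapply(cls, function(cl) {
      switch(cl,
             specific = 1L,
             nonspecific = sample(2:(ubiquitous_min - 1L), 1L),
             ubiquitous = sample(ubiquitous_min:n_tissues, 1L))
    }, integer(1L))
    det <- matrix(FALSE, length(loci), n_tissues,
                  dimnames = list(loci, sprintf("tissue%02d",
                                                seq_len(n_tissues))))
    for (i in seq_along(loci)) {
      det[i, sample.int(n_tissues, n_det[i])] <- TRUE
    }
    list(detection = det,
         truth = data.frame(locus_id = loci, class = cls,
                            n_tissues = n_det, stringsAsFactors = FALSE))
  })
}

#' Simulate single-end reads over peptide regions as SAM text
#'
#' Emits `depth` alignments per peptide placement, each a `read_length`
#' all-match record whose start is uniform over positions overlapping the
#' placement's first block by at least 1 bp. Substitution counts are drawn
#' per-base at `mismatch_rate` and recorded in the `NM` tag; the CIGAR
#' stays all-match.
#'
#' @param peptide_locations location data.frame ([map_peptide()] format).
#' @param depth reads per placement (0 gives a header-only SAM).
#' @param mismatch_rate per-base substitution probability.
#' @param seed integer seed.
#' @param seqlengths named integer vector of chromosome lengths (header).
#' @param read_length read length in nt (default 100).
#' @return character vector of SAM lines (header included).
#' @export
simulate_reads <- function(peptide_locations, depth, mismatch_rate, seed,
                           seqlengths, read_length = 100L) {
  stopifnot(depth >= 0L, mismatch_rate >= 0, mismatch_rate <= 1)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                      as.integer(seqlengths)))
  if (depth == 0L || !nrow(peptide_locations)) return(header)
  with_substream(seed, "reads", {
    recs <- character(0)
    k <- 0L
    for (i in seq_len(nrow(peptide_locations))) {
      b <- peptide_locations$blocks[[i]][1L, ]
      chrom <- peptide_locations$chrom[i]
      lo <- max(1L, b$start - read_length + 1L)
      hi <- min(b$end, seqlengths[[chrom]] - read_length + 1L)
      if (hi < lo) hi <- lo
      starts <- sample(lo:hi, depth, replace = TRUE)
      nm <- rbinom(depth, read_length, mismatch_rate)
      seqs <- vapply(seq_len(depth), function(j) random_dna(read_length),
                     character(1L))
      recs <- c(recs, sprintf(
        "read%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
        k + seq_len(depth), chrom, starts, read_length, seqs, nm))
      k <- k + depth
    }
    c(header, recs)
  })
}
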