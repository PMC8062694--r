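# Dark-antigen candidate screening.
#
# 9-mers enumerated from the translated segments of novel loci are scored
# by pluggable MHC / C-terminal cleavage / TAP components, combined with
# the NetCTLpan-convention weights (MHC + 0.225 * cleavage + 0.025 * TAP),
# expressed as a percentile rank against a frozen background of random
# natural 9-mers, and intersected with the tumor/normal fold-change
# criterion.

#' Epitope scoring configuration
#'
#' @param w_cleavage weight of the C-terminal cleavage score (default
#'   0.225).
#' @param w_tap weight of the TAP transport score (default 0.025).
#' @param rank_threshold maximum percent rank for selection (default 0.5).
#' @param background_size number of background 9-mers (default 1000).
#' @param background_seed seed used to draw the frozen background.
#' @param fold_change_min minimum tumor/normal linear fold change (default
#'   1.5).
#' @param combine `"additive"` (NetCTLpan convention) or
#'   `"weighted_average"` (normalized by the weight sum).
#' @return an `epitope_config` object.
#' @export
epitope_config <- function(w_cleavage = 0.225, w_tap = 0.025,
                           rank_threshold = 0.5, background_size = 1000L,
                           background_seed = 1L, fold_change_min = 1.5,
                           combine = c("additive", "weighted_average")) {
  stopifnot(w_cleavage >= 0, w_tap >= 0, rank_threshold > 0,
            rank_threshold <= 100, background_size >= 1L)
  structure(list(w_cleavage = w_cleavage, w_tap = w_tap,
                 rank_threshold = rank_threshold,
                 background_size = as.integer(background_size),
                 background_seed = as.integer(background_seed),
                 fold_change_min = fold_change_min,
                 combine = match.arg(combine)),
            class = "epitope_config")
}

#' Enumerate all overlapping 9-mer windows of a protein
#'
#' @param protein amino-acid string.
#' @return data.frame with `nine_mer` and 1-based `offset`; zero rows if
#'   the protein is shorter than 9 residues.
#' @export
enumerate_9mers <- function(protein) {
  n <- nchar(protein) - 8L
  if (n <= 0L) {
    return(data.frame(nine_mer = character(), offset = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(nine_mer = substring(protein, seq_len(n), seq_len(n) + 8L),
             offset = seq_len(n), stringsAsFactors = FALSE)
}

#' Combine component scores into a presentation score
#'
#' Additive (default): `mhc + w_cleavage * cleavage + w_tap * tap`, the
#' published convention of the reference tool whose printed weights are
#' the defaults here. `"weighted_average"` divides by
#' `1 + w_cleavage + w_tap`.
#'
#' @param mhc,cleavage,tap component scores (vectorized).
#' @param cfg an [epitope_config()].
#' @return numeric combined scores.
#' @export
combined_score <- function(mhc, cleavage, tap, cfg = epitope_config()) {
  s <- mhc + cfg$w_cleavage * cleavage + cfg$w_tap * tap
  if (cfg$combine == "weighted_average") {
    s <- s / (1 + cfg$w_cleavage + cfg$w_tap)
  }
  s
}

# Deterministic toy scorer tables. MHC depends only on the anchor
# positions 2 and 9 (mean of two per-residue preference tables), cleavage
# on the C-terminal residue, TAP on mean Kyte-Doolittle hydropathy scaled
# to [0, 1]. Values are fixed constants of the package.
.ANCHOR2 <- c(A = 0.30, C = 0.05, D = 0.00, E = 0.02, F = 0.35, G = 0.10,
              H = 0.05, I = 0.80, K = 0.02, L = 1.00, M = 0.90, N = 0.05,
              P = 0.00, Q = 0.20, R = 0.01, S = 0.15, T = 0.25, V = 0.70,
              W = 0.10, Y = 0.15)
.ANCHOR9 <- c(A = 0.25, C = 0.05, D = 0.00, E = 0.00, F = 0.40, G = 0.02,
              H = 0.02, I = 0.75, K = 0.05, L = 0.90, M = 0.50, N = 0.02,
              P = 0.01, Q = 0.02, R = 0.05, S = 0.05, T = 0.10, V = 1.00,
              W = 0.15, Y = 0.30)
.CLEAVAGE <- c(A = 0.40, C = 0.20, D = 0.05, E = 0.10, F = 0.80, G = 0.10,
               H = 0.30, I = 0.60, K = 0.55, L = 0.90, M = 0.70, N = 0.15,
               P = 0.00, Q = 0.20, R = 0.60, S = 0.25, T = 0.30, V = 1.00,
               W = 0.75, Y = 0.85)
.KD <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
         I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
         R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

#' Reference 9-mer scorer
#'
#' A deterministic, documented stand-in scorer with the same interface as
#' any external predictor plugin: per 9-mer it returns MHC, C-terminal
#' cleavage and TAP component scores, each in [0, 1]. The MHC component
#' reads only the anchor positions 2 and 9; the allele tag is accepted for
#' interface compatibility and ignored.
#'
#' @param nine_mers character vector of 9-residue peptides.
#' @param allele ignored by this scorer.
#' @return data.frame with `nine_mer`, `mhc`, `cleavage`, `tap`.
#' @export
reference_scorer <- function(nine_mers, allele = NULL) {
  stopifnot(all(nchar(nine_mers) == 9L))
  p2 <- substring(nine_mers, 2L, 2L)
  p9 <- substring(nine_mers, 9L, 9L)
  mhc <- (.ANCHOR2[p2] + .ANCHOR9[p9]) / 2
  cleav <- .CLEAVAGE[p9]
  kd_min <- min(.KD); kd_rng <- diff(range(.KD))
  tap <- vapply(nine_mers, function(s) {
    mean((.KD[strsplit(s, "", fixed = TRUE)[[1L]]] - kd_min) / kd_rng)
  }, numeric(1L), USE.NAMES = FALSE)
  data.frame(nine_mer = nine_mers, mhc = unname(mhc),
             cleavage = unname(cleav), tap = tap, stringsAsFactors = FALSE)
}

#' Build the frozen background of random natural 9-mers
#'
#' Samples `cfg$background_size` 9-mer windows uniformly from all windows
#' of the supplied natural proteome, scores them with `scorer` and returns
#' their combined scores. With a fixed seed and proteome the background is
#' bit-stable.
#'
#' @param proteome named character vector of natural protein sequences.
#' @param cfg an [epitope_config()].
#' @param scorer scoring function with the [reference_scorer()] interface.
#' @param allele optional allele tag passed to the scorer.
#' @return numeric vector of background combined scores.
#' @export
build_background <- function(proteome, cfg = epitope_config(),
                             scorer = reference_scorer, allele = NULL) {
  windows <- do.call(rbind, lapply(proteome, enumerate_9mers))
  if (!nrow(windows)) stop("proteome yields no 9-mer windows")
  with_substream(cfg$background_seed, "epitope_background", {
    ii <- sample.int(nrow(windows), cfg$background_size, replace = TRUE)
    sc <- scorer(windows$nine_mer[ii], allele)
    combined_score(sc$mhc, sc$cleavage, sc$tap, cfg)
  })
}

#' Percentile rank of scores against the frozen background
#'
#' `rank = 100 * #(background >= score) / background size`; background
#' scores tied with the query count against it (conservative). A score
#' above the whole background ranks 0.
#'
#' @param score numeric vector of combined scores.
#' @param background frozen background scores from [build_background()].
#' @return numeric vector of percent ranks in [0, 100].
#' @export
percent_rank <- function(score, background) {
  n <- length(background)
  sb <- sort(background)
  100 * (n - findInterval(score, sb, left.open = TRUE)) / n
}

#' Score all 9-mers of a set of locus proteins
#'
#' @param loci data.frame with `locus_id` and `protein` (the translated
#'   segment of the locus).
#' @param background frozen background scores.
#' @param cfg an [epitope_config()].
#' @param scorer scorer function.
#' @param allele optional allele tag.
#' @return data.frame of epitope candidates with component scores,
#'   combined score and percent rank.
#' @export
score_epitopes <- function(loci, background, cfg = epitope_config(),
                           scorer = reference_scorer, allele = NULL) {
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    w <- enumerate_9mers(loci$protein[i])
    if (!nrow(w)) return(NULL)
    w$source_locus <- loci$locus_id[i]
    w
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(data.frame(nine_mer = character(), offset = integer(),
                      source_locus = character(), mhc = numeric(),
                      cleavage = numeric(), tap = numeric(),
                      combined = numeric(), percent_rank = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  sc <- scorer(out$nine_mer, allele)
  out$mhc <- sc$mhc; out$cleavage <- sc$cleavage; out$tap <- sc$tap
  out$combined <- combined_score(sc$mhc, sc$cleavage, sc$tap, cfg)
  out$percent_rank <- percent_rank(out$combined, background)
  rownames(out) <- NULL
  out
}

#' Select dark-antigen candidates
#'
#' Keeps 9-mers whose percent rank is at or below the threshold and whose
#' source locus is upregulated in tumor by at least the configured fold
#' change. The fold-change criterion applies only where a matched-normal
#' fold change exists; loci without one (no matched normals) pass on the
#' rank criterion alone.
#'
#' @param epitopes scored 9-mers from [score_epitopes()].
#' @param locus_fold_changes named numeric vector of linear tumor/normal
#'   fold changes (NA = no matched normals).
#' @param cfg an [epitope_config()].
#' @return list with `candidates` (selected rows, plus
#'   `locus_fold_change`) and `locus_summary` (per-locus: has at least one
#'   passing 9-mer).
#' @export
select_candidates <- function(epitopes, locus_fold_changes,
                              cfg = epitope_config()) {
  fc <- locus_fold_changes[epitopes$source_locus]
  pass_rank <- epitopes$percent_rank <= cfg$rank_threshold
  pass_fc <- is.na(fc) | fc >= cfg$fold_change_min
  cand <- epitopes[pass_rank & pass_fc, , drop = FALSE]
  cand$locus_fold_change <- unname(fc[pass_rank & pass_fc])
  rownames(cand) <- NULL
  loci <- unique(epitopes$source_locus)
  summary <- data.frame(
    locus_id = loci,
    has_candidate = loci %in% cand$source_locus,
    stringsAsFactors = FALSE)
  list(candidates = cand, locus_summary = summary)
}

#' Fixture with one planted high-scoring 9-mer
#'
#' Builds a small set of locus proteins in which exactly one 9-mer — an
#' optimal-anchor, cleavage-favorable, maximally hydrophobic window
#' embedded in an upregulated locus — scores at the top of the reference
#' scorer's range, while every other window is composed of low-preference
#' residues. Used to validate end-to-end candidate selection.
#'
#' @param seed integer seed for the filler residues.
#' @param n_loci number of loci (>= 2; locus 1 carries the planted 9-mer
#'   and a fold change of 2, the others are not upregulated).
#' @return list with `loci` (data.frame `locus_id`, `protein`),
#'   `fold_changes` (named numeric) and `planted` (the 9-mer string).
#' @export
simulate_antigen_fixture <- function(seed = 1L, n_loci = 3L) {
  stopifnot(n_loci >= 2L)
  low <- names(sort(.ANCHOR2 + .ANCHOR9 + .CLEAVAGE + (.KD - min(.KD)) /
                      diff(range(.KD))))[1:6]
  planted <- paste0("G", names(which.max(.ANCHOR2)), "IIIIII",
                    names(which.max(.ANCHOR9)))
  with_substream(seed, "antigen_fixture", {
    filler <- function(n) paste(sample(low, n, replace = TRUE),
                                collapse = "")
    prot1 <- paste0(filler(10L), planted, filler(10L))
    loci <- data.frame(
      locus_id = sprintf("LOC%02d", seq_len(n_loci)),
      protein = c(prot1, vapply(seq_len(n_loci - 1L),
                                function(i) filler(25L), character(1L))),
      stringsAsFactors = FALSE)
    fc <- setNames(c(2, rep(1, n_loci - 1L)), loci$locus_id)
    list(loci = loci, fold_changes = fc, planted = planted)
  })
}
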