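# Novel-peptide classification and class-specific target-decoy FDR.
#
# Peptides are classed known / variant / novel by sequence matching against
# the known proteome (under I/L equivalence) and the variant entries. Known
# and variant matches are discarded from both the target and the decoy sets
# before FDR is estimated within the novel class alone, so that the
# abundant, high-scoring known-class matches cannot mask false novel
# discoveries.

#' Build the known/variant matching index
#'
#' Precomputes (a) the set of I/L-collapsed fully tryptic peptides of the
#' known proteome (used to discard decoy matches that read as known tryptic
#' peptides) and (b) collapsed protein strings for contiguous-substring
#' matching, the in-package equivalent of a BLASTP exact-identity filter.
#'
#' @param known_proteome named character vector of protein sequences.
#' @param variant_proteins character vector of variant entry sequences.
#' @param missed_cleavages missed cleavages enumerated for the tryptic set.
#' @param peptide_length length bounds for tryptic index membership.
#' @return a `peptide_index` object.
#' @export
known_peptide_index <- function(known_proteome, variant_proteins = character(),
                                missed_cleavages = 2L,
                                peptide_length = c(7L, 45L)) {
  tryp <- unlist(lapply(known_proteome, digest_tryptic,
                        missed_cleavages = missed_cleavages),
                 use.names = FALSE)
  tryp <- tryp[nchar(tryp) >= peptide_length[1] &
                 nchar(tryp) <= peptide_length[2]]
  tryp_set <- new.env(parent = emptyenv())
  for (p in unique(il_collapse(tryp))) assign(p, TRUE, envir = tryp_set)
  structure(list(
    tryptic = tryp_set,
    known_concat = paste(il_collapse(known_proteome), collapse = "#"),
    variant_concat = if (length(variant_proteins)) {
      paste(il_collapse(variant_proteins), collapse = "#")
    } else {
      ""
    }), class = "peptide_index")
}

is_known_tryptic <- function(peptides, index) {
  vapply(il_collapse(peptides), function(p) {
    exists(p, envir = index$tryptic, inherits = FALSE)
  }, logical(1L), USE.NAMES = FALSE)
}

#' Classify peptides as known, variant or novel
#'
#' A peptide is `known` if (I/L-collapsed) it is a contiguous substring of
#' any known protein — which subsumes the fully tryptic case; `variant` if
#' it instead matches a variant entry; otherwise `novel`. Modifications
#' must be stripped before calling: class membership is a pure sequence
#' property.
#'
#' @param peptides character vector (no empty strings).
#' @param index a [known_peptide_index()].
#' @return named character vector of classes, one per input peptide.
#' @export
classify_peptides <- function(peptides, index) {
  if (any(is.na(peptides) | !nzchar(peptides))) {
    stop("empty peptide sequence")
  }
  cp <- il_collapse(peptides)
  uq <- unique(cp)
  in_known <- vapply(uq, grepl, logical(1L), x = index$known_concat,
                     fixed = TRUE, USE.NAMES = FALSE)
  cls <- ifelse(in_known, "known", "novel")
  if (nzchar(index$variant_concat)) {
    maybe_var <- !in_known
    in_var <- logical(length(uq))
    in_var[maybe_var] <- vapply(uq[maybe_var], grepl, logical(1L),
                                x = index$variant_concat, fixed = TRUE,
                                USE.NAMES = FALSE)
    cls[in_var] <- "variant"
  }
  setNames(cls[match(cp, uq)], peptides)
}

#' Partition PSMs for class-specific FDR
#'
#' Removes, before novel-class FDR estimation: target PSMs whose peptide
#' classifies as known or variant; decoy PSMs whose (reversed-read) peptide
#' matches a known tryptic peptide; and decoy PSMs whose matched entry
#' originates from a non-noncoding class, so the surviving decoys mirror
#' the novel-class search space.
#'
#' @param psms PSM data.frame (`spectrum_id`, `peptide`, `score`,
#'   `is_decoy`, `matched_entry`, ...).
#' @param index a [known_peptide_index()].
#' @param db the `search_db` (used for decoy origin classes); may be NULL,
#'   in which case all non-known-tryptic decoys are kept.
#' @return list with `novel_targets`, `novel_decoys`, `discarded`.
#' @export
prefilter_for_fdr <- function(psms, index, db = NULL) {
  tg <- psms[!psms$is_decoy, , drop = FALSE]
  dc <- psms[psms$is_decoy, , drop = FALSE]
  keep_t <- rep(TRUE, nrow(tg))
  if (nrow(tg)) {
    cls <- classify_peptides(tg$peptide, index)
    keep_t <- cls == "novel"
  }
  keep_d <- rep(TRUE, nrow(dc))
  if (nrow(dc)) {
    keep_d <- !is_known_tryptic(dc$peptide, index)
    if (!is.null(db)) {
      origin <- db$entries$origin_class[match(dc$matched_entry,
                                              db$entries$entry_id)]
      keep_d <- keep_d & !is.na(origin) & origin == "noncoding"
    }
  }
  list(novel_targets = tg[keep_t, , drop = FALSE],
       novel_decoys = dc[keep_d, , drop = FALSE],
       discarded = rbind(tg[!keep_t, , drop = FALSE],
                         dc[!keep_d, , drop = FALSE]))
}

# Decoy-based q-values for a set of target scores. At each target score s,
# FDR(s) = #{decoys >= s} / #{targets >= s} (ties count the decoy, which is
# conservative), capped at 1; q(s) = min over thresholds <= s of FDR.
compute_qvalues <- function(target_scores, decoy_scores) {
  n <- length(target_scores)
  if (!n) return(numeric(0))
  ord <- order(target_scores, decreasing = TRUE)
  s <- target_scores[ord]
  n_ge_t <- seq_len(n)  # targets >= s within the sorted target list
  sd_sorted <- sort(decoy_scores)
  n_ge_d <- length(decoy_scores) -
    findInterval(s, sd_sorted, left.open = TRUE)
  fdr <- pmin(1, n_ge_d / n_ge_t)
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

#' Class-specific FDR for novel peptides
#'
#' Collapses PSMs to their best score per peptide (default) or works at PSM
#' level, computes decoy-based q-values within the novel class, and accepts
#' peptides with q-value at or below `alpha`.
#'
#' @param novel_targets,novel_decoys PSM data.frames from
#'   [prefilter_for_fdr()] (need `peptide` and `score`).
#' @param alpha acceptance threshold on the q-value, default 0.01.
#' @param level `"peptide"` (best PSM per peptide) or `"psm"`.
#' @return data.frame of verdicts: `peptide`, `class`, `best_score`,
#'   `q_value`, `supporting_psm_count`, `accepted`.
#' @export
class_specific_fdr <- function(novel_targets, novel_decoys, alpha = 0.01,
                               level = c("peptide", "psm")) {
  level <- match.arg(level)
  stopifnot(alpha > 0, alpha < 1)
  if (!nrow(novel_targets)) {
    return(data.frame(peptide = character(), class = character(),
                      best_score = numeric(), q_value = numeric(),
                      supporting_psm_count = integer(), accepted = logical(),
                      stringsAsFactors = FALSE))
  }
  if (level == "peptide") {
    t_best <- tapply(novel_targets$score, novel_targets$peptide, max)
    t_n <- tapply(novel_targets$score, novel_targets$peptide, length)
    d_best <- if (nrow(novel_decoys)) {
      as.numeric(tapply(novel_decoys$score, novel_decoys$peptide, max))
    } else {
      numeric(0)
    }
    peptides <- names(t_best)
    scores <- as.numeric(t_best)
    counts <- as.integer(t_n)
  } else {
    peptides <- novel_targets$peptide
    scores <- novel_targets$score
    counts <- rep(1L, length(scores))
    d_best <- novel_decoys$score
  }
  if (!length(d_best)) {
    warning("no decoys survive the prefilter; q-values are all zero")
  }
  q <- compute_qvalues(scores, d_best)
  out <- data.frame(peptide = peptides, class = "novel", best_score = scores,
                    q_value = q, supporting_psm_count = counts,
                    accepted = q <= alpha, stringsAsFactors = FALSE)
  out[order(-out$best_score), , drop = FALSE]
}

#' Global (class-agnostic) FDR over all target peptides
#'
#' The contrast to [class_specific_fdr()]: q-values computed over the whole
#' target list against the whole decoy list, with no class partitioning.
#' Used to demonstrate why class-specific estimation matters when an
#' abundant class scores systematically higher.
#'
#' @inheritParams class_specific_fdr
#' @param targets,decoys PSM data.frames (any classes).
#' @return verdict data.frame as in [class_specific_fdr()], minus `class`.
#' @export
global_fdr <- function(targets, decoys, alpha = 0.01,
                       level = c("peptide", "psm")) {
  level <- match.arg(level)
  res <- class_specific_fdr(targets, decoys, alpha = alpha, level = level)
  res$class <- NULL
  res
}
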