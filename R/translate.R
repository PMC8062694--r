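# Nucleotide translation and in-silico digestion.
#
# The three-frame translation of noncoding transcripts is the backbone of the
# search-database construction: every transcript is translated in frames
# 0/1/2 on its own (already strand-resolved) spliced sequence, split at stop
# codons, and segments long enough to yield detectable tryptic peptides are
# kept as database entries.

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

.pkg_cache <- new.env(parent = emptyenv())

get_codon_table <- function() {
  if (is.null(.pkg_cache$codon_table)) {
    .pkg_cache$codon_table <- codon_table()
  }
  .pkg_cache$codon_table
}

#' Translate one reading frame of a nucleotide sequence
#'
#' Codons containing `N` (or any non-ACGT symbol) translate to `X`; stop
#' codons translate to `*`. Trailing bases that do not fill a codon are
#' dropped.
#'
#' @param seq a single nucleotide string over `A,C,G,T,N`.
#' @param frame 0, 1 or 2: offset of the first codon.
#' @return a single amino-acid string (possibly empty).
#' @export
translate_frame <- function(seq, frame = 0L) {
  stopifnot(length(seq) == 1L, frame %in% 0:2)
  seq <- toupper(seq)
  n <- (nchar(seq) - frame) %/% 3L
  if (n <= 0L) return("")
  starts <- frame + 1L + 3L * (seq_len(n) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- get_codon_table()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Three-frame translation split at stop codons
#'
#' Translates `seq` in frames 0-2, splits each frame's translation at stop
#' codons, and keeps segments of at least `min_segment_len` residues. The
#' per-segment amino-acid offset within the frame translation (`aa_start`,
#' 1-based) is retained so that residues can later be mapped back to
#' transcript and genome coordinates.
#'
#' @param seq nucleotide string over `A,C,G,T,N`.
#' @param min_segment_len minimum segment length in residues (>= 1).
#' @return data.frame with columns `frame`, `segment_index`, `aa_start`,
#'   `protein`. Empty input yields zero rows.
#' @export
translate_three_frames <- function(seq, min_segment_len = 7L) {
  stopifnot(min_segment_len >= 1L)
  if (is.na(seq) || nchar(seq) == 0L) {
    return(data.frame(frame = integer(), segment_index = integer(),
                      aa_start = integer(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  out <- vector("list", 3L)
  for (f in 0:2) {
    aa <- translate_frame(seq, f)
    if (nchar(aa) == 0L) next
    m <- gregexpr("[^*]+", aa)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    keep <- lens >= min_segment_len
    if (!any(keep)) next
    segs <- substring(aa, starts[keep], starts[keep] + lens[keep] - 1L)
    out[[f + 1L]] <- data.frame(
      frame = f,
      segment_index = seq_len(sum(keep)),
      aa_start = starts[keep],
      protein = segs,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res)) {
    res <- data.frame(frame = integer(), segment_index = integer(),
                      aa_start = integer(), protein = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is P, and emits
#' every peptide carrying at most `missed_cleavages` internal cleavage
#' sites. Length filtering is left to the caller.
#'
#' @param protein amino-acid string.
#' @param missed_cleavages maximum internal missed cleavage sites (>= 0).
#' @return character vector of peptides ordered by start position, then span.
#' @export
digest_tryptic <- function(protein, missed_cleavages = 0L) {
  stopifnot(missed_cleavages >= 0L, length(protein) == 1L)
  n <- nchar(protein)
  if (n == 0L) return(character())
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites == n | aa[pmin(sites + 1L, n)] != "P"]
  bounds <- unique(c(0L, sites, n))       # peptide i spans (bounds[i], bounds[i+1]]
  k <- length(bounds) - 1L
  peps <- character(0)
  for (i in seq_len(k)) {
    for (mc in 0:missed_cleavages) {
      j <- i + mc
      if (j > k) break
      peps <- c(peps, substr(protein, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  peps
}
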