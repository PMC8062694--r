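# Orthogonal RNA-seq evidence: count aligned reads supporting each novel
# peptide's genomic region. Desk-scale SAM text is parsed directly into
# the minimal alignment record the counting rule needs (position, CIGAR
# reference span, NM edit distance).

cigar_ref_span <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1L]]
  if (m[1L] == -1L) return(NA_integer_)
  ops <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1L]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^\\d+", "", ops)
  if (sum(nchar(ops)) != nchar(cigar)) return(NA_integer_)
  span <- sum(lens[op %in% c("M", "D", "N", "=", "X")])
  if (span < 1L) NA_integer_ else span
}

#' Parse SAM text into an alignment table
#'
#' Reads the 11 mandatory fields plus the `NM` edit-distance tag. Records
#' with a malformed CIGAR are skipped with a warning count; a missing
#' `NM` tag is recorded as NA.
#'
#' @param sam character vector of SAM lines, or a path to a SAM file.
#' @return data.frame: `read_id`, `chrom`, `pos`, `cigar`, `ref_span`,
#'   `edit_distance`.
#' @export
parse_sam <- function(sam) {
  if (length(sam) == 1L && file.exists(sam)) sam <- readLines(sam)
  body <- sam[!startsWith(sam, "@") & nzchar(sam)]
  if (!length(body)) {
    return(data.frame(read_id = character(), chrom = character(),
                      pos = integer(), cigar = character(),
                      ref_span = integer(), edit_distance = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1L)) >= 11L
  if (any(!ok)) warning(sum(!ok), " malformed SAM record(s) skipped")
  fields <- fields[ok]
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1L])) else NA_integer_
  }, integer(1L))
  out <- data.frame(
    read_id = vapply(fields, `[[`, character(1L), 1L),
    chrom = vapply(fields, `[[`, character(1L), 3L),
    pos = as.integer(vapply(fields, `[[`, character(1L), 4L)),
    cigar = vapply(fields, `[[`, character(1L), 6L),
    edit_distance = nm, stringsAsFactors = FALSE)
  out$ref_span <- vapply(out$cigar, cigar_ref_span, integer(1L),
                         USE.NAMES = FALSE)
  bad <- is.na(out$ref_span)
  if (any(bad)) warning(sum(bad), " record(s) with malformed CIGAR skipped")
  out[!bad, , drop = FALSE]
}

#' Count reads supporting each peptide placement
#'
#' A read counts toward a placement if its reference span overlaps any of
#' the placement's blocks by at least `min_overlap` bases and its edit
#' distance is at most `max_mismatch`. Each read counts at most once per
#' placement. Reads lacking an edit-distance tag fail the mismatch filter
#' unless `missing_nm_as_zero` is set.
#'
#' @param locations peptide location data.frame (e.g. from
#'   [read_peptide_gff3()]).
#' @param sam SAM lines/path, a parsed alignment data.frame, or a named
#'   list of them (one per sample).
#' @param min_overlap minimum overlap in bases (default 1).
#' @param max_mismatch maximum edit distance (default 1).
#' @param require_all_blocks if TRUE a read must overlap every block of a
#'   junction-spanning placement; default FALSE (any block suffices).
#' @param missing_nm_as_zero treat a missing NM tag as edit distance 0.
#' @return data.frame: `placement_id`, `sample_id`, `read_count`.
#' @export
count_supporting_reads <- function(locations, sam, min_overlap = 1L,
                                   max_mismatch = 1L,
                                   require_all_blocks = FALSE,
                                   missing_nm_as_zero = FALSE) {
  if (!is.list(sam) || is.data.frame(sam) || is.character(sam)) {
    sam <- list(sample1 = sam)
  }
  out <- lapply(names(sam), function(sname) {
    aln <- sam[[sname]]
    if (!is.data.frame(aln)) aln <- parse_sam(aln)
    nm <- aln$edit_distance
    if (missing_nm_as_zero) nm[is.na(nm)] <- 0L
    aln <- aln[!is.na(nm) & nm <= max_mismatch, , drop = FALSE]
    counts <- vapply(seq_len(nrow(locations)), function(i) {
      b <- locations$blocks[[i]]
      on_chrom <- aln$chrom == locations$chrom[i]
      if (!any(on_chrom)) return(0L)
      a <- aln[on_chrom, , drop = FALSE]
      a_end <- a$pos + a$ref_span - 1L
      hit_block <- vapply(seq_len(nrow(b)), function(j) {
        ov <- pmin(a_end, b$end[j]) - pmax(a$pos, b$start[j]) + 1L
        ov >= min_overlap
      }, logical(nrow(a)))
      hit_block <- matrix(hit_block, nrow = nrow(a))
      hits <- if (require_all_blocks) {
        apply(hit_block, 1L, all)
      } else {
        apply(hit_block, 1L, any)
      }
      sum(hits)
    }, integer(1L))
    data.frame(placement_id = locations$placement_id, sample_id = sname,
               read_count = counts, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
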