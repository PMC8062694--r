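# Search-database construction: known proteins, missense variant entries,
# three-frame translations of noncoding transcripts, and reversed decoys.

#' Missense mutation specification
#'
#' @param protein_id identifier of the reference protein.
#' @param position 1-based residue index.
#' @param ref_aa,alt_aa reference and alternate amino acids (must differ).
#' @return a `mutation_spec` object.
#' @export
mutation_spec <- function(protein_id, position, ref_aa, alt_aa) {
  if (ref_aa == alt_aa) {
    stop("ref_aa equals alt_aa at position ", position, "; not a mutation")
  }
  structure(list(protein_id = protein_id, position = as.integer(position),
                 ref_aa = ref_aa, alt_aa = alt_aa), class = "mutation_spec")
}

#' Apply a missense mutation to a protein sequence
#'
#' @param protein amino-acid string.
#' @param m a [mutation_spec()].
#' @return the mutated sequence (same length).
#' @export
apply_mutation <- function(protein, m) {
  stopifnot(inherits(m, "mutation_spec"))
  if (m$position < 1L || m$position > nchar(protein)) {
    stop("mutation position ", m$position, " outside protein of length ",
         nchar(protein))
  }
  ref <- substr(protein, m$position, m$position)
  if (ref != m$ref_aa) {
    stop("reference mismatch at position ", m$position, ": expected ",
         m$ref_aa, ", found ", ref)
  }
  paste0(substr(protein, 1L, m$position - 1L), m$alt_aa,
         substr(protein, m$position + 1L, nchar(protein)))
}

# Three-frame translation entries for all noncoding transcripts of a world.
# locus_id is the noncoding gene (or the repeat family for repeat copies).
noncoding_entries <- function(world, min_segment_len = 7L) {
  ncs <- Filter(function(tx) tx$biotype != "protein_coding",
                world$transcripts)
  rows <- lapply(ncs, function(tx) {
    segs <- translate_three_frames(tx$spliced, min_segment_len)
    if (!nrow(segs)) return(NULL)
    data.frame(
      entry_id = sprintf("%s:F%d:S%d", tx$id, segs$frame, segs$segment_index),
      class = "noncoding", origin_class = "noncoding",
      source = tx$id, frame = segs$frame, segment_index = segs$segment_index,
      aa_start = segs$aa_start, protein = segs$protein,
      locus_id = if (!is.na(tx$family)) tx$family else tx$gene_id,
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) {
    return(data.frame(entry_id = character(), class = character(),
                      origin_class = character(), source = character(),
                      frame = integer(), segment_index = integer(),
                      aa_start = integer(), protein = character(),
                      locus_id = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate reversed-sequence decoys
#'
#' Each target protein is reversed end-to-end; decoy IDs get a `decoy_`
#' prefix and the original class is recorded so decoys can later be
#' partitioned by class for class-specific FDR. Palindromic sequences
#' (identical when reversed) are flagged with a warning.
#'
#' @param entries entry data.frame with `entry_id`, `class`, `protein`.
#' @return same-shaped data.frame of decoys.
#' @export
make_decoys <- function(entries) {
  dec <- entries
  dec$protein <- str_rev(entries$protein)
  pal <- dec$protein == entries$protein
  if (any(pal)) {
    warning(sum(pal), " palindromic sequence(s) unchanged by reversal: ",
            paste(utils::head(entries$entry_id[pal], 5L), collapse = ", "))
  }
  dec$entry_id <- paste0("decoy_", entries$entry_id)
  dec$origin_class <- entries$class
  dec$class <- "decoy"
  dec
}

#' Build the combined target + decoy search database
#'
#' Assembles known proteins, missense variant entries, and three-frame
#' translations of every noncoding transcript, then appends
#' reversed-sequence decoys generated from the full target set.
#'
#' @param world a [generate_world()] object (or any list with
#'   `known_proteome`, `transcripts`).
#' @param mutations data.frame of missense specs (`protein_id`, `position`,
#'   `ref_aa`, `alt_aa`); defaults to the world's own.
#' @param min_segment_len minimum translated segment length kept (residues).
#' @return object of class `search_db`: list with `entries` (data.frame) and
#'   `transcripts`.
#' @export
build_search_db <- function(world, mutations = world$mutations,
                            min_segment_len = world$config$min_segment_len) {
  if (is.null(min_segment_len)) min_segment_len <- 7L
  known <- data.frame(
    entry_id = names(world$known_proteome), class = "known",
    origin_class = "known", source = names(world$known_proteome),
    frame = NA_integer_, segment_index = NA_integer_, aa_start = NA_integer_,
    protein = unname(world$known_proteome), locus_id = NA_character_,
    stringsAsFactors = FALSE)
  var <- if (!is.null(mutations) && nrow(mutations)) {
    prot <- vapply(seq_len(nrow(mutations)), function(i) {
      apply_mutation(world$known_proteome[[mutations$protein_id[i]]],
                     mutation_spec(mutations$protein_id[i],
                                   mutations$position[i],
                                   mutations$ref_aa[i], mutations$alt_aa[i]))
    }, character(1L))
    data.frame(
      entry_id = sprintf("VAR_%s_%s%d%s", mutations$protein_id,
                         mutations$ref_aa, mutations$position,
                         mutations$alt_aa),
      class = "variant", origin_class = "variant",
      source = mutations$protein_id, frame = NA_integer_,
      segment_index = NA_integer_, aa_start = NA_integer_, protein = prot,
      locus_id = NA_character_, stringsAsFactors = FALSE)
  } else {
    known[0L, ]
  }
  nc <- noncoding_entries(world, min_segment_len)
  targets <- rbind(known, var, nc)
  if (anyDuplicated(targets$entry_id)) {
    stop("duplicate entry IDs in target database: ",
         paste(unique(targets$entry_id[duplicated(targets$entry_id)]),
               collapse = ", "))
  }
  entries <- rbind(targets, suppressWarnings(make_decoys(targets)))
  rownames(entries) <- NULL
  structure(list(entries = entries, transcripts = world$transcripts),
            class = "search_db")
}

#' @export
print.search_db <- function(x, ...) {
  tab <- table(x$entries$class)
  cat("search_db:", nrow(x$entries), "entries (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Write a search database as FASTA plus a TSV index
#'
#' FASTA headers follow the grammar `class|entry_id|source|frame|segment`;
#' the sidecar index carries entry metadata (including the segment's
#' amino-acid offset needed for genomic mapping).
#'
#' @param db a [build_search_db()] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_search_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- db$entries
  hdr <- sprintf("%s|%s|%s|%s|%s", e$class, e$entry_id, e$source,
                 ifelse(is.na(e$frame), ".", e$frame),
                 ifelse(is.na(e$segment_index), ".", e$segment_index))
  aa <- Biostrings::AAStringSet(setNames(e$protein, hdr))
  Biostrings::writeXStringSet(aa, file.path(dir, "search_db.fasta"))
  write.table(e, file.path(dir, "search_db_index.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a search database written by [write_search_db()]
#'
#' @param dir directory containing `search_db.fasta` and
#'   `search_db_index.tsv`.
#' @param transcripts optional transcript list to reattach (needed for
#'   genomic mapping).
#' @return a `search_db` object.
#' @export
read_search_db <- function(dir, transcripts = NULL) {
  idx <- read.delim(file.path(dir, "search_db_index.tsv"),
                    stringsAsFactors = FALSE)
  fa <- Biostrings::readAAStringSet(file.path(dir, "search_db.fasta"))
  parts <- strsplit(names(fa), "|", fixed = TRUE)
  fasta_ids <- vapply(parts, `[[`, character(1L), 2L)
  if (!identical(fasta_ids, idx$entry_id) ||
      !identical(unname(as.character(fa)), idx$protein)) {
    stop("FASTA and index are inconsistent")
  }
  idx$locus_id <- as.character(idx$locus_id)
  structure(list(entries = idx, transcripts = transcripts),
            class = "search_db")
}
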