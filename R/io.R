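# Plain-text interchange: genome/proteome FASTA, annotation and peptide
# GFF3 (1-based inclusive), BED export (0-based half-open), and TSV tables.
# Writing uses simple controlled formatting; reading standard formats goes
# through Biostrings / rtracklayer.

gff3_attr <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, function(v) is.na(v) || !nzchar(as.character(v)),
                   logical(1L))]
  paste(sprintf("%s=%s", names(kv), unlist(kv)), collapse = ";")
}

#' Write the world annotation as GFF3
#'
#' @param annotation feature data.frame from [generate_world()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  a <- annotation
  lines <- c("##gff-version 3",
             vapply(seq_len(nrow(a)), function(i) {
               paste(a$seqid[i], a$source[i], a$type[i], a$start[i],
                     a$end[i], ".", a$strand[i],
                     ifelse(is.na(a$phase[i]), ".", a$phase[i]),
                     gff3_attr(ID = a$ID[i], gene_id = a$gene_id[i],
                               biotype = a$biotype[i],
                               parent_gene = a$parent_gene[i],
                               family = a$family[i]),
                     sep = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an annotation GFF3 back into the internal feature table
#'
#' @param path GFF3 file written by [write_annotation_gff3()].
#' @return feature data.frame.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  grab <- function(col) {
    if (col %in% colnames(md)) as.character(md[[col]]) else
      rep(NA_character_, length(gr))
  }
  phase <- if ("phase" %in% colnames(md)) {
    suppressWarnings(as.integer(as.character(md$phase)))
  } else {
    rep(NA_integer_, length(gr))
  }
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             source = grab("source"),
             type = as.character(md$type),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             ID = grab("ID"), gene_id = grab("gene_id"),
             biotype = grab("biotype"), parent_gene = grab("parent_gene"),
             family = grab("family"), phase = phase,
             stringsAsFactors = FALSE)
}

#' Write peptide placements as GFF3
#'
#' One feature line per genomic block; the blocks of one placement share a
#' `Parent` attribute so junction-spanning peptides stay grouped.
#'
#' @param locations location data.frame (from [map_peptide()] /
#'   [annotate_peptides()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peptide_gff3 <- function(locations, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(locations))) {
    b <- locations$blocks[[i]]
    lines <- c(lines, vapply(seq_len(nrow(b)), function(j) {
      paste(locations$chrom[i], "darkpep", "peptide_block", b$start[j],
            b$end[j], ".", locations$strand[i], ".",
            gff3_attr(ID = sprintf("%s.b%d", locations$placement_id[i], j),
                      Parent = locations$placement_id[i],
                      peptide = locations$peptide[i],
                      frame = locations$frame[i]),
            sep = "\t")
    }, character(1L)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a peptide GFF3 back into a location table
#'
#' @param path GFF3 written by [write_peptide_gff3()].
#' @return location data.frame with `blocks` list-column (columns as in
#'   [map_peptide()] minus database provenance).
#' @export
read_peptide_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) return(empty_locations())
  md <- S4Vectors::mcols(gr)
  parent <- vapply(md$Parent, function(p) as.character(p)[1L], character(1L))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   peptide = as.character(md$peptide),
                   frame = suppressWarnings(as.integer(
                     as.character(md$frame))),
                   placement_id = parent, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, df$placement_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    data.frame(placement_id = d$placement_id[1L], peptide = d$peptide[1L],
               chrom = d$chrom[1L], strand = d$strand[1L],
               frame = d$frame[1L], source_entry = NA_character_,
               gene_id = NA_character_, biotype = NA_character_,
               family = NA_character_, start = min(d$start),
               end = max(d$end),
               blocks = I(list(data.frame(start = d$start, end = d$end))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export peptide blocks as BED
#'
#' Standard 6-column BED (0-based half-open), one row per block.
#'
#' @param locations location data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peptide_bed <- function(locations, path) {
  rows <- character(0)
  for (i in seq_len(nrow(locations))) {
    b <- locations$blocks[[i]]
    rows <- c(rows, sprintf("%s\t%d\t%d\t%s\t0\t%s", locations$chrom[i],
                            b$start - 1L, b$end, locations$placement_id[i],
                            locations$strand[i]))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Write the synthetic world to a directory of standard text formats
#'
#' Genome FASTA, annotation GFF3, known-proteome FASTA, missense variant
#' TSV, and the ground-truth novel-peptide TSV.
#'
#' @param world a [generate_world()] object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(world$genome),
                              file.path(dir, "genome.fasta"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(world$known_proteome),
                              file.path(dir, "known_proteome.fasta"))
  write_annotation_gff3(world$annotation, file.path(dir, "annotation.gff3"))
  write_tsv(world$mutations, file.path(dir, "mutations.tsv"))
  write_tsv(world$truth$novel_peptides,
            file.path(dir, "truth_novel_peptides.tsv"))
  invisible(dir)
}

#' Write/read a plain TSV table
#'
#' @param df data.frame (list-columns are not supported).
#' @param path file path.
#' @return `path` (write) or data.frame (read).
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
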