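# Genomic mapping of accepted novel peptides, origin-category assignment
# with pseudogene-first precedence, and grouping into novel coding loci.
#
# Coordinates are 1-based inclusive externally (GFF3 convention); interval
# work is delegated to GenomicRanges/IRanges.

#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

# placement keys avoid , ; = % which are reserved in GFF3 attributes
blocks_key <- function(blocks) {
  paste(sprintf("%d-%d", blocks$start, blocks$end), collapse = "_")
}

#' Map a peptide to genomic coordinates
#'
#' Finds every placement of `peptide` (under I/L equivalence) in any
#' noncoding translated entry and converts the matched residues to genomic
#' blocks through the source transcript's exon structure. Junction-spanning
#' peptides yield multiple blocks; peptides present in several genomic
#' copies (repeat families) yield one placement per copy.
#'
#' @param peptide amino-acid string.
#' @param db a `search_db` with `transcripts` attached.
#' @return data.frame of peptide locations (`placement_id`, `peptide`,
#'   `chrom`, `strand`, `frame`, `source_entry`, `gene_id`, `biotype`,
#'   `family`, `start`, `end`) with a `blocks` list-column of
#'   `data.frame(start, end)`. Zero rows (with a warning) if unplaceable.
#' @export
map_peptide <- function(peptide, db) {
  stopifnot(nzchar(peptide))
  ent <- db$entries[db$entries$class == "noncoding", , drop = FALSE]
  cp <- il_collapse(peptide)
  rows <- list()
  for (i in seq_len(nrow(ent))) {
    hits <- gregexpr(cp, il_collapse(ent$protein[i]), fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    tx <- db$transcripts[[ent$source[i]]]
    if (is.null(tx)) next
    gpos <- tx_positions(tx)
    L <- nchar(peptide)
    for (o in as.integer(hits)) {
      nt_start <- ent$frame[i] + 3L * (ent$aa_start[i] + o - 2L) + 1L
      idx <- nt_start:(nt_start + 3L * L - 1L)
      pos <- gpos[idx]
      step <- if (tx$strand == "+") 1L else -1L
      run <- cumsum(c(1L, diff(pos) != step))
      blocks <- do.call(rbind, lapply(split(pos, run), function(p) {
        data.frame(start = min(p), end = max(p))
      }))
      blocks <- blocks[order(blocks$start), , drop = FALSE]
      rownames(blocks) <- NULL
      rows[[length(rows) + 1L]] <- data.frame(
        placement_id = sprintf("%s@%s%s:%s", peptide, tx$chrom, tx$strand,
                               blocks_key(blocks)),
        peptide = peptide, chrom = tx$chrom, strand = tx$strand,
        frame = ent$frame[i], source_entry = ent$entry_id[i],
        gene_id = tx$gene_id, biotype = tx$biotype,
        family = if (is.null(tx$family)) NA_character_ else tx$family,
        start = min(blocks$start), end = max(blocks$end),
        blocks = I(list(blocks)), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("peptide ", peptide, " not found in any noncoding entry")
    return(empty_locations())
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$placement_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_locations <- function() {
  data.frame(placement_id = character(), peptide = character(),
             chrom = character(), strand = character(), frame = integer(),
             source_entry = character(), gene_id = character(),
             biotype = character(), family = character(),
             start = integer(), end = integer(),
             blocks = I(list()), stringsAsFactors = FALSE)
}

#' Re-translate a peptide location from the genome
#'
#' Extracts the genomic blocks (strand-aware), concatenates them in
#' transcription order and translates them; the result must reproduce the
#' peptide exactly for a valid location.
#'
#' @param loc one row of a location data.frame.
#' @param genome named character vector of chromosome sequences.
#' @return the translated amino-acid string.
#' @export
retranslate_location <- function(loc, genome) {
  blocks <- loc$blocks[[1L]]
  chrom_seq <- genome[[loc$chrom]]
  segs <- substring(chrom_seq, blocks$start, blocks$end)
  nt <- if (loc$strand == "+") {
    paste(segs, collapse = "")
  } else {
    paste(rev(vapply(segs, revcomp, character(1L))), collapse = "")
  }
  translate_frame(nt, 0L)
}

# ---- annotation index and category assignment ------------------------------

granges_of <- function(df) {
  GRanges(df$seqid, IRanges(df$start, df$end),
          strand = ifelse(is.na(df$strand), "*", df$strand))
}

#' Build the interval index used for category assignment
#'
#' Derives introns from coding-gene exons and precomputes upstream and
#' downstream windows (1 kb beyond the outermost UTR boundary of each
#' coding gene), plus codon-frame anchors for CDS pieces.
#'
#' @param annotation feature data.frame as produced by [generate_world()].
#' @return an `annotation_index` object.
#' @export
index_annotation <- function(annotation) {
  a <- annotation
  pick <- function(types, biotype = NULL) {
    sel <- a$type %in% types
    if (!is.null(biotype)) sel <- sel & !is.na(a$biotype) &
        a$biotype == biotype
    a[sel, , drop = FALSE]
  }
  cds <- pick("CDS")
  cds_anchor <- integer(nrow(cds))
  if (nrow(cds)) {
    ph <- ifelse(is.na(cds$phase), 0L, cds$phase)
    plus <- cds$strand == "+"
    cds_anchor[plus] <- (cds$start[plus] + (3L - ph[plus]) %% 3L) %% 3L
    cds_anchor[!plus] <- (cds$end[!plus] - (3L - ph[!plus]) %% 3L) %% 3L
  }
  coding_exons <- pick("exon", "protein_coding")
  introns <- NULL
  if (nrow(coding_exons)) {
    introns <- do.call(rbind, lapply(split(coding_exons,
                                           coding_exons$gene_id),
                                     function(e) {
      e <- e[order(e$start), , drop = FALSE]
      if (nrow(e) < 2L) return(NULL)
      data.frame(seqid = e$seqid[-1L], strand = e$strand[-1L],
                 start = e$end[-nrow(e)] + 1L, end = e$start[-1L] - 1L,
                 gene_id = e$gene_id[-1L], stringsAsFactors = FALSE)
    }))
  }
  if (is.null(introns)) {
    introns <- data.frame(seqid = character(), strand = character(),
                          start = integer(), end = integer(),
                          gene_id = character())
  }
  genes <- pick("gene", "protein_coding")
  upstream <- downstream <- genes[0L, c("seqid", "strand", "start", "end",
                                        "gene_id")]
  if (nrow(genes)) {
    plus <- genes$strand == "+"
    upstream <- data.frame(
      seqid = genes$seqid, strand = genes$strand,
      start = ifelse(plus, pmax(1L, genes$start - 1000L), genes$end + 1L),
      end = ifelse(plus, genes$start - 1L, genes$end + 1000L),
      gene_id = genes$gene_id, stringsAsFactors = FALSE)
    downstream <- data.frame(
      seqid = genes$seqid, strand = genes$strand,
      start = ifelse(plus, genes$end + 1L, pmax(1L, genes$start - 1000L)),
      end = ifelse(plus, genes$end + 1000L, genes$start - 1L),
      gene_id = genes$gene_id, stringsAsFactors = FALSE)
  }
  structure(list(
    pseudogene = pick("pseudogene"),
    lncrna = pick("lncRNA"),
    repeats = pick("repeat_region"),
    utr = pick(c("five_prime_UTR", "three_prime_UTR")),
    cds = cbind(cds, codon_anchor = cds_anchor),
    coding_exons = coding_exons,
    introns = introns,
    genes = genes,
    upstream = upstream,
    downstream = downstream), class = "annotation_index")
}

overlap_rows <- function(blocks, chrom, feat) {
  if (!nrow(feat)) return(integer(0))
  sel <- which(feat$seqid == chrom)
  if (!length(sel)) return(integer(0))
  f <- feat[sel, , drop = FALSE]
  hit <- vapply(seq_len(nrow(f)), function(i) {
    any(blocks$start <= f$end[i] & blocks$end >= f$start[i])
  }, logical(1L))
  sel[hit]
}

location_frame_anchor <- function(loc) {
  blocks <- loc$blocks[[1L]]
  if (loc$strand == "+") min(blocks$start) %% 3L else max(blocks$end) %% 3L
}

#' Assign an origin category to a peptide location
#'
#' Applies the fixed precedence pseudogene > lncRNA > retroelement > UTR >
#' exonic (alternative frame) > intron-exon boundary > intronic > upstream >
#' downstream > intergenic, with a minimum overlap of 1 bp against any
#' block. Upstream/downstream require the location to fall within 1 kb of
#' the nearest UTR boundary of a coding gene. CDS overlap in the annotated
#' frame (same strand, same codon anchor) is not called exonic and falls
#' through to the remaining categories.
#'
#' @param loc one row of a location data.frame.
#' @param index an [index_annotation()] object.
#' @return data.frame with `category` and `host_id` (the noncoding gene,
#'   repeat family, host coding gene, or NA for intergenic).
#' @export
assign_category <- function(loc, index) {
  blocks <- loc$blocks[[1L]]
  chrom <- loc$chrom
  res <- function(category, host) data.frame(category = category,
                                             host_id = host,
                                             stringsAsFactors = FALSE)
  h <- overlap_rows(blocks, chrom, index$pseudogene)
  if (length(h)) return(res("pseudogene", index$pseudogene$gene_id[h[1L]]))
  h <- overlap_rows(blocks, chrom, index$lncrna)
  if (length(h)) return(res("lncRNA", index$lncrna$gene_id[h[1L]]))
  h <- overlap_rows(blocks, chrom, index$repeats)
  if (length(h)) return(res("retroelement", index$repeats$family[h[1L]]))
  h <- overlap_rows(blocks, chrom, index$utr)
  if (length(h)) return(res("utr", index$utr$gene_id[h[1L]]))
  h <- overlap_rows(blocks, chrom, index$cds)
  if (length(h)) {
    anchor <- location_frame_anchor(loc)
    altframe <- index$cds$strand[h] != loc$strand |
      index$cds$codon_anchor[h] != anchor
    if (any(altframe)) {
      return(res("exonic_altframe", index$cds$gene_id[h[altframe][1L]]))
    }
  }
  he <- overlap_rows(blocks, chrom, index$coding_exons)
  hi <- overlap_rows(blocks, chrom, index$introns)
  shared <- intersect(index$coding_exons$gene_id[he],
                      index$introns$gene_id[hi])
  if (length(shared)) return(res("intron_exon_boundary", shared[1L]))
  if (length(hi)) return(res("intronic", index$introns$gene_id[hi[1L]]))
  h <- overlap_rows(blocks, chrom, index$upstream)
  if (length(h)) return(res("upstream", index$upstream$gene_id[h[1L]]))
  h <- overlap_rows(blocks, chrom, index$downstream)
  if (length(h)) return(res("downstream", index$downstream$gene_id[h[1L]]))
  res("intergenic", NA_character_)
}

#' Map and categorize a set of accepted peptides
#'
#' Runs [map_peptide()] and [assign_category()] over all peptides, then
#' applies the multi-mapping rule: a peptide whose placements all fall in
#' annotated repeat intervals is kept as a single retroelement assignment
#' for its repeat family instead of being discarded.
#'
#' @param peptides character vector of accepted novel peptides.
#' @param db a `search_db` with transcripts.
#' @param annotation feature data.frame (or an `annotation_index`).
#' @return data.frame of assignments: one row per retained (peptide,
#'   placement) with `category` and `host_id`, carrying the location
#'   columns.
#' @export
annotate_peptides <- function(peptides, db, annotation) {
  index <- if (inherits(annotation, "annotation_index")) annotation else
    index_annotation(annotation)
  locs <- do.call(rbind, lapply(unique(peptides), function(p) {
    suppressWarnings(map_peptide(p, db))
  }))
  if (is.null(locs) || !nrow(locs)) {
    out <- empty_locations()
    out$category <- character(0)
    out$host_id <- character(0)
    return(out)
  }
  cats <- do.call(rbind, lapply(seq_len(nrow(locs)), function(i) {
    assign_category(locs[i, , drop = FALSE], index)
  }))
  locs$category <- cats$category
  locs$host_id <- cats$host_id
  # collapse multi-mapped all-retroelement peptides to one family assignment
  keep <- rep(TRUE, nrow(locs))
  for (p in unique(locs$peptide)) {
    ii <- which(locs$peptide == p)
    if (length(ii) > 1L && all(locs$category[ii] == "retroelement") &&
        length(unique(locs$host_id[ii])) == 1L) {
      keep[ii[-1L]] <- FALSE
    }
  }
  out <- locs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group categorized peptide placements into novel coding loci
#'
#' Pseudogene, lncRNA and retroelement assignments group by their noncoding
#' gene / repeat family; host-gene categories (UTR, alternative-frame
#' exonic, intronic, boundary, upstream, downstream) group by (host coding
#' gene, category); intergenic placements are clustered by single linkage
#' within `intergenic_window` bases on the same chromosome and strand.
#'
#' @param assignments output of [annotate_peptides()].
#' @param intergenic_window clustering window in bases (default 10000).
#' @return data.frame of loci: `locus_id`, `category`, `n_unique_peptides`,
#'   `parent_gene_class`, with `unique_peptides` and `placements`
#'   list-columns.
#' @export
group_into_loci <- function(assignments, intergenic_window = 10000L) {
  a <- assignments
  if (!nrow(a)) {
    return(data.frame(locus_id = character(), category = character(),
                      n_unique_peptides = integer(),
                      parent_gene_class = character(),
                      unique_peptides = I(list()), placements = I(list()),
                      stringsAsFactors = FALSE))
  }
  gene_keyed <- a$category %in% c("pseudogene", "lncRNA", "retroelement")
  host_keyed <- a$category %in% c("utr", "exonic_altframe",
                                  "intron_exon_boundary", "intronic",
                                  "upstream", "downstream")
  key <- character(nrow(a))
  key[gene_keyed] <- a$host_id[gene_keyed]
  key[host_keyed] <- paste(a$host_id[host_keyed], a$category[host_keyed],
                           sep = ":")
  ig <- which(a$category == "intergenic")
  if (length(ig)) {
    for (grp in split(ig, paste(a$chrom[ig], a$strand[ig]))) {
      ord <- grp[order(a$start[grp])]
      cl <- cumsum(c(1L, diff(a$start[ord]) > intergenic_window))
      key[ord] <- sprintf("IG:%s%s:%d", a$chrom[ord], a$strand[ord], cl)
    }
  }
  loci <- lapply(split(seq_len(nrow(a)), key), function(ii) {
    data.frame(locus_id = key[ii[1L]], category = a$category[ii[1L]],
               n_unique_peptides = length(unique(a$peptide[ii])),
               parent_gene_class = NA_character_,
               unique_peptides = I(list(sort(unique(a$peptide[ii])))),
               placements = I(list(a$placement_id[ii])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' Retain loci supported by at least k unique peptides
#'
#' @param loci locus data.frame from [group_into_loci()].
#' @param k minimum unique-peptide support (default 2).
#' @return filtered locus data.frame.
#' @export
filter_min_unique_peptides <- function(loci, k = 2L) {
  out <- loci[loci$n_unique_peptides >= k, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tag pseudogene loci with their parental gene's function class
#'
#' @param loci locus data.frame.
#' @param lookup named character vector: pseudogene gene ID -> function
#'   class (e.g. "ribosomal protein"). Missing keys tag as "unannotated".
#' @return loci with `parent_gene_class` filled for pseudogene loci.
#' @export
tag_parent_class <- function(loci, lookup) {
  sel <- loci$category == "pseudogene"
  cls <- lookup[loci$locus_id[sel]]
  cls[is.na(cls)] <- "unannotated"
  loci$parent_gene_class[sel] <- unname(cls)
  loci
}
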