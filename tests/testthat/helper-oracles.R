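# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take different code paths: Biostrings translation,
# exhaustive threshold enumeration, naive per-feature overlap loops, and
# plain counting.

# Three-frame translation via Biostrings, splitting at stops by hand.
oracle_three_frames <- function(seq, min_len) {
  out <- list()
  for (f in 0:2) {
    n <- (nchar(seq) - f) %/% 3L
    if (n <= 0L) next
    sub <- substr(seq, f + 1L, f + 3L * n)
    aa <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "X",
      no.init.codon = TRUE)))
    segs <- strsplit(aa, "*", fixed = TRUE)[[1L]]
    pos <- 1L
    si <- 0L
    for (s in segs) {
      if (nchar(s) >= min_len) {
        si <- si + 1L
        out[[length(out) + 1L]] <- data.frame(
          frame = f, protein = s, stringsAsFactors = FALSE)
      }
      pos <- pos + nchar(s) + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(frame = integer(), protein = character()))
  }
  do.call(rbind, out)
}

# Exhaustive q-value oracle: for every target score, minimize FDR over all
# thresholds at or below it.
oracle_qvalues <- function(target_scores, decoy_scores) {
  fdr <- vapply(target_scores, function(t) {
    min(1, sum(decoy_scores >= t) / sum(target_scores >= t))
  }, numeric(1L))
  vapply(target_scores, function(s) {
    min(fdr[target_scores <= s])
  }, numeric(1L))
}

oracle_percent_rank <- function(scores, background) {
  vapply(scores, function(s) {
    100 * sum(background >= s) / length(background)
  }, numeric(1L))
}

# Naive category oracle: per-feature loops, own intron/flank derivation,
# same precedence list and frame-anchor definition.
oracle_category <- function(loc, ann) {
  b <- loc$blocks[[1L]]
  hits <- function(rows) {
    if (!nrow(rows)) return(FALSE)
    any(vapply(seq_len(nrow(rows)), function(i) {
      rows$seqid[i] == loc$chrom &&
        any(b$start <= rows$end[i] & b$end >= rows$start[i])
    }, logical(1L)))
  }
  if (hits(ann[ann$type == "pseudogene", ])) return("pseudogene")
  if (hits(ann[ann$type == "lncRNA", ])) return("lncRNA")
  if (hits(ann[ann$type == "repeat_region", ])) return("retroelement")
  if (hits(ann[ann$type %in% c("five_prime_UTR", "three_prime_UTR"), ])) {
    return("utr")
  }
  cds <- ann[ann$type == "CDS", ]
  loc_anchor <- if (loc$strand == "+") min(b$start) %% 3L else
    max(b$end) %% 3L
  for (i in seq_len(nrow(cds))) {
    if (cds$seqid[i] != loc$chrom) next
    if (!any(b$start <= cds$end[i] & b$end >= cds$start[i])) next
    ph <- if (is.na(cds$phase[i])) 0L else cds$phase[i]
    anchor <- if (cds$strand[i] == "+") {
      (cds$start[i] + (3L - ph) %% 3L) %% 3L
    } else {
      (cds$end[i] - (3L - ph) %% 3L) %% 3L
    }
    if (cds$strand[i] != loc$strand || anchor != loc_anchor) {
      return("exonic_altframe")
    }
  }
  coding <- unique(ann$gene_id[ann$type == "gene" & !is.na(ann$biotype) &
                                 ann$biotype == "protein_coding"])
  exon_genes <- intron_genes <- character(0)
  for (g in coding) {
    ex <- ann[ann$type == "exon" & ann$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    if (hits(ex)) exon_genes <- c(exon_genes, g)
    if (nrow(ex) >= 2L) {
      intr <- data.frame(seqid = ex$seqid[-1L],
                         start = ex$end[-nrow(ex)] + 1L,
                         end = ex$start[-1L] - 1L)
      if (hits(intr)) intron_genes <- c(intron_genes, g)
    }
  }
  if (length(intersect(exon_genes, intron_genes))) {
    return("intron_exon_boundary")
  }
  if (length(intron_genes)) return("intronic")
  genes <- ann[ann$type == "gene" & !is.na(ann$biotype) &
                 ann$biotype == "protein_coding", ]
  for (i in seq_len(nrow(genes))) {
    up <- if (genes$strand[i] == "+") {
      data.frame(seqid = genes$seqid[i],
                 start = max(1L, genes$start[i] - 1000L),
                 end = genes$start[i] - 1L)
    } else {
      data.frame(seqid = genes$seqid[i], start = genes$end[i] + 1L,
                 end = genes$end[i] + 1000L)
    }
    if (hits(up)) return("upstream")
  }
  for (i in seq_len(nrow(genes))) {
    dn <- if (genes$strand[i] == "+") {
      data.frame(seqid = genes$seqid[i], start = genes$end[i] + 1L,
                 end = genes$end[i] + 1000L)
    } else {
      data.frame(seqid = genes$seqid[i],
                 start = max(1L, genes$start[i] - 1000L),
                 end = genes$start[i] - 1L)
    }
    if (hits(dn)) return("downstream")
  }
  "intergenic"
}

random_location_on <- function(ann, chrom, chrom_len) {
  n_blocks <- sample(1:2, 1L)
  start1 <- sample.int(chrom_len - 400L, 1L)
  w1 <- sample(15:60, 1L)
  blocks <- data.frame(start = start1, end = start1 + w1 - 1L)
  if (n_blocks == 2L) {
    gap <- sample(30:200, 1L)
    w2 <- sample(15:60, 1L)
    s2 <- blocks$end[1L] + gap + 1L
    blocks <- rbind(blocks, data.frame(start = s2, end = s2 + w2 - 1L))
  }
  make_location(chrom, sample(c("+", "-"), 1L), blocks)
}

# Brute-force read counting over all (read, block) pairs.
oracle_count_reads <- function(aln, blocks, chrom, min_overlap = 1L,
                               max_mismatch = 1L) {
  n <- 0L
  for (i in seq_len(nrow(aln))) {
    if (aln$chrom[i] != chrom) next
    if (is.na(aln$edit_distance[i]) ||
        aln$edit_distance[i] > max_mismatch) next
    a1 <- aln$pos[i]; a2 <- aln$pos[i] + aln$ref_span[i] - 1L
    hit <- FALSE
    for (j in seq_len(nrow(blocks))) {
      ov <- min(a2, blocks$end[j]) - max(a1, blocks$start[j]) + 1L
      if (ov >= min_overlap) hit <- TRUE
    }
    if (hit) n <- n + 1L
  }
  n
}
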