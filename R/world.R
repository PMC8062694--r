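# Synthetic genome, annotation and proteome generation.
#
# The generator lays out a single toy chromosome containing protein-coding
# genes (with UTRs, one intron and 1 kb flanks), processed-pseudogene-like
# copies of coding genes, spliced lncRNAs carrying an open reading frame,
# and a LINE-1-like repeat family with near-identical genomic copies. It is
# the stand-in for the reference genome + gene annotation + known proteome
# that a real proteogenomic search would start from, and carries a ground
# truth used to validate every downstream stage.

STOP_CODONS <- c("TAA", "TAG", "TGA")

nonstop_codons <- function() {
  setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
}

random_orf <- function(n_aa) {
  # ATG + (n_aa - 1) non-stop codons + TAA; translates to an n_aa protein
  paste0("ATG", paste(sample(nonstop_codons(), n_aa - 1L, replace = TRUE),
                      collapse = ""), "TAA")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1L))
  }
  paste(bases, collapse = "")
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators. The defaults are
#' the package's standard study conditions: a colorectal-cancer-like paired
#' label-free design (8 tumor/normal pairs), a 31-tissue healthy panel, and
#' PSM class sizes large enough to measure false-discovery calibration.
#'
#' @param seed root seed; all generator randomness flows from it through
#'   named substreams.
#' @param n_coding_genes,n_pseudogenes,n_lncrnas,n_repeat_copies element
#'   counts on the synthetic chromosome.
#' @param pseudogene_divergence per-nucleotide substitution probability
#'   applied when copying a parental CDS into a pseudogene.
#' @param psm_counts list with `known`, `novel_true`, `novel_false`, `decoy`
#'   PSM counts. `decoy = NA` derives a balanced decoy count in which
#'   noncoding-origin decoys match the number of incorrect novel-class
#'   target matches (the symmetry assumption underlying target-decoy FDR).
#' @param score_distributions list of `c(mean, sd)` for classes `known`,
#'   `novel` (correct novel-class matches) and `incorrect` (false matches
#'   and decoys, which share one distribution).
#' @param missingness_rate fraction of quantification cells set missing.
#' @param n_tumor_pairs paired tumor/normal sample count.
#' @param n_tissues tissue count of the healthy panel.
#' @param n_variants number of missense variant entries generated.
#' @param min_segment_len minimum three-frame-translation segment length.
#' @param coding_protein_len length (aa) of each synthetic known protein.
#' @param quant_noise_sd per-measurement log2 noise s.d.
#' @param n_planted_upregulated,planted_effect number of loci planted as
#'   tumor-upregulated and their log2 effect.
#' @param peptides_per_locus integer range of quantified peptides per locus.
#' @param baseline_log2 mean peptide log2 MS1 intensity.
#' @param max_chrom_length sizing cap for the synthetic chromosome.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_coding_genes = 25L,
                       n_pseudogenes = 15L,
                       n_lncrnas = 10L,
                       n_repeat_copies = 8L,
                       pseudogene_divergence = 0.05,
                       psm_counts = list(known = 2000L, novel_true = 800L,
                                         novel_false = 200L, decoy = NA),
                       score_distributions = list(
                         known = c(mean = 5, sd = 1),
                         novel = c(mean = 2.5, sd = 1),
                         incorrect = c(mean = 0, sd = 1)),
                       missingness_rate = 0.1,
                       n_tumor_pairs = 8L,
                       n_tissues = 31L,
                       n_variants = 5L,
                       min_segment_len = 7L,
                       coding_protein_len = 119L,
                       quant_noise_sd = 0.25,
                       n_planted_upregulated = 11L,
                       planted_effect = 1.0,
                       peptides_per_locus = c(2L, 5L),
                       baseline_log2 = 20,
                       max_chrom_length = 2e6) {
  cfg <- list(seed = as.integer(seed),
              n_coding_genes = as.integer(n_coding_genes),
              n_pseudogenes = as.integer(n_pseudogenes),
              n_lncrnas = as.integer(n_lncrnas),
              n_repeat_copies = as.integer(n_repeat_copies),
              pseudogene_divergence = pseudogene_divergence,
              psm_counts = psm_counts,
              score_distributions = score_distributions,
              missingness_rate = missingness_rate,
              n_tumor_pairs = as.integer(n_tumor_pairs),
              n_tissues = as.integer(n_tissues),
              n_variants = as.integer(n_variants),
              min_segment_len = as.integer(min_segment_len),
              coding_protein_len = as.integer(coding_protein_len),
              quant_noise_sd = quant_noise_sd,
              n_planted_upregulated = as.integer(n_planted_upregulated),
              planted_effect = planted_effect,
              peptides_per_locus = as.integer(peptides_per_locus),
              baseline_log2 = baseline_log2,
              max_chrom_length = max_chrom_length)
  counts <- unlist(cfg[c("n_coding_genes", "n_pseudogenes", "n_lncrnas",
                         "n_repeat_copies", "n_tumor_pairs", "n_tissues",
                         "n_variants")])
  if (any(counts < 0L)) stop("counts must be >= 0")
  probs <- c(cfg$pseudogene_divergence, cfg$missingness_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

# ---- transcript coordinate machinery ---------------------------------------

new_transcript <- function(id, gene_id, biotype, chrom, strand, exons,
                           spliced, parent_gene = NA_character_,
                           family = NA_character_) {
  stopifnot(strand %in% c("+", "-"),
            sum(exons$end - exons$start + 1L) == nchar(spliced))
  list(id = id, gene_id = gene_id, biotype = biotype, chrom = chrom,
       strand = strand, exons = exons, spliced = spliced,
       parent_gene = parent_gene, family = family)
}

# Genomic position of every spliced-transcript nucleotide, transcription order.
tx_positions <- function(tx) {
  if (tx$strand == "+") {
    unlist(Map(seq.int, tx$exons$start, tx$exons$end), use.names = FALSE)
  } else {
    unlist(Map(function(s, e) seq.int(e, s), tx$exons$start, tx$exons$end),
           use.names = FALSE)
  }
}

# Re-derive the spliced sequence from the genome (strand-aware); used by
# round-trip checks and peptide re-translation.
tx_spliced_from_genome <- function(tx, genome) {
  chrom_seq <- genome[[tx$chrom]]
  parts <- vapply(seq_len(nrow(tx$exons)), function(i) {
    s <- substr(chrom_seq, tx$exons$start[i], tx$exons$end[i])
    if (tx$strand == "-") revcomp(s) else s
  }, character(1L))
  paste(parts, collapse = "")
}

# Place a spliced transcript on the genome at `at` (leftmost coordinate).
# Returns the genomic insert sequence and exon table in transcription order.
place_transcript <- function(spliced, exon_lens, intron_lens, strand, at) {
  stopifnot(sum(exon_lens) == nchar(spliced),
            length(intron_lens) == length(exon_lens) - 1L)
  ends <- cumsum(exon_lens)
  starts <- ends - exon_lens + 1L
  parts <- substring(spliced, starts, ends)           # transcription order
  introns <- vapply(intron_lens, random_dna, character(1L))
  if (strand == "+") {
    genomic_parts <- parts
    widths <- exon_lens
  } else {
    genomic_parts <- rev(vapply(parts, revcomp, character(1L)))
    widths <- rev(exon_lens)
    introns <- rev(introns)
  }
  pieces <- character(0)
  exon_start <- integer(length(widths)); exon_end <- integer(length(widths))
  pos <- at
  for (i in seq_along(widths)) {
    exon_start[i] <- pos
    exon_end[i] <- pos + widths[i] - 1L
    pieces <- c(pieces, genomic_parts[i])
    pos <- exon_end[i] + 1L
    if (i < length(widths)) {
      pieces <- c(pieces, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  exons <- data.frame(start = exon_start, end = exon_end)
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL
  list(insert = paste(pieces, collapse = ""), exons = exons,
       span = c(at, pos - 1L))
}

feature_row <- function(seqid, type, start, end, strand, id,
                        gene_id = NA_character_, biotype = NA_character_,
                        parent_gene = NA_character_, family = NA_character_,
                        phase = NA_integer_) {
  data.frame(seqid = seqid, source = "darkpep", type = type,
             start = start, end = end, strand = strand, ID = id,
             gene_id = gene_id, biotype = biotype, parent_gene = parent_gene,
             family = family, phase = phase, stringsAsFactors = FALSE)
}

# ---- world generation ------------------------------------------------------

#' Generate a synthetic genome, annotation and proteome
#'
#' Builds a seeded toy chromosome with coding genes, pseudogenes (mutated
#' copies of sampled parental CDS), spliced lncRNAs containing an ORF, and a
#' family of near-identical LINE-1-like repeat copies, plus the known
#' proteome, a set of missense variant specifications and the ground-truth
#' table of novel peptides derivable from the noncoding transcripts.
#'
#' @param config a [sim_config()] object.
#' @return object of class `synthetic_world`: a list with `genome` (named
#'   chromosome sequences), `annotation` (feature data.frame), `transcripts`
#'   (list), `known_proteome` (named character), `mutations`
#'   (missense spec data.frame) and `truth`.
#' @export
generate_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "world", {
    chrom <- "chr1"
    pieces <- list()
    cursor <- 1L
    feats <- list()
    txs <- list()
    known <- character(0)

    pad <- function() {
      n <- 1500L + sample.int(500L, 1L)
      pieces[[length(pieces) + 1L]] <<- random_dna(n)
      cursor <<- cursor + n
    }

    # protein-coding genes (plus strand; UTRs, one intron, 1 kb flanks are
    # implicit in the spacing)
    utr5 <- 60L; utr3 <- 60L; intron_len <- 150L
    coding_cds <- character(config$n_coding_genes)
    for (i in seq_len(config$n_coding_genes)) {
      pad()
      gid <- sprintf("GENE%03d", i)
      cds <- random_orf(config$coding_protein_len + 1L)
      coding_cds[i] <- cds
      prot <- sub("\\*$", "", translate_frame(cds, 0L))
      known[gid] <- prot
      part_a <- 180L
      spliced <- paste0(random_dna(utr5), cds, random_dna(utr3))
      exon_lens <- c(utr5 + part_a, nchar(cds) - part_a + utr3)
      pl <- place_transcript(spliced, exon_lens, intron_len, "+", cursor)
      pieces[[length(pieces) + 1L]] <- pl$insert
      g0 <- pl$span[1]; g1 <- pl$span[2]
      cds_a <- c(g0 + utr5, g0 + utr5 + part_a - 1L)
      cds_b <- c(cds_a[2] + intron_len + 1L, cds_a[2] + intron_len +
                   (nchar(cds) - part_a))
      feats[[length(feats) + 1L]] <- rbind(
        feature_row(chrom, "gene", g0, g1, "+", gid, gid, "protein_coding"),
        feature_row(chrom, "exon", pl$exons$start[1], pl$exons$end[1], "+",
                    paste0(gid, ".e1"), gid, "protein_coding"),
        feature_row(chrom, "exon", pl$exons$start[2], pl$exons$end[2], "+",
                    paste0(gid, ".e2"), gid, "protein_coding"),
        feature_row(chrom, "CDS", cds_a[1], cds_a[2], "+",
                    paste0(gid, ".cds1"), gid, "protein_coding", phase = 0L),
        feature_row(chrom, "CDS", cds_b[1], cds_b[2], "+",
                    paste0(gid, ".cds2"), gid, "protein_coding", phase = 0L),
        feature_row(chrom, "five_prime_UTR", g0, g0 + utr5 - 1L, "+",
                    paste0(gid, ".u5"), gid, "protein_coding"),
        feature_row(chrom, "three_prime_UTR", g1 - utr3 + 1L, g1, "+",
                    paste0(gid, ".u3"), gid, "protein_coding"))
      txs[[gid]] <- new_transcript(gid, gid, "protein_coding", chrom, "+",
                                   pl$exons, spliced)
      cursor <- g1 + 1L
    }

    # pseudogenes: single-exon mutated copies of a parental CDS
    if (config$n_pseudogenes > 0L) {
      parents <- sample(sprintf("GENE%03d", seq_len(config$n_coding_genes)),
                        config$n_pseudogenes, replace = TRUE)
      for (i in seq_len(config$n_pseudogenes)) {
        pad()
        gid <- sprintf("PSG%03d", i)
        parent_cds <- coding_cds[match(parents[i],
                                       sprintf("GENE%03d",
                                               seq_len(config$n_coding_genes)))]
        spliced <- mutate_dna(parent_cds, config$pseudogene_divergence)
        strand <- sample(c("+", "-"), 1L)
        pl <- place_transcript(spliced, nchar(spliced), integer(0), strand,
                               cursor)
        pieces[[length(pieces) + 1L]] <- pl$insert
        feats[[length(feats) + 1L]] <- feature_row(
          chrom, "pseudogene", pl$span[1], pl$span[2], strand, gid, gid,
          "pseudogene", parent_gene = parents[i])
        txs[[gid]] <- new_transcript(gid, gid, "pseudogene", chrom, strand,
                                     pl$exons, spliced,
                                     parent_gene = parents[i])
        cursor <- pl$span[2] + 1L
      }
    }

    # lncRNAs: two exons; the spliced sequence carries a frame-0 ORF that
    # spans the junction so junction-crossing peptides arise
    for (i in seq_len(config$n_lncrnas)) {
      pad()
      gid <- sprintf("LNC%03d", i)
      spliced <- paste(sample(nonstop_codons(), 100L, replace = TRUE),
                       collapse = "")
      strand <- sample(c("+", "-"), 1L)
      pl <- place_transcript(spliced, c(150L, 150L), 120L, strand, cursor)
      pieces[[length(pieces) + 1L]] <- pl$insert
      feats[[length(feats) + 1L]] <- rbind(
        feature_row(chrom, "lncRNA", pl$span[1], pl$span[2], strand, gid,
                    gid, "lncRNA"),
        feature_row(chrom, "exon", min(pl$exons$start), min(pl$exons$end),
                    strand, paste0(gid, ".e1"), gid, "lncRNA"),
        feature_row(chrom, "exon", max(pl$exons$start), max(pl$exons$end),
                    strand, paste0(gid, ".e2"), gid, "lncRNA"))
      txs[[gid]] <- new_transcript(gid, gid, "lncRNA", chrom, strand,
                                   pl$exons, spliced)
      cursor <- pl$span[2] + 1L
    }

    # LINE-1-like repeat family: identical genomic copies of one element
    if (config$n_repeat_copies > 0L) {
      element <- paste0(random_dna(60L), random_orf(80L), random_dna(60L))
      for (i in seq_len(config$n_repeat_copies)) {
        pad()
        gid <- sprintf("RPT1_C%02d", i)
        strand <- sample(c("+", "-"), 1L)
        spliced <- element  # transcript orientation
        pl <- place_transcript(spliced, nchar(spliced), integer(0), strand,
                               cursor)
        pieces[[length(pieces) + 1L]] <- pl$insert
        feats[[length(feats) + 1L]] <- feature_row(
          chrom, "repeat_region", pl$span[1], pl$span[2], strand, gid, gid,
          "repeat", family = "RPT1")
        txs[[gid]] <- new_transcript(gid, gid, "repeat", chrom, strand,
                                     pl$exons, spliced, family = "RPT1")
        cursor <- pl$span[2] + 1L
      }
    }

    pad()
    total_len <- sum(nchar(unlist(pieces)))
    if (total_len > config$max_chrom_length) {
      stop("requested element counts exceed chromosome capacity (",
           total_len, " > ", config$max_chrom_length, " nt)")
    }
    genome <- setNames(paste(unlist(pieces), collapse = ""), chrom)
    annotation <- do.call(rbind, feats)
    rownames(annotation) <- NULL

    # missense variant specifications on known proteins
    mutations <- if (config$n_variants > 0L) {
      pid <- sample(names(known), config$n_variants, replace = TRUE)
      pos <- vapply(pid, function(p) 1L + sample.int(nchar(known[[p]]) - 1L,
                                                     1L), integer(1L))
      ref <- substring(known[pid], pos, pos)
      alt <- vapply(ref, function(r) sample(setdiff(AA20, r), 1L),
                    character(1L))
      data.frame(protein_id = pid, position = pos, ref_aa = ref,
                 alt_aa = alt, row.names = NULL, stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = character(), position = integer(),
                 ref_aa = character(), alt_aa = character(),
                 stringsAsFactors = FALSE)
    }

    world <- structure(
      list(genome = genome, annotation = annotation, transcripts = txs,
           known_proteome = known, mutations = mutations, truth = NULL,
           config = config),
      class = "synthetic_world")
    world$truth <- compute_ground_truth(world)
    world
  })
}

# True novel peptides: fully tryptic products of the three-frame-translated
# noncoding transcripts that do not match the known proteome (under I/L
# equivalence) nor any variant entry.
compute_ground_truth <- function(world) {
  cfg <- world$config
  entries <- noncoding_entries(world, cfg$min_segment_len)
  idx <- known_peptide_index(world$known_proteome,
                             variant_proteins = variant_proteins(world))
  rows <- list()
  for (i in seq_len(nrow(entries))) {
    peps <- digest_tryptic(entries$protein[i], 0L)
    peps <- peps[nchar(peps) >= 7L & nchar(peps) <= 45L]
    if (!length(peps)) next
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = peps, entry_id = entries$entry_id[i],
      locus_id = entries$locus_id[i], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(list(novel_peptides = data.frame(peptide = character(),
                                            entry_id = character(),
                                            locus_id = character())))
  }
  df <- do.call(rbind, rows)
  cls <- classify_peptides(unique(df$peptide), idx)
  novel <- names(cls)[cls == "novel"]
  df <- df[df$peptide %in% novel, , drop = FALSE]
  # one row per (peptide, locus); keep one representative entry
  key <- paste(df$peptide, df$locus_id)
  df <- df[!duplicated(key), , drop = FALSE]
  rownames(df) <- NULL
  list(novel_peptides = df)
}

variant_proteins <- function(world) {
  m <- world$mutations
  if (!nrow(m)) return(character(0))
  vapply(seq_len(nrow(m)), function(i) {
    apply_mutation(world$known_proteome[[m$protein_id[i]]],
                   mutation_spec(m$protein_id[i], m$position[i],
                                 m$ref_aa[i], m$alt_aa[i]))
  }, character(1L))
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", sum(nchar(x$genome)), "nt on",
      length(x$genome), "chromosome(s)\n")
  bt <- table(vapply(x$transcripts, `[[`, character(1L), "biotype"))
  cat("  transcripts:", paste(names(bt), bt, sep = "=", collapse = ", "),
      "\n")
  cat("  known proteins:", length(x$known_proteome),
      "| variant specs:", nrow(x$mutations),
      "| true novel peptides:", nrow(x$truth$novel_peptides), "\n")
  invisible(x)
}
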