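test_that("unique pseudogene peptides map to one re-translatable location", {
  w <- get_small_world(); db <- get_small_db()
  truth <- w$truth$novel_peptides
  psg <- truth[grepl("^PSG", truth$locus_id), ]
  single <- psg$peptide[!psg$peptide %in%
                          truth$peptide[duplicated(truth$peptide)]]
  expect_gt(length(single), 0L)
  for (p in head(single, 5L)) {
    locs <- map_peptide(p, db)
    expect_gte(nrow(locs), 1L)
    for (i in seq_len(nrow(locs))) {
      expect_equal(il_collapse(retranslate_location(locs[i, , drop = FALSE],
                                                    w$genome)),
                   il_collapse(p))
      b <- locs$blocks[[i]]
      expect_equal(sum(b$end - b$start + 1L), 3L * nchar(p))
    }
  }
})

test_that("repeat-family peptides map to every genomic copy", {
  w <- get_small_world(); db <- get_small_db()
  truth <- w$truth$novel_peptides
  rpt <- truth$peptide[truth$locus_id == "RPT1"]
  expect_gt(length(rpt), 0L)
  locs <- map_peptide(rpt[1], db)
  expect_equal(nrow(locs), w$config$n_repeat_copies)
})

test_that("junction-spanning lncRNA peptides carry two blocks", {
  w <- get_small_world(); db <- get_small_db()
  truth <- w$truth$novel_peptides
  lnc <- truth$peptide[grepl("^LNC", truth$locus_id)]
  n_blocks <- vapply(lnc, function(p) {
    locs <- map_peptide(p, db)
    max(vapply(locs$blocks, nrow, integer(1L)))
  }, integer(1L))
  expect_true(any(n_blocks == 2L))
  p <- lnc[which(n_blocks == 2L)[1L]]
  locs <- map_peptide(p, db)
  i <- which(vapply(locs$blocks, nrow, integer(1L)) == 2L)[1L]
  b <- locs$blocks[[i]]
  expect_equal(sum(b$end - b$start + 1L), 3L * nchar(p))
})

test_that("unmappable peptides return an empty table with a warning", {
  db <- get_small_db()
  expect_warning(locs <- map_peptide("WWWWWWWWWW", db), "not found")
  expect_equal(nrow(locs), 0L)
})

# hand-built annotation exercising every category and the precedence order
toy_annotation <- function() {
  rbind(
    darkpep:::feature_row("chrT", "gene", 10000, 11000, "+", "G1", "G1",
                          "protein_coding"),
    darkpep:::feature_row("chrT", "exon", 10000, 10400, "+", "G1.e1", "G1",
                          "protein_coding"),
    darkpep:::feature_row("chrT", "exon", 10600, 11000, "+", "G1.e2", "G1",
                          "protein_coding"),
    darkpep:::feature_row("chrT", "CDS", 10060, 10400, "+", "G1.c1", "G1",
                          "protein_coding", phase = 0L),
    darkpep:::feature_row("chrT", "CDS", 10600, 10940, "+", "G1.c2", "G1",
                          "protein_coding", phase = 2L),
    darkpep:::feature_row("chrT", "five_prime_UTR", 10000, 10059, "+",
                          "G1.u5", "G1", "protein_coding"),
    darkpep:::feature_row("chrT", "three_prime_UTR", 10941, 11000, "+",
                          "G1.u3", "G1", "protein_coding"),
    darkpep:::feature_row("chrT", "pseudogene", 20000, 20500, "+", "PSGX",
                          "PSGX", "pseudogene", parent_gene = "G1"),
    darkpep:::feature_row("chrT", "lncRNA", 20400, 21000, "+", "LNCX",
                          "LNCX", "lncRNA"),
    darkpep:::feature_row("chrT", "repeat_region", 30000, 30400, "-",
                          "RPTX_C1", "RPTX_C1", "repeat", family = "RPTX"))
}

test_that("category precedence follows pseudogene-first rules", {
  idx <- index_annotation(toy_annotation())
  cat_of <- function(strand, s, e, s2 = NULL, e2 = NULL) {
    b <- data.frame(start = s, end = e)
    if (!is.null(s2)) b <- rbind(b, data.frame(start = s2, end = e2))
    assign_category(make_location("chrT", strand, b), idx)$category
  }
  # overlapping both a pseudogene and a lncRNA counts as pseudogene only
  expect_equal(cat_of("+", 20420, 20460), "pseudogene")
  expect_equal(cat_of("+", 20600, 20660), "lncRNA")
  expect_equal(cat_of("-", 30100, 30160), "retroelement")
  expect_equal(cat_of("+", 10020, 10050), "utr")
  # CDS overlap out of the annotated frame (anchor differs)
  cds_anchor <- (10060 + 0) %% 3
  alt_start <- 10100 + ((cds_anchor + 1 - 10100) %% 3)
  expect_equal(alt_start %% 3 == cds_anchor, FALSE)
  expect_equal(cat_of("+", alt_start, alt_start + 29), "exonic_altframe")
  # antisense over the CDS is also out of frame
  expect_equal(cat_of("-", 10100, 10160), "exonic_altframe")
  # same-frame CDS overlap falls through (here to the exon/intron boundary)
  same_start <- 10300 + ((cds_anchor - 10300) %% 3)
  expect_equal(cat_of("+", same_start, 10450), "intron_exon_boundary")
  # fully intronic (same-frame anchor, no CDS overlap)
  expect_equal(cat_of("+", 10450, 10520), "intronic")
  expect_equal(cat_of("+", 9500, 9520), "upstream")     # 500 bp 5' of gene
  expect_equal(cat_of("+", 8400, 8500), "intergenic")   # 1.5 kb away
  expect_equal(cat_of("+", 11200, 11260), "downstream")
  expect_equal(cat_of("+", 50000, 50060), "intergenic")
})

test_that("category assignment matches the naive oracle on random
          locations", {
  w <- get_small_world()
  idx <- index_annotation(w$annotation)
  chrom_len <- nchar(w$genome[["chr1"]])
  withr::with_seed(29, {
    for (i in 1:300) {
      loc <- random_location_on(w$annotation, "chr1", chrom_len)
      expect_equal(assign_category(loc, idx)$category,
                   oracle_category(loc, w$annotation),
                   info = sprintf("location %d", i))
    }
  })
})

test_that("grouping keys separate loci by gene and category", {
  asn <- data.frame(
    placement_id = sprintf("pl%d", 1:6),
    peptide = c("AAK", "CCK", "DDK", "EEK", "EEK", "FFK"),
    chrom = "chrT", strand = "+",
    start = c(100, 200, 300, 5000, 5000, 40000),
    end = c(130, 230, 330, 5030, 5030, 40030),
    category = c("pseudogene", "pseudogene", "pseudogene", "utr", "utr",
                 "intronic"),
    host_id = c("PSGX", "PSGX", "PSGX", "G1", "G1", "G1"),
    stringsAsFactors = FALSE)
  loci <- group_into_loci(asn)
  expect_equal(nrow(loci), 3L)
  psg <- loci[loci$locus_id == "PSGX", ]
  expect_equal(psg$n_unique_peptides, 3L)
  # the same peptide seen twice counts once; utr and intron of one gene
  # are distinct loci
  expect_equal(loci$n_unique_peptides[loci$locus_id == "G1:utr"], 1L)
  expect_true("G1:intronic" %in% loci$locus_id)
  # partition: every placement appears in exactly one locus
  expect_equal(sort(unlist(loci$placements)), sort(asn$placement_id))
})

test_that("intergenic placements cluster by single linkage within 10 kb", {
  asn <- data.frame(
    placement_id = sprintf("pl%d", 1:3),
    peptide = c("AAK", "CCK", "DDK"), chrom = "chrT", strand = "+",
    start = c(1000, 9000, 40000), end = c(1030, 9030, 40030),
    category = "intergenic", host_id = NA_character_,
    stringsAsFactors = FALSE)
  loci <- group_into_loci(asn)
  expect_equal(nrow(loci), 2L)
  expect_equal(sort(loci$n_unique_peptides), c(1L, 2L))
})

test_that("the minimum-unique-peptide filter keeps supported loci", {
  loci <- data.frame(locus_id = c("a", "b", "c"), category = "pseudogene",
                     n_unique_peptides = c(1L, 2L, 3L),
                     parent_gene_class = NA_character_,
                     stringsAsFactors = FALSE)
  expect_equal(filter_min_unique_peptides(loci, 2L)$locus_id, c("b", "c"))
  expect_equal(nrow(filter_min_unique_peptides(loci, 1L)), 3L)
  expect_equal(nrow(filter_min_unique_peptides(loci, 10L)), 0L)
})

test_that("parental-gene classes tag pseudogene loci only", {
  loci <- data.frame(locus_id = c("PSG1", "PSG2", "LNC1"),
                     category = c("pseudogene", "pseudogene", "lncRNA"),
                     n_unique_peptides = 2L,
                     parent_gene_class = NA_character_,
                     stringsAsFactors = FALSE)
  tagged <- tag_parent_class(loci, c(PSG1 = "ribosomal protein"))
  expect_equal(tagged$parent_gene_class,
               c("ribosomal protein", "unannotated", NA))
})

test_that("peptide GFF3 round-trips blocks exactly", {
  w <- get_small_world(); db <- get_small_db()
  truth <- w$truth$novel_peptides
  locs <- do.call(rbind, lapply(unique(truth$peptide)[1:10], function(p) {
    suppressWarnings(map_peptide(p, db))
  }))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_peptide_gff3(locs, path)
  back <- read_peptide_gff3(path)
  back <- back[match(locs$placement_id, back$placement_id), ]
  expect_equal(back$peptide, locs$peptide)
  expect_equal(back$blocks, locs$blocks, ignore_attr = TRUE)
  multi <- which(vapply(locs$blocks, nrow, integer(1L)) > 1L)
  if (length(multi)) {
    lines <- readLines(path)
    id <- locs$placement_id[multi[1L]]
    expect_equal(sum(grepl(paste0("Parent=", id, ";"), lines, fixed = TRUE)),
                 nrow(locs$blocks[[multi[1L]]]))
  }
  # empty input produces a header-only file
  path2 <- withr::local_tempfile(fileext = ".gff3")
  write_peptide_gff3(darkpep:::empty_locations(), path2)
  expect_equal(readLines(path2), "##gff-version 3")
})
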