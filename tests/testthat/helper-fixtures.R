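# Shared fixtures: one small synthetic world (and its database/index) is
# built once per test run and reused across files.

.fix <- new.env(parent = emptyenv())

small_config <- function(seed = 1L) {
  sim_config(seed = seed, n_coding_genes = 6L, n_pseudogenes = 4L,
             n_lncrnas = 3L, n_repeat_copies = 4L, n_variants = 3L,
             psm_counts = list(known = 200L, novel_true = 80L,
                               novel_false = 40L, decoy = NA))
}

get_small_world <- function() {
  if (is.null(.fix$world)) .fix$world <- generate_world(small_config())
  .fix$world
}

get_small_db <- function() {
  if (is.null(.fix$db)) .fix$db <- build_search_db(get_small_world())
  .fix$db
}

get_small_index <- function() {
  if (is.null(.fix$index)) {
    w <- get_small_world()
    .fix$index <- known_peptide_index(
      w$known_proteome,
      variant_proteins = darkpep:::variant_proteins(w))
  }
  .fix$index
}

random_aa_seq <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}

random_dna_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_location <- function(chrom, strand, blocks) {
  data.frame(placement_id = sprintf("loc@%s%s:%d", chrom, strand,
                                    blocks$start[1]),
             peptide = "PEPTIDEK", chrom = chrom, strand = strand,
             frame = 0L, source_entry = NA_character_,
             gene_id = NA_character_, biotype = NA_character_,
             family = NA_character_, start = min(blocks$start),
             end = max(blocks$end), blocks = I(list(blocks)),
             stringsAsFactors = FALSE)
}
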