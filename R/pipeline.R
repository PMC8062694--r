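# End-to-end orchestration: synthetic world -> search database -> PSM
# simulation -> class-specific FDR -> genomic annotation and locus
# grouping -> quantification and differential testing -> tissue classes ->
# dark-antigen screening -> RNA-read support. One root seed drives every
# stage through named substreams; the manifest records parameters and
# per-stage row counts so reruns can be compared exactly.

PIPELINE_STAGES <- c("simulate", "builddb", "psms", "fdr", "annotate",
                     "quant", "tissueclass", "epitopes", "rnascan")

#' Pipeline configuration
#'
#' @param seed root seed.
#' @param outdir output directory.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param alpha novel-class FDR threshold.
#' @param k_min_peptides minimum unique peptides per locus.
#' @param epitope an [epitope_config()].
#' @param stages stages to run (prefix of the full ordered list; later
#'   stages depend on earlier ones).
#' @param rnascan_depth,rnascan_mismatch_rate read-simulation parameters
#'   for the orthogonal-evidence stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42L, outdir = tempfile("darkpep_run_"),
                            sim = sim_config(seed = seed), alpha = 0.01,
                            k_min_peptides = 2L,
                            epitope = epitope_config(background_seed = seed),
                            stages = PIPELINE_STAGES,
                            rnascan_depth = 10L,
                            rnascan_mismatch_rate = 0.005) {
  sim$seed <- as.integer(seed)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), outdir = outdir, sim = sim,
                 alpha = alpha, k_min_peptides = as.integer(k_min_peptides),
                 epitope = epitope, stages = stages,
                 rnascan_depth = as.integer(rnascan_depth),
                 rnascan_mismatch_rate = rnascan_mismatch_rate),
            class = "pipeline_config")
}

check_stage_deps <- function(stages) {
  idx <- match(stages, PIPELINE_STAGES)
  need <- seq_len(max(idx))
  missing <- setdiff(PIPELINE_STAGES[need], stages)
  if (length(missing)) {
    stop("stage dependency error: enabled stage(s) require disabled ",
         "stage(s): ", paste(missing, collapse = ", "))
  }
}

#' Run the full pipeline on synthetic data
#'
#' Executes the enabled stages in order, writes every intermediate table
#' under `config$outdir`, and returns a manifest with the parameters,
#' per-stage row counts and output-file digests.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_manifest` list (also written as
#'   `manifest.tsv`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  check_stage_deps(config$stages)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  state <- new.env(parent = emptyenv())
  on_stage <- function(s) s %in% config$stages

  if (on_stage("simulate")) {
    state$world <- generate_world(config$sim)
    write_world(state$world, file.path(config$outdir, "world"))
    counts$simulate <- c(
      transcripts = length(state$world$transcripts),
      true_novel_peptides = nrow(state$world$truth$novel_peptides))
  }
  if (on_stage("builddb")) {
    state$db <- build_search_db(state$world)
    write_search_db(state$db, file.path(config$outdir, "db"))
    counts$builddb <- c(entries = nrow(state$db$entries),
                        targets = sum(state$db$entries$class != "decoy"))
  }
  if (on_stage("psms")) {
    state$psms <- simulate_psms(state$world, state$db, config$sim,
                                seed = config$seed)
    write_tsv(state$psms, file.path(config$outdir, "psms.tsv"))
    write_tsv(attr(state$psms, "truth"),
              file.path(config$outdir, "psm_truth.tsv"))
    counts$psms <- c(psms = nrow(state$psms),
                     decoys = sum(state$psms$is_decoy))
  }
  if (on_stage("fdr")) {
    state$index <- known_peptide_index(
      state$world$known_proteome,
      variant_proteins = variant_proteins(state$world))
    parts <- prefilter_for_fdr(state$psms, state$index, state$db)
    state$verdicts <- class_specific_fdr(parts$novel_targets,
                                         parts$novel_decoys,
                                         alpha = config$alpha)
    write_tsv(state$verdicts, file.path(config$outdir, "verdicts.tsv"))
    counts$fdr <- c(novel_target_psms = nrow(parts$novel_targets),
                    novel_decoy_psms = nrow(parts$novel_decoys),
                    discarded_psms = nrow(parts$discarded),
                    accepted_peptides = sum(state$verdicts$accepted))
  }
  if (on_stage("annotate")) {
    accepted <- state$verdicts$peptide[state$verdicts$accepted]
    state$assignments <- annotate_peptides(accepted, state$db,
                                           state$world$annotation)
    loci_all <- group_into_loci(state$assignments)
    state$loci <- filter_min_unique_peptides(loci_all,
                                             config$k_min_peptides)
    parent_lookup <- vapply(state$world$transcripts, function(tx) {
      if (is.na(tx$parent_gene)) NA_character_ else tx$parent_gene
    }, character(1L))
    parent_lookup <- parent_lookup[!is.na(parent_lookup)]
    state$loci <- tag_parent_class(state$loci, parent_lookup)
    write_peptide_gff3(state$assignments,
                       file.path(config$outdir, "peptides.gff3"))
    write_peptide_bed(state$assignments,
                      file.path(config$outdir, "peptides.bed"))
    locus_flat <- state$loci[, c("locus_id", "category",
                                 "n_unique_peptides", "parent_gene_class")]
    write_tsv(locus_flat, file.path(config$outdir, "loci.tsv"))
    counts$annotate <- c(placements = nrow(state$assignments),
                         loci_all = nrow(loci_all),
                         loci_min_k = nrow(state$loci))
  }
  if (on_stage("quant")) {
    design <- make_paired_design(config$sim$n_tumor_pairs)
    qs <- simulate_quant(state$loci$locus_id, design, config$sim,
                         seed = config$seed)
    state$quant <- qs
    lq <- summarize_labelfree(qs$peptide_mat, qs$locus_map)
    state$locus_mat <- lq
    state$diff <- test_differential(lq, design, mode = "paired")
    state$fc <- fold_change(lq, design)
    write_tsv(data.frame(locus_id = rownames(lq), lq,
                         check.names = FALSE),
              file.path(config$outdir, "locus_matrix.tsv"))
    write_tsv(state$diff, file.path(config$outdir, "differential.tsv"))
    counts$quant <- c(loci = nrow(lq),
                      tested = sum(state$diff$tested),
                      significant = sum(state$diff$tested &
                                          state$diff$p_value < 0.05,
                                        na.rm = TRUE))
  }
  if (on_stage("tissueclass")) {
    panel <- simulate_tissue_panel(state$loci$locus_id,
                                   n_tissues = config$sim$n_tissues,
                                   seed = config$seed)
    state$tissue <- classify_tissue_specificity(panel$detection)
    state$tissue_truth <- panel$truth
    write_tsv(state$tissue, file.path(config$outdir, "tissue_classes.tsv"))
    counts$tissueclass <- table(state$tissue$class)
  }
  if (on_stage("epitopes")) {
    nc <- noncoding_entries(state$world, config$sim$min_segment_len)
    seg <- do.call(rbind, lapply(state$loci$locus_id, function(l) {
      sub <- nc[nc$locus_id == l, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      data.frame(locus_id = l,
                 protein = sub$protein[which.max(nchar(sub$protein))],
                 stringsAsFactors = FALSE)
    }))
    bg <- build_background(state$world$known_proteome, config$epitope)
    epi <- score_epitopes(seg, bg, config$epitope)
    state$candidates <- select_candidates(epi, state$fc, config$epitope)
    write_tsv(state$candidates$candidates,
              file.path(config$outdir, "dark_antigen_candidates.tsv"))
    counts$epitopes <- c(nine_mers = nrow(epi),
                         candidates = nrow(state$candidates$candidates),
                         loci_with_candidate =
                           sum(state$candidates$locus_summary$has_candidate))
  }
  if (on_stage("rnascan")) {
    locs <- state$assignments[seq_len(min(5L, nrow(state$assignments))), ,
                              drop = FALSE]
    sam <- simulate_reads(locs, depth = config$rnascan_depth,
                          mismatch_rate = config$rnascan_mismatch_rate,
                          seed = config$seed,
                          seqlengths = nchar(state$world$genome))
    names(sam) <- NULL
    sam_path <- file.path(config$outdir, "reads.sam")
    writeLines(sam, sam_path)
    state$read_counts <- count_supporting_reads(locs, sam_path)
    write_tsv(state$read_counts, file.path(config$outdir,
                                           "read_counts.tsv"))
    counts$rnascan <- c(reads = sum(!startsWith(sam, "@")),
                        placements = nrow(locs))
  }

  files <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest", files)]
  manifest <- structure(list(
    seed = config$seed,
    parameters = list(alpha = config$alpha,
                      k_min_peptides = config$k_min_peptides,
                      rank_threshold = config$epitope$rank_threshold,
                      fold_change_min = config$epitope$fold_change_min),
    counts = counts,
    digests = tools::md5sum(files),
    state = state), class = "pipeline_manifest")
  flat <- data.frame(
    key = c(paste0("param.", names(manifest$parameters)),
            unlist(lapply(names(counts), function(s) {
              paste0(s, ".", names(counts[[s]]))
            }))),
    value = c(unlist(manifest$parameters),
              unlist(lapply(counts, as.numeric))),
    stringsAsFactors = FALSE)
  write_tsv(flat, file.path(config$outdir, "manifest.tsv"))
  manifest
}

#' One-command synthetic demo
#'
#' Generates a synthetic world and runs every pipeline stage.
#'
#' @param seed root seed.
#' @param outdir output directory.
#' @param ... passed to [pipeline_config()].
#' @return the pipeline manifest.
#' @export
run_demo <- function(seed = 42L, outdir = tempfile("darkpep_demo_"), ...) {
  run_pipeline(pipeline_config(seed = seed, outdir = outdir, ...))
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("darkpep pipeline manifest (seed", x$seed, ")\n")
  for (s in names(x$counts)) {
    cat(sprintf("  %-11s %s\n", s,
                paste(names(x$counts[[s]]), unlist(x$counts[[s]]),
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}
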