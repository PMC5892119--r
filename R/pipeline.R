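# End-to-end orchestration: configuration, fixture bundles, the full
# classify -> quantify -> pairs -> DE -> effects -> motifs run, and a
# report audit that recomputes every summary from the stage artifacts.

#' Pipeline configuration
#'
#' Collects input paths and every tunable parameter of the pipeline,
#' with defaults set to the analysis' standard values: minimum antisense
#' overlap 8 nt, presence in at least 4 replicates, mean-TPM thresholds
#' of 40 (antisense) and 14 (intergenic), paired-test alpha 0.05, FDR
#' 0.05 (inclusive), 100-nt promoter windows and BRE/TATA centroids at
#' -38/-29. Unknown arguments are rejected.
#'
#' @param annotation,transcripts,counts,samples,genome input paths
#'   (GFF3, GTF, counts TSV, sample-sheet TSV, FASTA).
#' @param category_map optional TSV (`gene_id`, `category`) for
#'   enrichment; `NULL` skips the enrichment stage.
#' @param outdir output directory for stage artifacts.
#' @param min_overlap,min_replicates,tpm_thresholds,alpha,fdr parameters
#'   as documented in the stage functions.
#' @param window_upstream,window_downstream promoter window half-widths.
#' @param bre_centroid,tata_centroid,centroid_tolerance,relaxed_shift
#'   promoter-model settings.
#' @param ref_condition,pair_condition reference condition for DE and the
#'   condition whose replicates feed the paired test.
#' @param seed seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(annotation, transcripts, counts, samples,
                            genome, category_map = NULL, outdir,
                            min_overlap = 8L, min_replicates = 4L,
                            tpm_thresholds = c(antisense = 40,
                                               intergenic = 14),
                            alpha = 0.05, fdr = 0.05,
                            window_upstream = 100L,
                            window_downstream = 100L,
                            bre_centroid = -38L, tata_centroid = -29L,
                            centroid_tolerance = 3L, relaxed_shift = 3L,
                            ref_condition = "control",
                            pair_condition = "stress",
                            seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$min_overlap < 1) stop("min_overlap must be >= 1", call. = FALSE)
  if (cfg$min_replicates < 1) stop("min_replicates must be >= 1",
                                   call. = FALSE)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)",
                                             call. = FALSE)
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("fdr must be in (0, 1)",
                                         call. = FALSE)
  if (any(cfg$tpm_thresholds < 0)) stop("TPM thresholds must be >= 0",
                                        call. = FALSE)
  if (cfg$window_upstream < 1 || cfg$window_downstream < 0)
    stop("window sizes out of domain", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a synthetic fixture bundle to disk
#'
#' Generates a dataset with [simulate_dataset()] and writes the standard
#' files a pipeline run consumes: annotation GFF3, transcript GTF, genome
#' FASTA, counts + sample-sheet TSVs, category-map TSV, and the ground
#' truth as JSON.
#'
#' @param params a [sim_params()].
#' @param dir output directory (created if needed).
#' @return named list of file paths plus the in-memory `dataset`.
#' @export
make_fixture <- function(params = sim_params(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_dataset(params)
  paths <- list(
    annotation = file.path(dir, "annotation.gff3"),
    transcripts = file.path(dir, "transcripts.gtf"),
    genome = file.path(dir, "genome.fa"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    category_map = file.path(dir, "categories.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_annotation_gff3(ds$annotation, paths$annotation)
  write_transcripts_gtf(ds$transcripts, paths$transcripts)
  write_genome_fasta(ds$sequence, paths$genome)
  write_counts_tsv(ds$counts, paths$counts, paths$samples)
  utils::write.table(ds$category_map, paths$category_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- ds$truth
  truth$class_of <- as.list(truth$class_of)
  truth$expression_tier <- as.list(truth$expression_tier)
  truth$true_lfc <- as.list(truth$true_lfc)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  c(paths, list(dataset = ds))
}

#' Run the full sRNA landscape pipeline
#'
#' Stages: classification of transcripts into sRNA classes with cis
#' targets and binding regions; TPM normalisation and per-condition
#' presence/expression filtering; paired sRNA-vs-target expression tests;
#' NB differential expression with FDR calls; sRNA/target
#' cross-tabulation and (when a category map is supplied) hypergeometric
#' enrichment of up-regulated asRNA targets; promoter motif scanning with
#' centroid and promoter-fraction estimates. Deterministic given the
#' config; artifacts are written under `config$outdir` together with a
#' JSON report.
#'
#' @param config a [pipeline_config()].
#' @return the report (list), invisibly also written to
#'   `outdir/report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c("annotation", "transcripts", "counts", "samples", "genome"))
    if (!file.exists(config[[p]]))
      stop("pipeline input missing: ", p, " (", config[[p]], ")",
           call. = FALSE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  tsv <- function(df, f) utils::write.table(df, out(f), sep = "\t",
                                            quote = FALSE,
                                            row.names = FALSE)

  ann <- read_annotation(config$annotation)
  tx <- read_transcripts(config$transcripts)
  cm <- read_counts_tsv(config$counts, config$samples)
  genome_seq <- read_genome_fasta(config$genome)
  conditions <- unique(cm$samples$condition)

  ## classify ---------------------------------------------------------
  cl <- classify_transcripts(tx, ann, min_overlap = config$min_overlap)
  classes <- cl$classes
  srna_ids <- classes$transcript_id[classes$srna_class %in%
                                      c("antisense", "intergenic")]
  class_vec <- stats::setNames(classes$srna_class, classes$transcript_id)
  srna_tab <- merge(tx, classes, by = "transcript_id", sort = FALSE)
  write_srna_gff(srna_tab[srna_tab$srna_class %in%
                            c("antisense", "intergenic"), ],
                 out("srnas.gff3"))
  tsv(classes, "classes.tsv")
  tsv(cl$pairs, "cis_pairs.tsv")

  ## quantify ---------------------------------------------------------
  tpm_mat <- tpm(cm)
  utils::write.table(
    data.frame(feature_id = rownames(tpm_mat), tpm_mat,
               check.names = FALSE),
    out("tpm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  filters <- lapply(conditions, function(cond)
    filter_srnas(tpm_mat, class_vec[srna_ids], cm$samples, cond,
                 min_replicates = config$min_replicates,
                 thresholds = config$tpm_thresholds))
  names(filters) <- conditions
  for (cond in conditions)
    tsv(filters[[cond]], paste0("filter_", cond, ".tsv"))
  pass_any <- unique(unlist(lapply(filters, function(f)
    f$feature_id[f$pass])))

  ## paired cis tests -------------------------------------------------
  pair_cond <- config$pair_condition
  pass_pair <- filters[[pair_cond]]
  pass_pair <- pass_pair$feature_id[pass_pair$pass]
  pairs_tested <- cl$pairs[cl$pairs$srna_id %in% pass_pair, , drop = FALSE]
  pt <- run_all_pairs(tpm_mat, pairs_tested, cm$samples, pair_cond,
                      alpha = config$alpha)
  tsv(pt$results, "pair_tests.tsv")

  ## differential expression ------------------------------------------
  de <- run_de(cm, ref = config$ref_condition, fdr_threshold = config$fdr)
  tsv(de, "de.tsv")
  gene_ids <- ann$genes$gene_id
  srna_de <- de[de$feature_id %in% srna_ids, , drop = FALSE]
  mrna_de <- de[de$feature_id %in% gene_ids, , drop = FALSE]

  ## regulatory effects -----------------------------------------------
  asrna_pass <- intersect(
    pass_any, classes$transcript_id[classes$srna_class == "antisense"])
  xt_pairs <- cl$pairs[cl$pairs$srna_id %in% asrna_pass, , drop = FALSE]
  xt <- cross_tabulate(srna_de, mrna_de, xt_pairs)
  tsv(xt$table, "crosstab.tsv")
  tsv(xt$pairs, "crosstab_pairs.tsv")

  enr <- NULL
  if (!is.null(config$category_map) && file.exists(config$category_map)) {
    cmap <- utils::read.delim(config$category_map,
                              stringsAsFactors = FALSE)
    up_srnas <- srna_de$feature_id[srna_de$call == "up"]
    up_as <- intersect(up_srnas, xt_pairs$srna_id[xt_pairs$primary])
    targets <- unique(xt_pairs$gene_id[xt_pairs$primary &
                                         xt_pairs$srna_id %in% up_as])
    universe <- mrna_de$feature_id
    if (length(targets)) {
      enr <- hypergeom_enrichment(targets, cmap, universe)
      tsv(enr, "enrichment.tsv")
    }
  }

  ## promoter motifs --------------------------------------------------
  models <- default_motif_models(bre_centroid = config$bre_centroid,
                                 tata_centroid = config$tata_centroid,
                                 tolerance = config$centroid_tolerance)
  scan_tx <- tx[tx$transcript_id %in% pass_any, , drop = FALSE]
  scans <- scan_promoters(genome_seq, scan_tx, models,
                          upstream = config$window_upstream,
                          downstream = config$window_downstream)
  tsv(scans, "promoter_scans.tsv")
  frac <- fraction_with_promoter(scans, models,
                                 relaxed_shift = config$relaxed_shift)

  ## report -----------------------------------------------------------
  count_by_class <- function(cond) {
    f <- filters[[cond]]
    passed <- f[f$pass, ]
    as.list(table(factor(passed$srna_class,
                         c("antisense", "intergenic"))))
  }
  ov <- cl$pairs$overlap_nt[cl$pairs$primary &
                              cl$pairs$srna_id %in% asrna_pass]
  report <- list(
    parameters = config[setdiff(names(config),
                                c("annotation", "transcripts", "counts",
                                  "samples", "genome", "category_map",
                                  "outdir"))],
    inputs = list(
      annotation = unname(tools::md5sum(config$annotation)),
      transcripts = unname(tools::md5sum(config$transcripts)),
      counts = unname(tools::md5sum(config$counts)),
      genome = unname(tools::md5sum(config$genome))),
    n_transcripts = nrow(tx),
    class_counts = as.list(table(classes$srna_class)),
    srna_counts_by_condition = stats::setNames(
      lapply(conditions, count_by_class), conditions),
    binding_regions = as.list(table(factor(
      cl$pairs$binding_region[cl$pairs$primary &
                                cl$pairs$srna_id %in% asrna_pass],
      c("5UTR", "3UTR", "CDS")))),
    overlap_stats = if (length(ov)) {
      os <- overlap_stats(ov)
      list(n = os$n, median_nt = os$median_nt, mean_nt = os$mean_nt,
           min_nt = os$min_nt, max_nt = os$max_nt)
    } else NULL,
    pair_test_summary = as.list(pt$summary),
    de_summary = list(
      srna = as.list(table(factor(srna_de$call, c("up", "down", "ns")))),
      mrna = as.list(table(factor(mrna_de$call, c("up", "down", "ns"))))),
    crosstab = list(n_pairs = xt$n_pairs, discordant = xt$discordant,
                    discordant_fraction = xt$discordant_fraction),
    enrichment_top = if (!is.null(enr))
      list(category = enr$category[1], p_value = enr$p_value[1],
           fdr_q = enr$fdr_q[1]) else NULL,
    promoters = list(
      n_scanned = frac$n, strict_fraction = frac$strict,
      relaxed_fraction = frac$relaxed,
      BRE_centroid = motif_centroid(scans, "BRE")[c("n", "centroid")],
      TATA_centroid = motif_centroid(scans, "TATA")[c("n", "centroid")])
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(report)
}

#' Audit a pipeline report against its stage artifacts
#'
#' Recomputes every summary count and fraction in `report.json` from the
#' stage TSVs written alongside it and checks equality.
#'
#' @param outdir a pipeline output directory.
#' @return `TRUE` invisibly if the audit passes; otherwise an error
#'   naming the first mismatching field.
#' @export
audit_report <- function(outdir) {
  rpt <- jsonlite::read_json(file.path(outdir, "report.json"),
                             simplifyVector = TRUE)
  rd <- function(f) utils::read.delim(file.path(outdir, f),
                                      stringsAsFactors = FALSE)
  classes <- rd("classes.tsv")
  pairs <- rd("cis_pairs.tsv")
  pair_tests <- rd("pair_tests.tsv")
  de <- rd("de.tsv")
  xt_pairs <- rd("crosstab_pairs.tsv")

  chk <- function(field, expected, got) {
    if (!isTRUE(all.equal(unname(expected), unname(got),
                          tolerance = 1e-8)))
      stop("report audit failed at '", field, "': report ", expected,
           " vs recomputed ", got, call. = FALSE)
  }
  cc <- table(classes$srna_class)
  for (k in names(rpt$class_counts))
    chk(paste0("class_counts.", k), rpt$class_counts[[k]],
        as.integer(cc[[k]]))
  chk("n_transcripts", rpt$n_transcripts, nrow(classes))
  chk("pair_test_summary.srna_higher", rpt$pair_test_summary$srna_higher,
      sum(pair_tests$significant & pair_tests$direction == "srna_higher"))
  chk("pair_test_summary.target_higher",
      rpt$pair_test_summary$target_higher,
      sum(pair_tests$significant & pair_tests$direction == "target_higher"))
  chk("pair_test_summary.not_significant",
      rpt$pair_test_summary$not_significant, sum(!pair_tests$significant))
  srna_ids <- classes$transcript_id[classes$srna_class %in%
                                      c("antisense", "intergenic")]
  srna_de <- de[de$feature_id %in% srna_ids, ]
  for (k in c("up", "down", "ns"))
    chk(paste0("de_summary.srna.", k), rpt$de_summary$srna[[k]],
        sum(srna_de$call == k))
  disc <- sum(xt_pairs$srna_call == "up" & xt_pairs$target_call == "down") +
    sum(xt_pairs$srna_call == "down" & xt_pairs$target_call == "up")
  chk("crosstab.n_pairs", rpt$crosstab$n_pairs, nrow(xt_pairs))
  chk("crosstab.discordant", rpt$crosstab$discordant, disc)
  if (rpt$crosstab$n_pairs > 0)
    chk("crosstab.discordant_fraction", rpt$crosstab$discordant_fraction,
        disc / nrow(xt_pairs))
  scans <- rd("promoter_scans.tsv")
  chk("promoters.n_scanned", rpt$promoters$n_scanned, nrow(scans))
  invisible(TRUE)
}
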