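test_that("all generators are byte-deterministic under a fixed seed", {
  p <- sim_params(seed = 5L)
  g1 <- simulate_genome(p); g2 <- simulate_genome(p)
  expect_identical(g1$annotation$genes, g2$annotation$genes)
  expect_identical(g1$sequence, g2$sequence)

  s1 <- plant_srnas(g1$annotation, p); s2 <- plant_srnas(g2$annotation, p)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$truth, s2$truth)

  c1 <- simulate_counts(g1$annotation, s1$transcripts, s1$truth, p)
  c2 <- simulate_counts(g1$annotation, s1$transcripts, s1$truth, p)
  expect_identical(c1$counts$counts, c2$counts$counts)

  m1 <- plant_motifs(g1$sequence, s1$transcripts, c1$truth, p)
  m2 <- plant_motifs(g1$sequence, s1$transcripts, c1$truth, p)
  expect_identical(m1$sequence, m2$sequence)

  # different seeds give different data
  g3 <- simulate_genome(sim_params(seed = 6L))
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("empty genome is valid: no genes, pure background sequence", {
  p <- sim_params(n_genes = 0L, replicon_length = 1000L)
  g <- simulate_genome(p)
  expect_equal(nrow(g$annotation$genes), 0L)
  expect_equal(nchar(g$sequence[["chr1"]]), 1000L)
})

test_that("generated genes never overlap (brute-force pairwise check)", {
  for (seed in 1:200) {
    gen <- simulate_genome(sim_params(
      n_genes = sample(2:30, 1), replicon_length = 120000L, seed = seed),
      with_sequence = FALSE)
    g <- gen$annotation$genes
    if (nrow(g) < 2) next
    for (i in 1:(nrow(g) - 1)) {
      ov <- srnascape:::overlap_len(g$start[i], g$end[i],
                                    g$start[(i + 1):nrow(g)],
                                    g$end[(i + 1):nrow(g)])
      expect_true(all(ov == 0L))
    }
  }
})

test_that("infeasible packing errors with advice", {
  expect_error(simulate_genome(sim_params(n_genes = 50L,
                                          replicon_length = 5000L)),
               "replicon_length")
})

test_that("planted asRNAs are always on the strand opposite their target", {
  for (seed in 1:10) {
    p <- sim_params(seed = seed)
    gen <- simulate_genome(p, with_sequence = FALSE)
    pl <- plant_srnas(gen$annotation, p)
    cis <- pl$truth$cis_target_of
    tx <- pl$transcripts
    g <- gen$annotation$genes
    ts <- setNames(tx$strand, tx$transcript_id)
    gs <- setNames(g$strand, g$gene_id)
    expect_true(all(ts[cis$srna_id] != gs[cis$gene_id]))
  }
})

test_that("classification recovers every planted class exactly", {
  for (seed in 1:10) {
    p <- sim_params(seed = seed)
    gen <- simulate_genome(p, with_sequence = FALSE)
    pl <- plant_srnas(gen$annotation, p)
    cl <- classify_transcripts(pl$transcripts, gen$annotation,
                               min_overlap = p$min_overlap)
    got <- setNames(cl$classes$srna_class, cl$classes$transcript_id)
    truth <- pl$truth$class_of
    expect_equal(unname(got[truth == "antisense"]),
                 rep("antisense", sum(truth == "antisense")))
    expect_equal(unname(got[truth == "intergenic"]),
                 rep("intergenic", sum(truth == "intergenic")))
    expect_equal(unname(got[truth == "decoy_sense"]),
                 rep("excluded_sense", sum(truth == "decoy_sense")))
    expect_equal(unname(got[truth == "decoy_subthreshold"]),
                 rep("excluded_subthreshold",
                     sum(truth == "decoy_subthreshold")))
  }
})

test_that("intended binding regions match binned output in >= 99% of plants", {
  n_match <- 0L; n_total <- 0L
  for (seed in 1:40) {
    p <- sim_params(seed = seed)
    gen <- simulate_genome(p, with_sequence = FALSE)
    pl <- plant_srnas(gen$annotation, p)
    cl <- classify_transcripts(pl$transcripts, gen$annotation)
    m <- merge(pl$truth$cis_target_of, cl$pairs[cl$pairs$primary, ],
               by = "srna_id")
    expect_true(all(m$gene_id.x == m$gene_id.y))
    n_match <- n_match + sum(m$intended_region == m$binding_region)
    n_total <- n_total + nrow(m)
  }
  expect_gte(n_match / n_total, 0.99)
})

test_that("simulated counts match the NB moments they were drawn from", {
  # alpha -> 0: variance/mean ratio -> 1 (Poisson limit)
  p0 <- sim_params(seed = 71L, nb_dispersion = 1e-8)
  set.seed(71)
  mu <- 200
  draws <- rnbinom(10000, mu = mu, size = 1 / p0$nb_dispersion)
  expect_lt(abs(var(draws) / mean(draws) - 1), 0.05)

  # requested mean recovered within 3 SE over >= 5000 draws
  p <- sim_params(seed = 73L, nb_dispersion = 0.05)
  n <- 5000
  mu <- 150
  draws <- withr::with_seed(73, rnbinom(n, mu = mu, size = 1 / 0.05))
  se <- sqrt((mu + 0.05 * mu^2) / n)
  expect_lt(abs(mean(draws) - mu), 3 * se)

  # marginal check through the generator itself: per-feature mean across
  # samples scales with the planted base expression
  params <- sim_params(seed = 79L, n_replicates = 30L,
                       low_expr_fraction = 0, de_fraction = 0,
                       anti_corr_fraction = 0,
                       library_scale_range = c(1, 1))
  gen <- simulate_genome(params, with_sequence = FALSE)
  pl <- plant_srnas(gen$annotation, params)
  sim <- simulate_counts(gen$annotation, pl$transcripts, pl$truth, params)
  cm <- sim$counts
  expected <- sim$truth$base_expression[rownames(cm$counts)] *
    cm$lengths[rownames(cm$counts)] / 1000 * params$count_scale
  obs <- rowMeans(cm$counts)
  sel <- expected > 50
  se_mu <- sqrt((expected + params$nb_dispersion * expected^2) /
                  ncol(cm$counts))
  expect_gt(mean(abs(obs[sel] - expected[sel]) <= 3 * se_mu[sel]), 0.95)
})

test_that("sub-threshold expression decoys are removed by the filter", {
  p <- sim_params(seed = 83L, low_expr_fraction = 0.2)
  gen <- simulate_genome(p)
  pl <- plant_srnas(gen$annotation, p)
  sim <- simulate_counts(gen$annotation, pl$transcripts, pl$truth, p)
  cl <- classify_transcripts(pl$transcripts, gen$annotation)
  keep <- cl$classes$srna_class %in% c("antisense", "intergenic")
  classes <- setNames(cl$classes$srna_class[keep],
                      cl$classes$transcript_id[keep])
  tpm_mat <- tpm(sim$counts)
  for (cond in c("control", "stress")) {
    fl <- filter_srnas(tpm_mat, classes, sim$counts$samples, cond)
    tier <- sim$truth$expression_tier[fl$feature_id]
    expect_true(all(!fl$pass[tier == "low"]))
  }
})

test_that("planted truth is self-consistent under brute-force re-derivation", {
  p <- sim_params(seed = 89L)
  gen <- simulate_genome(p, with_sequence = FALSE)
  pl <- plant_srnas(gen$annotation, p)
  g <- gen$annotation$genes
  for (i in seq_len(nrow(pl$truth$cis_target_of))) {
    row <- pl$truth$cis_target_of[i, ]
    t1 <- pl$transcripts[pl$transcripts$transcript_id == row$srna_id, ]
    brute <- brute_classify(t1, g, p$min_overlap)
    expect_equal(brute$class, "antisense")
    expect_true(row$gene_id %in% names(brute$overlaps))
    expect_equal(brute_region(t1, g[g$gene_id == row$gene_id, ]),
                 row$intended_region)
  }
})

test_that("motif planting is strand-aware", {
  p <- sim_params(seed = 97L, motif_fraction = 1)
  ds <- simulate_dataset(p)
  pos <- ds$truth$motif_positions
  tx <- ds$transcripts
  models <- default_motif_models()
  for (i in seq_len(min(nrow(pos), 30))) {
    row <- pos[i, ]
    t1 <- tx[tx$transcript_id == row$srna_id, ]
    m <- models[[row$motif]]
    tss <- if (t1$strand == "+") t1$start else t1$end
    w <- extract_window(ds$sequence, t1$chrom, tss, t1$strand)
    # the consensus string must sit at the planted offset in the
    # transcription-direction window, whatever the strand
    start_in_window <- (row$center - m$width %/% 2) - w$rel_start + 1L
    expect_equal(substr(w$seq, start_in_window,
                        start_in_window + m$width - 1L), m$consensus)
  }
})
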