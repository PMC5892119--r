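test_that("window extraction follows the TSS-relative convention", {
  seq <- paste(rep("ACGT", 500), collapse = "")  # 2000 bp
  genome <- c(chr1 = seq)

  w <- extract_window(genome, "chr1", 500, "+", 100, 100)
  expect_equal(w$rel_start, -100L)
  expect_equal(nchar(w$seq), 200L)
  expect_equal(w$seq, substr(seq, 401, 600))
  expect_false(w$truncated)

  wm <- extract_window(genome, "chr1", 500, "-", 100, 100)
  expect_equal(nchar(wm$seq), 200L)
  # reverse complement of genomic (400, 600); rel -1 is genomic base 500
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seq, 401, 600))))
  expect_equal(wm$seq, rc)
  expect_equal(wm$rel_start, -100L)
  up1 <- substr(wm$seq, 100, 100)  # rel -1
  expect_equal(up1, c(A = "T", C = "G", G = "C", T = "A")[[
    substr(seq, 501, 501)]])

  wt <- extract_window(genome, "chr1", 20, "+", 100, 100)
  expect_true(wt$truncated)
  expect_equal(wt$rel_start, -20L)
  expect_equal(nchar(wt$seq), 120L)

  expect_error(extract_window(genome, "chr1", 3000, "+"), "outside")
  expect_error(extract_window(genome, "chr2", 10, "+"), "unknown replicon")
})

test_that("consensus strings hit at maximal score; ties pick most upstream", {
  model <- motif_model("TATA", "TTTATATA", -29L)
  bg <- paste(rep("C", 200), collapse = "")
  win <- list(seq = paste0(substr(bg, 1, 50), "TTTATATA",
                           substr(bg, 59, 200)),
              rel_start = -100L)
  hit <- scan_motif(win, model)
  expect_true(hit$hit)
  expect_equal(hit$center, -100L + 50L + 4L)
  expect_equal(hit$score, sum(apply(model$pwm, 2, max)), tolerance = 1e-9)

  # two identical occurrences: the upstream one is reported
  win2 <- list(seq = paste0("TTTATATA", substr(bg, 9, 100), "TTTATATA"),
               rel_start = -100L)
  expect_equal(scan_motif(win2, model)$center, -100L + 4L)

  short <- list(seq = "TTTA", rel_start = -2L)
  expect_equal(scan_motif(short, model)$flag, "window_too_short")
})

test_that("PWM scanning equals exhaustive per-offset scoring", {
  models <- default_motif_models()
  set.seed(47)
  for (i in 1:15) {
    win <- list(seq = paste(sample(c("A", "C", "G", "T"), 300,
                                   replace = TRUE), collapse = ""),
                rel_start = -150L)
    for (m in models) {
      scores <- brute_pwm_scores(win$seq, m$pwm)
      got <- scan_motif(win, m)
      best <- which.max(scores)
      if (scores[best] >= m$threshold) {
        expect_true(got$hit)
        expect_equal(got$center, win$rel_start + best - 1L + m$width %/% 2L)
        expect_equal(got$score, scores[best], tolerance = 1e-9)
      } else {
        expect_false(got$hit)
      }
    }
  }
})

test_that("IUPAC degeneracy is honoured: any matching string passes", {
  model <- motif_model("BRE", "RNWAAW", -38L)
  for (s in c("GATAAA", "ACAAAT", "GGTAAT")) {
    win <- list(seq = paste0(paste(rep("C", 40), collapse = ""), s,
                             paste(rep("C", 40), collapse = "")),
                rel_start = -50L)
    expect_true(scan_motif(win, model)$hit)
  }
  nonmatch <- list(seq = paste0(paste(rep("C", 40), collapse = ""), "TTTTTT",
                                paste(rep("C", 40), collapse = "")),
                   rel_start = -50L)
  expect_false(scan_motif(nonmatch, model)$hit)
})

test_that("centroid summarises hit centres", {
  scans <- data.frame(srna_id = c("a", "b"),
                      TATA_hit = c(TRUE, TRUE),
                      TATA_center = c(-29L, -29L),
                      TATA_score = c(5, 5))
  c1 <- motif_centroid(scans, "TATA")
  expect_equal(c1$centroid, -29)
  expect_equal(c1$sd, 0)
  scans$TATA_center <- c(-27L, -31L)
  expect_equal(motif_centroid(scans, "TATA")$centroid, -29)
  scans$TATA_center <- NA_integer_
  expect_equal(motif_centroid(scans, "TATA")$n, 0L)
})

test_that("planted motifs are recovered: centroid, fraction, strand symmetry", {
  params <- sim_params(seed = 53L, motif_fraction = 0.3)
  ds <- simulate_dataset(params)
  planted_ids <- names(ds$truth$class_of)[ds$truth$class_of %in%
                                            c("antisense", "intergenic")]
  tx <- ds$transcripts[ds$transcripts$transcript_id %in% planted_ids, ]
  models <- default_motif_models()
  scans <- scan_promoters(ds$sequence, tx, models)

  expect_lt(abs(motif_centroid(scans, "BRE")$centroid - (-38)), 1)
  expect_lt(abs(motif_centroid(scans, "TATA")$centroid - (-29)), 1)
  fr <- fraction_with_promoter(scans, models)
  expect_lt(abs(fr$strict - 0.30), 0.05)
  expect_gte(fr$relaxed, fr$strict)

  # strand symmetry: reverse-complement the genome, flip all coordinates
  L <- nchar(ds$sequence[["chr1"]])
  rc_genome <- c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ds$sequence[["chr1"]]))))
  tx_rc <- tx
  tx_rc$start <- L - tx$end
  tx_rc$end <- L - tx$start
  tx_rc$strand <- ifelse(tx$strand == "+", "-", "+")
  scans_rc <- scan_promoters(rc_genome, tx_rc, models)
  expect_equal(scans_rc$BRE_center, scans$BRE_center)
  expect_equal(scans_rc$TATA_center, scans$TATA_center)
})

test_that("no planted motifs means only background hits", {
  params <- sim_params(seed = 59L, motif_fraction = 0)
  ds <- simulate_dataset(params)
  planted_ids <- names(ds$truth$class_of)[ds$truth$class_of %in%
                                            c("antisense", "intergenic")]
  tx <- ds$transcripts[ds$transcripts$transcript_id %in% planted_ids, ]
  models <- default_motif_models()
  scans <- scan_promoters(ds$sequence, tx, models)
  fr <- fraction_with_promoter(scans, models)
  # the octamer consensus has a ~1.5e-5 per-offset match rate; a joint
  # positioned double hit by chance is essentially impossible
  expect_lt(fr$strict, 0.05)
  expect_gte(fr$relaxed, fr$strict)
})

test_that("widening tolerance never lowers the promoter fraction", {
  params <- sim_params(seed = 61L)
  ds <- simulate_dataset(params)
  planted_ids <- names(ds$truth$class_of)[ds$truth$class_of %in%
                                            c("antisense", "intergenic")]
  tx <- ds$transcripts[ds$transcripts$transcript_id %in% planted_ids, ]
  models <- default_motif_models()
  scans <- scan_promoters(ds$sequence, tx, models)
  prev <- -1
  for (extra in c(0L, 2L, 5L, 10L)) {
    fr <- fraction_with_promoter(scans, models, relaxed_shift = extra)
    expect_gte(fr$relaxed, fr$strict)
    expect_gte(fr$relaxed, prev)
    prev <- fr$relaxed
  }
})

test_that("FASTA round-trips through Biostrings wrappers", {
  seqs <- c(chr1 = "ACGTACGTAA", plasmid = "GGGCCCATAT")
  path <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(seqs, path)
  expect_equal(read_genome_fasta(path), seqs)
})
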