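test_that("GFF3 1-based inclusive coordinates become 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 1000",
    "chr1\tsrc\tgene\t101\t500\t.\t+\t.\tID=g1",
    "chr1\tsrc\tCDS\t101\t500\t.\t+\t.\tID=g1.c;Parent=g1"
  ), path)
  ann <- read_annotation(path)
  expect_equal(ann$genes$start, 100L)
  expect_equal(ann$genes$end, 500L)
  expect_equal(ann$genes$strand, "+")
  expect_equal(unname(ann$replicon_lengths["chr1"]), 1000L)
  expect_true(is.na(ann$genes$utr5_start))
  expect_true(is.na(ann$genes$utr3_start))
})

test_that("duplicate gene ids and malformed lines are rejected", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t200\t300\t.\t+\t.\tID=g1"
  ), path)
  expect_error(read_annotation(path), "duplicate gene_id")

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tgene\t1\t100"), bad)
  expect_error(read_annotation(bad), "line 2")
})

test_that("gene with UTR children populates all sub-intervals and round-trips", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 5000",
    "chr1\tsrc\tgene\t101\t500\t.\t+\t.\tID=g1;product=thing",
    "chr1\tsrc\tfive_prime_UTR\t101\t130\t.\t+\t.\tID=g1.u5;Parent=g1",
    "chr1\tsrc\tCDS\t131\t470\t.\t+\t.\tID=g1.c;Parent=g1",
    "chr1\tsrc\tthree_prime_UTR\t471\t500\t.\t+\t.\tID=g1.u3;Parent=g1"
  ), path)
  ann <- read_annotation(path)
  g <- ann$genes
  expect_equal(g$utr5_start, 100L)
  expect_equal(g$utr5_end, 130L)
  expect_equal(g$cds_start, 130L)
  expect_equal(g$cds_end, 470L)
  expect_equal(g$utr3_start, 470L)
  expect_equal(g$utr3_end, 500L)

  out <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, out)
  again <- read_annotation(out)
  expect_equal(again$genes, ann$genes)
  expect_equal(again$replicon_lengths, ann$replicon_lengths)
})

test_that("annotation write/read is the identity on random genomes", {
  for (seed in 1:5) {
    gen <- simulate_genome(sim_params(n_genes = 25L, seed = seed),
                           with_sequence = FALSE)
    out <- withr::local_tempfile(fileext = ".gff3")
    write_annotation_gff3(gen$annotation, out)
    back <- read_annotation(out)
    expect_equal(back$genes, gen$annotation$genes)
    expect_equal(back$replicon_lengths, gen$annotation$replicon_lengths)
  }
})

test_that("GTF transcript coordinates convert and round-trip; order kept", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tasm\ttranscript\t1\t100\t.\t-\t.\tgene_id "t1"; transcript_id "t1";'
  ), path)
  tx <- read_transcripts(path)
  expect_equal(tx$start, 0L)
  expect_equal(tx$end, 100L)
  expect_equal(tx$length_nt, 100L)
  expect_equal(tx$strand, "-")

  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(), empty)
  expect_equal(nrow(read_transcripts(empty)), 0L)

  set.seed(42)
  n <- 50
  rnd <- data.frame(
    transcript_id = sprintf("t%02d", 1:n), chrom = "chr1",
    start = as.integer(sort(sample(1:10000, n))), stringsAsFactors = FALSE)
  rnd$end <- rnd$start + sample(50:500, n, replace = TRUE)
  rnd$strand <- sample(c("+", "-"), n, replace = TRUE)
  rnd$length_nt <- rnd$end - rnd$start
  out <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts_gtf(rnd, out)
  expect_equal(read_transcripts(out), rnd)
})

test_that("multi-exon transcripts are rejected as unsupported", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tasm\texon\t1\t100\t.\t+\t.\tgene_id "t1"; transcript_id "t1";',
    'chr1\tasm\texon\t200\t300\t.\t+\t.\tgene_id "t1"; transcript_id "t1";'
  ), path)
  expect_error(read_transcripts(path), "multi-exon")
})

test_that("sRNA GFF stores class attributes and round-trips", {
  srnas <- data.frame(
    transcript_id = c("a1", "i1"), chrom = "chr1",
    start = c(100L, 900L), end = c(500L, 1000L), strand = c("+", "-"),
    srna_class = c("antisense", "intergenic"),
    cis_target = c("gX", NA), binding_region = c("CDS", NA),
    overlap_nt = c(200L, NA), stringsAsFactors = FALSE)
  out <- withr::local_tempfile(fileext = ".gff3")
  write_srna_gff(srnas, out)
  lines <- readLines(out)
  expect_match(lines[2], "\t101\t500\t")  # back to 1-based inclusive
  back <- read_srna_gff(out)
  expect_equal(back, srnas)

  empty_out <- withr::local_tempfile(fileext = ".gff3")
  write_srna_gff(srnas[0, ], empty_out)
  expect_equal(readLines(empty_out), "##gff-version 3")
})

test_that("invalid intervals and strands are rejected at construction", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 10L,
                      end = 10L, strand = "+", cds_start = 10L,
                      cds_end = 10L, stringsAsFactors = FALSE)
  expect_error(genome_annotation(genes, c(chr1 = 100L)), "end must be > start")
  genes$end <- 50L; genes$cds_end <- 50L; genes$strand <- "*"
  expect_error(genome_annotation(genes, c(chr1 = 100L)), "strand")
  genes$strand <- "+"; genes$end <- 200L; genes$cds_end <- 200L
  expect_error(genome_annotation(genes, c(chr1 = 100L)), "beyond replicon")
})

test_that("indexed overlap queries match a brute-force scan", {
  for (seed in 1:20) {
    case <- random_case(seed)
    genes <- case$ann$genes
    set.seed(seed + 1000)
    q <- data.frame(chrom = "chr1",
                    start = sample(0:59000, 20), stringsAsFactors = FALSE)
    q$end <- q$start + sample(10:2000, 20, replace = TRUE)
    q$strand <- sample(c("+", "-"), 20, replace = TRUE)
    qg <- srnascape:::as_granges0(q)
    gg <- srnascape:::as_granges0(genes)
    hits <- GenomicRanges::findOverlaps(qg, gg, ignore.strand = TRUE)
    idx <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    for (i in seq_len(nrow(q))) {
      brute <- which(vapply(seq_len(nrow(genes)), function(j)
        length(intersect(bases_of(q$start[i], q$end[i]),
                         bases_of(genes$start[j], genes$end[j]))) > 0,
        logical(1)))
      got <- sort(unname(idx[[as.character(i)]]))
      expect_equal(if (is.null(got)) integer() else got, brute)
    }
  }
})
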