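# Independent oracles and tiny fixture builders. Everything here is
# deliberately naive (per-base set arithmetic, exhaustive enumeration)
# so it cannot share bugs with the interval-indexed implementation.

# per-base membership of a half-open interval
bases_of <- function(start, end) if (end > start) seq(start, end - 1L) else integer()

# Brute-force per-base classification of one transcript against a gene
# table, mirroring the documented rules by counting shared bases.
brute_classify <- function(t1, genes, min_overlap = 8L) {
  tb <- bases_of(t1$start, t1$end)
  same_ov <- 0L
  anti <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != t1$chrom) next
    ov <- length(intersect(tb, bases_of(g$start, g$end)))
    if (ov == 0) next
    if (g$strand == t1$strand) same_ov <- same_ov + ov
    else anti[[g$gene_id]] <- ov
  }
  if (same_ov > 0) return(list(class = "excluded_sense"))
  if (!length(anti)) return(list(class = "intergenic"))
  mx <- max(unlist(anti))
  if (mx < min_overlap) return(list(class = "excluded_subthreshold"))
  targets <- names(anti)[unlist(anti) >= min_overlap]
  list(class = "antisense", overlaps = unlist(anti)[targets])
}

# Per-base binding-region binning for one transcript/gene pair.
brute_region <- function(t1, g) {
  tb <- bases_of(t1$start, t1$end)
  u5 <- if (!is.na(g$utr5_start))
    length(intersect(tb, bases_of(g$utr5_start, g$utr5_end))) else 0L
  u3 <- if (!is.na(g$utr3_start))
    length(intersect(tb, bases_of(g$utr3_start, g$utr3_end))) else 0L
  cd <- length(intersect(tb, bases_of(g$cds_start, g$cds_end)))
  shares <- c("5UTR" = u5, "3UTR" = u3, "CDS" = cd)
  names(which.max(shares[c("5UTR", "3UTR", "CDS")]))
}

# Exhaustive hypergeometric upper tail via the pmf written out in
# binomial coefficients (no phyper anywhere).
brute_hyper_upper <- function(k, K, N, n) {
  lo <- max(0L, n - (N - K)); hi <- min(K, n)
  pmf <- vapply(lo:hi, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1))
  sum(pmf[(lo:hi) >= k])
}

# Naive per-offset PWM scorer: returns the score vector.
brute_pwm_scores <- function(seq, pwm) {
  w <- ncol(pwm)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars) - w + 1L
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(w)) {
      b <- chars[i + j - 1L]
      if (!b %in% rownames(pwm)) return(-Inf)
      s <- s + pwm[b, j]
    }
    s
  }, numeric(1))
}

# A small hand-built annotation: one + gene with both UTRs, one - gene
# with both UTRs, one leaderless + gene.
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    start = c(100L, 1000L, 2000L),
    end = c(500L, 1400L, 2300L),
    strand = c("+", "-", "+"),
    cds_start = c(130L, 1040L, 2000L),
    cds_end = c(470L, 1360L, 2250L),
    utr5_start = c(100L, 1360L, NA),
    utr5_end = c(130L, 1400L, NA),
    utr3_start = c(470L, 1000L, 2250L),
    utr3_end = c(500L, 1040L, 2300L),
    product = c("alpha", "beta", "gamma"),
    stringsAsFactors = FALSE
  )
  genome_annotation(genes, c(chr1 = 5000L))
}

tx_row <- function(id, start, end, strand, chrom = "chr1") {
  data.frame(transcript_id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             length_nt = as.integer(end - start), stringsAsFactors = FALSE)
}

# Random small genome + transcripts for property tests.
random_case <- function(seed, n_genes_max = 20L) {
  params <- sim_params(
    n_genes = sample(3:n_genes_max, 1),
    replicon_length = 60000L,
    n_asrna = 3L, n_intergenic = 2L, n_decoy_sense = 2L,
    n_decoy_subthreshold = 2L, seed = seed)
  gen <- simulate_genome(params, with_sequence = FALSE)
  pl <- plant_srnas(gen$annotation, params)
  list(ann = gen$annotation, tx = pl$transcripts, truth = pl$truth,
       params = params)
}

# Deterministic small count matrix.
toy_counts <- function() {
  counts <- matrix(c(10L, 20L, 5L, 40L, 12L, 18L), nrow = 3,
                   dimnames = list(c("f1", "f2", "f3"), c("s1", "s2")))
  count_matrix(counts, c(f1 = 100L, f2 = 400L, f3 = 200L),
               data.frame(sample = c("s1", "s2"),
                          condition = c("control", "stress"),
                          replicate = c(1L, 1L)))
}
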