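# Seeded synthetic-data generator. Emulates the study design the
# pipeline is built for: a compact archaeal-style genome, a two-condition
# (control vs oxidative stress) experiment with 5 replicate libraries per
# condition, planted antisense/intergenic sRNAs with known cis targets
# and binding regions, negative-binomial counts with planted fold changes
# (including anti-correlated cis pairs), deliberate library-depth
# heterogeneity, and BRE/TATA promoter motifs planted at fixed
# TSS-relative offsets. Every planted fact is recorded in a ground-truth
# object so downstream stages can be scored exactly.

#' Parameters of the synthetic dataset generator
#'
#' Defaults mirror the study design the pipeline targets: 5 replicates
#' per condition, a minimum antisense overlap of 8 nt, binding regions in
#' roughly 7/26/67 proportions (5' UTR / 3' UTR / CDS), sRNA lengths of
#' 50-1000 nt, most mRNAs leaderless, 30% of sRNAs given BRE/TATA motifs
#' centred at -38 and -29, and a quarter of cis pairs planted with
#' anti-correlated fold changes.
#'
#' @param n_genes number of genes.
#' @param replicon_length replicon size in bp.
#' @param cds_length_range,utr_length_range CDS / UTR length ranges (nt).
#' @param leaderless_fraction fraction of genes without a 5' UTR.
#' @param utr3_fraction fraction of genes with an annotated 3' UTR.
#' @param min_gap minimum intergenic gap (nt).
#' @param n_asrna,n_intergenic planted antisense / intergenic sRNA counts.
#' @param n_decoy_sense,n_decoy_subthreshold planted decoys:
#'   sense-overlapping transcripts (excluded as confounded) and
#'   opposite-strand transcripts overlapping fewer than `min_overlap` nt.
#' @param srna_length_range sRNA length range (nt).
#' @param region_props target proportions of 5' UTR / 3' UTR / CDS
#'   binding regions among planted asRNAs.
#' @param min_overlap antisense overlap threshold (nt).
#' @param n_replicates replicates per condition.
#' @param conditions condition labels (reference first).
#' @param nb_mean_range base-expression range (log-uniform draw,
#'   arbitrary abundance units that become TPM after normalisation).
#' @param nb_dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param count_scale global scale from abundance to expected counts.
#' @param library_scale_range per-sample depth multipliers are drawn
#'   log-uniformly over this range (2-fold spread by default) so
#'   size-factor estimation is non-trivial.
#' @param low_expr_fraction fraction of planted sRNAs given sub-threshold
#'   expression (these must be removed by the TPM filter).
#' @param low_expr_mean base expression of the low tier.
#' @param anti_corr_fraction fraction of asRNA cis pairs planted with
#'   opposite-sign fold changes (sRNA up, target down).
#' @param de_fraction fraction of the remaining features given a
#'   condition fold change.
#' @param lfc_magnitude absolute planted log2 fold change.
#' @param motif_fraction fraction of planted sRNAs receiving promoter
#'   motifs.
#' @param motif_offsets named integer vector of TSS-relative motif-centre
#'   positions (upstream negative).
#' @param seed base random seed; sub-stages use fixed offsets from it.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_genes = 60L,
                       replicon_length = 200000L,
                       cds_length_range = c(300L, 1500L),
                       utr_length_range = c(20L, 60L),
                       leaderless_fraction = 0.6,
                       utr3_fraction = 0.9,
                       min_gap = 80L,
                       n_asrna = 40L,
                       n_intergenic = 15L,
                       n_decoy_sense = 8L,
                       n_decoy_subthreshold = 8L,
                       srna_length_range = c(50L, 1000L),
                       region_props = c("5UTR" = 0.07, "3UTR" = 0.26,
                                        "CDS" = 0.67),
                       min_overlap = 8L,
                       n_replicates = 5L,
                       conditions = c("control", "stress"),
                       nb_mean_range = c(20, 2000),
                       nb_dispersion = 0.05,
                       count_scale = 2,
                       library_scale_range = c(2^-0.5, 2^0.5),
                       low_expr_fraction = 0.15,
                       low_expr_mean = 0.2,
                       anti_corr_fraction = 0.25,
                       de_fraction = 0.2,
                       lfc_magnitude = 2,
                       motif_fraction = 0.30,
                       motif_offsets = c(BRE = -38L, TATA = -29L),
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$n_genes >= 0, p$replicon_length >= 1,
            p$nb_dispersion > 0,
            p$anti_corr_fraction >= 0, p$anti_corr_fraction <= 1,
            p$motif_fraction >= 0, p$motif_fraction <= 1,
            p$low_expr_fraction >= 0, p$low_expr_fraction <= 1,
            p$min_overlap >= 1, p$n_replicates >= 2,
            length(p$conditions) == 2)
  if (abs(sum(p$region_props) - 1) > 1e-9)
    stop("region_props must sum to 1", call. = FALSE)
  class(p) <- "sim_params"
  p
}

#' Simulate an annotated genome
#'
#' Places `n_genes` non-overlapping genes with at least `min_gap` nt
#' between neighbours on random strands. Each gene has a CDS; a
#' configurable fraction is leaderless (no 5' UTR) and most carry a 3'
#' UTR. The background sequence is uniform random. Fully deterministic
#' under the seed.
#'
#' @param params a [sim_params()].
#' @param seed random seed (default derived from `params$seed`).
#' @param with_sequence set `FALSE` to skip sequence generation when only
#'   the annotation is needed.
#' @return list: `annotation` (a [genome_annotation()]) and `sequence`
#'   (named character vector, `NULL` when skipped).
#' @export
simulate_genome <- function(params = sim_params(), seed = params$seed,
                            with_sequence = TRUE) {
  withr::with_seed(seed, {
    n <- params$n_genes
    L <- params$replicon_length
    chrom <- "chr1"

    if (n > 0) {
      cds_len <- sample(params$cds_length_range[1]:params$cds_length_range[2],
                        n, replace = TRUE)
      has5 <- stats::runif(n) >= params$leaderless_fraction
      has3 <- stats::runif(n) < params$utr3_fraction
      u5 <- ifelse(has5, sample(params$utr_length_range[1]:
                                  params$utr_length_range[2],
                                n, replace = TRUE), 0L)
      u3 <- ifelse(has3, sample(params$utr_length_range[1]:
                                  params$utr_length_range[2],
                                n, replace = TRUE), 0L)
      glen <- cds_len + u5 + u3
      needed <- sum(glen) + (n + 1L) * params$min_gap
      if (sum(glen) > L / 2 || needed > L)
        stop("cannot pack ", n, " genes into ", L,
             " bp; increase replicon_length", call. = FALSE)
      # distribute the leftover space over n+1 gaps, each >= min_gap
      slack <- L - sum(glen) - (n + 1L) * params$min_gap
      w <- stats::rexp(n + 1L)
      extra <- floor(slack * w / sum(w))
      gaps <- params$min_gap + extra
      starts <- cumsum(c(gaps[1], if (n > 1) glen[-n] + gaps[2:n]))
      strand <- sample(STRANDS, n, replace = TRUE)

      # sub-feature layout along the genome depends on strand: the 5'
      # UTR is upstream in transcription direction
      left_u <- ifelse(strand == "+", u5, u3)
      right_u <- ifelse(strand == "+", u3, u5)
      genes <- data.frame(
        gene_id = sprintf("GENE_%04d", seq_len(n)),
        chrom = chrom, start = starts, end = starts + glen,
        strand = strand,
        cds_start = starts + left_u, cds_end = starts + left_u + cds_len,
        utr5_start = ifelse(u5 > 0,
                            ifelse(strand == "+", starts,
                                   starts + left_u + cds_len),
                            NA_integer_),
        utr5_end = ifelse(u5 > 0,
                          ifelse(strand == "+", starts + u5,
                                 starts + glen),
                          NA_integer_),
        utr3_start = ifelse(u3 > 0,
                            ifelse(strand == "+", starts + left_u + cds_len,
                                   starts),
                            NA_integer_),
        utr3_end = ifelse(u3 > 0,
                          ifelse(strand == "+", starts + glen,
                                 starts + u3),
                          NA_integer_),
        product = sprintf("hypothetical protein %04d", seq_len(n)),
        stringsAsFactors = FALSE
      )
    } else {
      genes <- data.frame(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), cds_start = integer(),
                          cds_end = integer(), stringsAsFactors = FALSE)
    }
    ann <- genome_annotation(genes, stats::setNames(L, chrom))
    seqs <- if (with_sequence) {
      stats::setNames(paste(sample(DNA_BASES, L, replace = TRUE),
                            collapse = ""), chrom)
    } else NULL
    list(annotation = ann, sequence = seqs)
  })
}

# distance from a gene's edges to its nearest neighbours (any strand),
# used to clip sRNA extensions so they stay clear of other genes
.free_space <- function(genes, i) {
  g <- genes[i, ]
  others <- genes[-i, , drop = FALSE]
  others <- others[others$chrom == g$chrom, , drop = FALSE]
  left_lim <- suppressWarnings(max(others$end[others$end <= g$start], 0L))
  right_all <- others$start[others$start >= g$end]
  right_lim <- if (length(right_all)) min(right_all) else NA_integer_
  list(left = g$start - left_lim, right_lim = right_lim)
}

#' Plant sRNA transcripts with known classes
#'
#' Plants four transcript populations: antisense sRNAs opposite randomly
#' chosen genes with the overlap confined to an intended binding region
#' (5' UTR / 3' UTR / CDS in `region_props` proportions) and any length
#' excess extended away from the gene; intergenic sRNAs strictly between
#' genes; sense-overlapping decoys (same strand as a gene, must be
#' excluded by classification); and sub-threshold decoys whose
#' opposite-strand overlap is below `min_overlap`.
#'
#' @param ann annotation from [simulate_genome()].
#' @param params a [sim_params()].
#' @param seed random seed.
#' @return list: `transcripts` (data.frame as in [read_transcripts()])
#'   and `truth` (list with `class_of`, `cis_target_of`,
#'   `expression_tier`).
#' @export
plant_srnas <- function(ann, params = sim_params(), seed = params$seed + 1L) {
  genes <- ann$genes
  L <- ann$replicon_lengths[[1]]
  chrom <- names(ann$replicon_lengths)[1]
  withr::with_seed(seed, {
    tx <- list(); truth_class <- character(); cis <- list()

    ## --- antisense sRNAs ---------------------------------------------
    if (params$n_asrna > nrow(genes))
      stop("n_asrna exceeds the number of genes; no room to place",
           call. = FALSE)
    regions <- sample(names(params$region_props), params$n_asrna,
                      replace = TRUE, prob = params$region_props)
    available <- seq_len(nrow(genes))
    for (i in seq_len(params$n_asrna)) {
      reg <- regions[i]
      ok <- switch(reg,
                   "5UTR" = available[!is.na(genes$utr5_start[available])],
                   "3UTR" = available[!is.na(genes$utr3_start[available])],
                   "CDS" = available)
      if (!length(ok)) { ok <- available; reg <- "CDS" }
      gi <- if (length(ok) == 1) ok else sample(ok, 1)
      available <- setdiff(available, gi)
      g <- genes[gi, ]
      len <- sample(params$srna_length_range[1]:params$srna_length_range[2], 1)
      free <- .free_space(genes, gi)
      gap_left <- free$left
      gap_right <- if (is.na(free$right_lim)) L - g$end
                   else free$right_lim - g$end

      if (reg == "CDS") {
        ov <- min(len, g$cds_end - g$cds_start)
        off <- sample.int(g$cds_end - g$cds_start - ov + 1L, 1) - 1L
        s0 <- g$cds_start + off; e0 <- s0 + ov
      } else {
        rs <- if (reg == "5UTR") g$utr5_start else g$utr3_start
        re <- if (reg == "5UTR") g$utr5_end else g$utr3_end
        # outward side: away from the CDS, past the gene boundary
        outward_right <- (re == g$end)
        ov <- min(len, re - rs)
        ext <- min(len - ov,
                   max(0L, (if (outward_right) gap_right else gap_left) - 1L))
        if (outward_right) { s0 <- re - ov; e0 <- re + ext }
        else { s0 <- rs - ext; e0 <- rs + ov }
      }
      s0 <- max(0L, s0); e0 <- min(L, e0)
      id <- sprintf("ASRNA_%03d", i)
      tx[[id]] <- data.frame(transcript_id = id, chrom = chrom,
                             start = as.integer(s0), end = as.integer(e0),
                             strand = setdiff(STRANDS, g$strand),
                             stringsAsFactors = FALSE)
      truth_class[id] <- "antisense"
      cis[[id]] <- data.frame(srna_id = id, gene_id = g$gene_id,
                              intended_region = reg,
                              stringsAsFactors = FALSE)
    }

    ## --- intergenic sRNAs --------------------------------------------
    gs <- genes[order(genes$start), , drop = FALSE]
    gap_start <- c(0L, gs$end)
    gap_end <- c(gs$start, L)
    usable <- which(gap_end - gap_start >= params$srna_length_range[1] + 2L)
    if (params$n_intergenic > 0 && !length(usable))
      stop("no intergenic gap can host an sRNA; increase replicon_length",
           call. = FALSE)
    for (i in seq_len(params$n_intergenic)) {
      gpi <- usable[(i - 1L) %% length(usable) + 1L]
      lo <- gap_start[gpi] + 1L; hi <- gap_end[gpi] - 1L
      len <- min(hi - lo,
                 sample(params$srna_length_range[1]:
                          params$srna_length_range[2], 1))
      s0 <- lo + sample.int(hi - lo - len + 1L, 1) - 1L
      id <- sprintf("IRNA_%03d", i)
      tx[[id]] <- data.frame(transcript_id = id, chrom = chrom,
                             start = as.integer(s0),
                             end = as.integer(s0 + len),
                             strand = sample(STRANDS, 1),
                             stringsAsFactors = FALSE)
      truth_class[id] <- "intergenic"
    }

    ## --- decoys -------------------------------------------------------
    for (i in seq_len(params$n_decoy_sense)) {
      gi <- sample.int(nrow(genes), 1)
      g <- genes[gi, ]
      len <- min(g$end - g$start,
                 sample(params$srna_length_range[1]:
                          params$srna_length_range[2], 1))
      s0 <- g$start + sample.int(g$end - g$start - len + 1L, 1) - 1L
      id <- sprintf("DSENSE_%02d", i)
      tx[[id]] <- data.frame(transcript_id = id, chrom = chrom,
                             start = as.integer(s0),
                             end = as.integer(s0 + len),
                             strand = g$strand, stringsAsFactors = FALSE)
      truth_class[id] <- "decoy_sense"
    }
    for (i in seq_len(params$n_decoy_subthreshold)) {
      gi <- sample.int(nrow(genes), 1)
      g <- genes[gi, ]
      ov <- sample.int(params$min_overlap - 1L, 1)
      free <- .free_space(genes, gi)
      gap_right <- if (is.na(free$right_lim)) L - g$end
                   else free$right_lim - g$end
      ext <- min(params$srna_length_range[1] - ov + 40L,
                 max(1L, gap_right - 1L))
      id <- sprintf("DSUB_%02d", i)
      tx[[id]] <- data.frame(transcript_id = id, chrom = chrom,
                             start = as.integer(g$end - ov),
                             end = as.integer(min(L, g$end + ext)),
                             strand = setdiff(STRANDS, g$strand),
                             stringsAsFactors = FALSE)
      truth_class[id] <- "decoy_subthreshold"
    }

    transcripts <- do.call(rbind, tx)
    rownames(transcripts) <- NULL
    transcripts$length_nt <- transcripts$end - transcripts$start
    cis_df <- if (length(cis)) do.call(rbind, cis) else
      data.frame(srna_id = character(), gene_id = character(),
                 intended_region = character(), stringsAsFactors = FALSE)
    rownames(cis_df) <- NULL

    # expression tiers: a fraction of planted sRNAs is sub-threshold;
    # asRNAs reserved for anti-correlated pairs stay in the high tier
    planted <- names(truth_class)[truth_class %in%
                                    c("antisense", "intergenic")]
    n_anti <- round(params$anti_corr_fraction * params$n_asrna)
    anti_ids <- utils::head(cis_df$srna_id, n_anti)
    eligible_low <- setdiff(planted, anti_ids)
    n_low <- min(length(eligible_low),
                 floor(params$low_expr_fraction * length(planted)))
    low_ids <- if (n_low) sample(eligible_low, n_low) else character()
    tier <- stats::setNames(rep("high", length(truth_class)),
                            names(truth_class))
    tier[low_ids] <- "low"

    list(transcripts = transcripts,
         truth = list(class_of = truth_class,
                      cis_target_of = cis_df,
                      anti_corr_ids = anti_ids,
                      expression_tier = tier))
  })
}

#' Simulate replicate NB count matrices with planted fold changes
#'
#' Draws counts NB(mu, alpha) independently per feature and sample with
#' mu = library_scale x base_expression x (length/1000) x count_scale x
#' 2^(lfc x stress). Base expressions are log-uniform; low-tier sRNAs get
#' `low_expr_mean`. The planted anti-correlated cis pairs receive (sRNA
#' +lfc, target -lfc) at high expression; a `de_fraction` of the
#' remaining features receives a random-sign fold change. Per-sample
#' library scales are drawn over a two-fold range so depth normalisation
#' is exercised.
#'
#' @param ann annotation (provides gene lengths).
#' @param transcripts planted transcript table.
#' @param truth truth list from [plant_srnas()].
#' @param params a [sim_params()].
#' @param seed random seed.
#' @param planted_lfc optional named vector overriding the generated
#'   fold-change assignment.
#' @return list: `counts` (a [count_matrix()]) and `truth` extended with
#'   `true_lfc`, `library_scales`, `base_expression`.
#' @export
simulate_counts <- function(ann, transcripts, truth,
                            params = sim_params(),
                            seed = params$seed + 2L,
                            planted_lfc = NULL) {
  genes <- ann$genes
  feat <- data.frame(
    feature_id = c(genes$gene_id, transcripts$transcript_id),
    length_nt = c(genes$end - genes$start, transcripts$length_nt),
    stringsAsFactors = FALSE
  )
  withr::with_seed(seed, {
    nf <- nrow(feat)
    base <- exp(stats::runif(nf, log(params$nb_mean_range[1]),
                             log(params$nb_mean_range[2])))
    names(base) <- feat$feature_id
    low <- names(truth$expression_tier)[truth$expression_tier == "low"]
    base[low] <- params$low_expr_mean

    if (is.null(planted_lfc)) {
      lfc <- stats::setNames(rep(0, nf), feat$feature_id)
      anti <- truth$anti_corr_ids
      cis <- truth$cis_target_of
      anti_targets <- cis$gene_id[match(anti, cis$srna_id)]
      lfc[anti] <- params$lfc_magnitude
      lfc[anti_targets] <- -params$lfc_magnitude
      # anti-correlated pair members must be well expressed to be
      # detectable at the planted effect size
      hi <- c(anti, anti_targets)
      base[hi] <- pmax(base[hi], 500)
      rest <- setdiff(feat$feature_id, c(anti, anti_targets, low))
      n_de <- round(params$de_fraction * length(rest))
      de_ids <- if (n_de) sample(rest, n_de) else character()
      lfc[de_ids] <- sample(c(-1, 1), length(de_ids), replace = TRUE) *
        params$lfc_magnitude
    } else {
      lfc <- stats::setNames(rep(0, nf), feat$feature_id)
      lfc[names(planted_lfc)] <- planted_lfc
    }
    if (any(is.na(lfc))) stop("true_lfc undefined for some features",
                              call. = FALSE)

    conds <- rep(params$conditions, each = params$n_replicates)
    samples <- data.frame(
      sample = sprintf("%s_%d", conds,
                       rep(seq_len(params$n_replicates), 2)),
      condition = conds,
      replicate = rep(seq_len(params$n_replicates), 2),
      stringsAsFactors = FALSE
    )
    lib <- exp(stats::runif(nrow(samples),
                            log(params$library_scale_range[1]),
                            log(params$library_scale_range[2])))
    names(lib) <- samples$sample

    stress <- as.integer(samples$condition == params$conditions[2])
    mu <- outer(base * feat$length_nt / 1000 * params$count_scale,
                lib) * 2^(lfc %o% stress)
    if (any(mu < 0)) stop("negative NB mean", call. = FALSE)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / params$nb_dispersion),
                     nrow = nrow(feat),
                     dimnames = list(feat$feature_id, samples$sample))
    cm <- count_matrix(counts,
                       stats::setNames(feat$length_nt, feat$feature_id),
                       samples)
    truth$true_lfc <- lfc
    truth$library_scales <- lib
    truth$base_expression <- base
    list(counts = cm, truth = truth)
  })
}

#' Plant promoter motifs upstream of sRNA TSSs
#'
#' Writes each motif's consensus string into the genome sequence so that
#' its centre sits at the configured TSS-relative offset, strand-aware
#' (reverse complement upstream in transcription direction for
#' minus-strand sRNAs), for a `motif_fraction` of the planted sRNAs.
#'
#' @param genome_seq named character vector of replicon sequences.
#' @param transcripts planted transcript table.
#' @param truth truth list (motif recipients are drawn from planted
#'   antisense/intergenic sRNAs).
#' @param params a [sim_params()].
#' @param models motif models to plant (consensus must be concrete).
#' @param seed random seed.
#' @param upstream,downstream extraction window; offsets must fall inside
#'   it.
#' @return list: `sequence` (modified), `truth` extended with
#'   `motif_ids` (recipients) and `motif_positions`.
#' @export
plant_motifs <- function(genome_seq, transcripts, truth,
                         params = sim_params(),
                         models = default_motif_models(
                           bre_centroid = params$motif_offsets[["BRE"]],
                           tata_centroid = params$motif_offsets[["TATA"]]),
                         seed = params$seed + 3L,
                         upstream = 100L, downstream = 100L) {
  for (m in models) {
    off <- params$motif_offsets[[m$name]]
    if (is.null(off)) stop("no offset for motif ", m$name, call. = FALSE)
    if (off - m$width %/% 2 < -upstream ||
        off + (m$width - m$width %/% 2) > downstream)
      stop("motif ", m$name, " offset ", off,
           " falls outside the extraction window", call. = FALSE)
  }
  planted <- names(truth$class_of)[truth$class_of %in%
                                     c("antisense", "intergenic")]
  withr::with_seed(seed, {
    n_with <- round(params$motif_fraction * length(planted))
    # A recipient's motifs must not fall inside any other candidate's
    # scan window, or the recorded truth would be ambiguous (a motif
    # planted for one sRNA would appear, mispositioned, in a
    # neighbour's promoter scan).
    ptx <- transcripts[match(planted, transcripts$transcript_id), ]
    tss_all <- ifelse(ptx$strand == "+", ptx$start, ptx$end)
    win_lo <- tss_all - max(upstream, downstream)
    win_hi <- tss_all + max(upstream, downstream)
    span <- max(abs(params$motif_offsets)) +
      max(vapply(models, function(m) m$width, integer(1)))
    candidates <- sample(planted)
    chosen <- character()
    for (id in candidates) {
      if (length(chosen) >= n_with) break
      i <- match(id, planted)
      lo <- tss_all[i] - span; hi <- tss_all[i] + span
      # all planted sRNAs are scanned downstream, so check against the
      # window of every other candidate
      clash <- any(win_hi[-i] > lo & win_lo[-i] < hi)
      if (!clash) chosen <- c(chosen, id)
    }
    chosen <- sort(chosen)

    seqs <- genome_seq
    pos <- list()
    for (id in chosen) {
      t1 <- transcripts[transcripts$transcript_id == id, ]
      tss <- if (t1$strand == "+") t1$start else t1$end
      L <- nchar(seqs[[t1$chrom]])
      ok <- TRUE
      for (m in models) {
        off <- params$motif_offsets[[m$name]]
        start_rel <- off - m$width %/% 2L
        if (t1$strand == "+") {
          g0 <- tss + start_rel
          g1 <- g0 + m$width
          motif <- m$consensus
        } else {
          g1 <- tss - start_rel
          g0 <- g1 - m$width
          motif <- .revcomp(m$consensus)
        }
        if (g0 < 0 || g1 > L) { ok <- FALSE; next }
        substr(seqs[[t1$chrom]], g0 + 1L, g1) <- motif
        pos[[length(pos) + 1L]] <- data.frame(
          srna_id = id, motif = m$name, center = off,
          stringsAsFactors = FALSE)
      }
      if (!ok) chosen <- setdiff(chosen, id)  # edge sRNA: not planted
    }
    truth$motif_ids <- chosen
    pos_df <- if (length(pos)) do.call(rbind, pos) else
      data.frame(srna_id = character(), motif = character(),
                 center = integer(), stringsAsFactors = FALSE)
    truth$motif_positions <- pos_df[pos_df$srna_id %in% chosen, ,
                                    drop = FALSE]
    list(sequence = seqs, truth = truth)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_genome()], [plant_srnas()], [simulate_counts()] and
#' [plant_motifs()] in sequence, plus a synthetic functional category map
#' in which the targets of anti-correlated asRNAs are enriched for one
#' category (`"transposase"`), giving the enrichment stage a planted
#' signal.
#'
#' @param params a [sim_params()].
#' @return list: `annotation`, `sequence`, `transcripts`, `counts`,
#'   `category_map` (data.frame `gene_id`, `category`), `truth`.
#' @export
simulate_dataset <- function(params = sim_params()) {
  gen <- simulate_genome(params)
  pl <- plant_srnas(gen$annotation, params)
  cnt <- simulate_counts(gen$annotation, pl$transcripts, pl$truth, params)
  mot <- plant_motifs(gen$sequence, pl$transcripts, cnt$truth, params)

  truth <- mot$truth
  genes <- gen$annotation$genes
  cats <- c("transporter", "metabolism", "hypothetical")
  cat_map <- withr::with_seed(params$seed + 4L, {
    assigned <- sample(cats, nrow(genes), replace = TRUE)
    names(assigned) <- genes$gene_id
    cis <- truth$cis_target_of
    anti_targets <- cis$gene_id[cis$srna_id %in% truth$anti_corr_ids]
    assigned[anti_targets] <- "transposase"
    # background members so the category is not identical to the target set
    bg <- sample(setdiff(genes$gene_id, anti_targets),
                 max(1L, round(0.05 * nrow(genes))))
    assigned[bg] <- "transposase"
    data.frame(gene_id = names(assigned), category = unname(assigned),
               stringsAsFactors = FALSE)
  })
  truth$enriched_category <- "transposase"
  list(annotation = gen$annotation, sequence = mot$sequence,
       transcripts = pl$transcripts, counts = cnt$counts,
       category_map = cat_map, truth = truth)
}
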