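#' Classify assembled transcripts into sRNA classes
#'
#' Strand-aware classification against a gene annotation. A transcript is
#' called `antisense` when it overlaps at least `min_overlap` nt of one or
#' more genes (full gene span, UTRs included) on the opposite strand and no
#' gene on its own strand; `intergenic` when it overlaps no gene on either
#' strand; `excluded_sense` when it overlaps a same-strand gene (such
#' cis-internal transcripts are confounded with the gene's own signal and
#' are not classifiable from coverage alone); and
#' `excluded_subthreshold` when its largest opposite-strand overlap is
#' positive but below `min_overlap`. Antisense takes precedence over
#' intergenic: a transcript that overlaps an opposite-strand gene and also
#' extends into intergenic space is antisense.
#'
#' @param tx transcript data.frame (`transcript_id`, `chrom`, `start`,
#'   `end`, `strand`; 0-based half-open).
#' @param ann a [genome_annotation()].
#' @param min_overlap minimum antisense overlap in nt (default 8).
#' @return list with `classes` (one row per transcript: `transcript_id`,
#'   `srna_class`, `n_targets`, and the primary target's `cis_target`,
#'   `overlap_nt`, `binding_region`, `NA` for non-antisense) and `pairs`
#'   (all cis pairs, see [find_cis_targets()]).
#' @export
classify_transcripts <- function(tx, ann, min_overlap = 8L) {
  stopifnot(inherits(ann, "genome_annotation"))
  min_overlap <- as.integer(min_overlap)
  if (is.na(min_overlap) || min_overlap < 1L)
    stop("min_overlap must be >= 1", call. = FALSE)
  unknown <- setdiff(unique(tx$chrom), names(ann$replicon_lengths))
  if (length(unknown))
    stop("transcript(s) on unknown replicon(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  n <- nrow(tx)
  cls <- rep("intergenic", n)
  genes <- ann$genes
  pairs_list <- vector("list", n)

  if (n && nrow(genes)) {
    txg <- as_granges0(tx)
    gg <- as_granges0(genes)
    hits <- GenomicRanges::findOverlaps(txg, gg, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- overlap_len(tx$start[qh], tx$end[qh], genes$start[sh], genes$end[sh])
    same <- tx$strand[qh] == genes$strand[sh]

    sense_hit <- unique(qh[same & ov > 0])
    cls[sense_hit] <- "excluded_sense"

    anti <- !same & ov > 0
    max_anti <- tapply(ov[anti], qh[anti], max)
    anti_ids <- as.integer(names(max_anti))
    anti_ids <- setdiff(anti_ids, sense_hit)
    cls[anti_ids[max_anti[as.character(anti_ids)] >= min_overlap]] <- "antisense"
    cls[anti_ids[max_anti[as.character(anti_ids)] < min_overlap]] <-
      "excluded_subthreshold"

    for (i in which(cls == "antisense")) {
      gi <- sh[qh == i & anti]
      keep <- overlap_len(tx$start[i], tx$end[i],
                          genes$start[gi], genes$end[gi]) >= min_overlap
      pairs_list[[i]] <- .cis_pairs_for(tx[i, ], genes[gi[keep], , drop = FALSE])
    }
  }

  pairs <- do.call(rbind, pairs_list[!vapply(pairs_list, is.null, TRUE)])
  if (is.null(pairs)) pairs <- .empty_pairs()
  rownames(pairs) <- NULL

  prim <- pairs[pairs$primary, , drop = FALSE]
  m <- match(tx$transcript_id, prim$srna_id)
  classes <- data.frame(
    transcript_id = tx$transcript_id,
    srna_class = cls,
    n_targets = as.integer(table(factor(pairs$srna_id,
                                        levels = tx$transcript_id))),
    cis_target = prim$gene_id[m],
    overlap_nt = prim$overlap_nt[m],
    binding_region = prim$binding_region[m],
    stringsAsFactors = FALSE
  )
  list(classes = classes, pairs = pairs)
}

.empty_pairs <- function() {
  data.frame(srna_id = character(), gene_id = character(),
             overlap_nt = integer(), utr5_nt = integer(), cds_nt = integer(),
             utr3_nt = integer(), binding_region = character(),
             primary = logical(), stringsAsFactors = FALSE)
}

# One CisPair row per opposite-strand gene, descending overlap (gene_id
# breaks ties for determinism); the primary target is the largest overlap.
.cis_pairs_for <- function(t1, genes) {
  if (!nrow(genes)) return(NULL)
  ov <- overlap_len(t1$start, t1$end, genes$start, genes$end)
  u5 <- ifelse(is.na(genes$utr5_start), 0L,
               overlap_len(t1$start, t1$end, genes$utr5_start, genes$utr5_end))
  cd <- overlap_len(t1$start, t1$end, genes$cds_start, genes$cds_end)
  u3 <- ifelse(is.na(genes$utr3_start), 0L,
               overlap_len(t1$start, t1$end, genes$utr3_start, genes$utr3_end))
  out <- data.frame(
    srna_id = t1$transcript_id, gene_id = genes$gene_id,
    overlap_nt = ov, utr5_nt = u5, cds_nt = cd, utr3_nt = u3,
    binding_region = bin_binding_region(u5, cd, u3),
    primary = FALSE, stringsAsFactors = FALSE
  )
  out <- out[order(-out$overlap_nt, out$gene_id), , drop = FALSE]
  out$primary[1] <- TRUE
  out
}

#' Find cis mRNA targets of an antisense sRNA
#'
#' One cis pair per opposite-strand gene with overlap of at least
#' `min_overlap` nt, sorted by descending overlap; the first is the
#' primary target. An asRNA spanning the gap between two adjacent
#' opposite-strand genes (3' UTR of one, 5' UTR of the next) yields two
#' pairs.
#'
#' @param asrna single-row transcript data.frame.
#' @param ann a [genome_annotation()].
#' @param min_overlap minimum overlap in nt.
#' @return data.frame of cis pairs: `srna_id`, `gene_id`, `overlap_nt`,
#'   per-region breakdown (`utr5_nt`, `cds_nt`, `utr3_nt`),
#'   `binding_region`, `primary`.
#' @export
find_cis_targets <- function(asrna, ann, min_overlap = 8L) {
  stopifnot(nrow(asrna) == 1)
  g <- ann$genes
  g <- g[g$chrom == asrna$chrom & g$strand != asrna$strand, , drop = FALSE]
  if (nrow(g)) {
    ov <- overlap_len(asrna$start, asrna$end, g$start, g$end)
    g <- g[ov >= min_overlap, , drop = FALSE]
  }
  out <- .cis_pairs_for(asrna, g)
  if (is.null(out)) .empty_pairs() else out
}

#' Bin a cis pair into its binding region
#'
#' The label is the gene region (5' UTR, CDS or 3' UTR) holding the
#' largest share of the overlap; ties break by precedence
#' 5' UTR > 3' UTR > CDS (UTR contact is the mechanistically informative
#' call). Vectorised over the three breakdown arguments.
#'
#' @param utr5_nt,cds_nt,utr3_nt per-region overlap in nt.
#' @return character vector in `{"5UTR", "3UTR", "CDS"}`.
#' @export
bin_binding_region <- function(utr5_nt, cds_nt, utr3_nt) {
  if (any(utr5_nt + cds_nt + utr3_nt == 0))
    stop("all-zero overlap breakdown cannot be binned", call. = FALSE)
  # precedence order for ties: 5' UTR, then 3' UTR, then CDS
  m <- cbind(utr5_nt, utr3_nt, cds_nt)
  c("5UTR", "3UTR", "CDS")[max.col(m, ties.method = "first")]
}

#' Summary statistics of sRNA-target overlap lengths
#'
#' Summarises primary-target overlap lengths: median (even counts average
#' the central pair), mean, range, and a histogram with 50-nt bins.
#'
#' @param overlaps integer vector of overlap lengths (nt), one per pair.
#' @return an `overlap_stats` list: `n`, `median_nt`, `mean_nt`, `min_nt`,
#'   `max_nt`, `histogram` (data.frame `bin_start`, `bin_end`, `count`).
#' @export
overlap_stats <- function(overlaps) {
  if (!length(overlaps)) stop("no overlaps supplied", call. = FALSE)
  breaks <- seq(0L, 50L * ceiling(max(overlaps) / 50), by = 50L)
  if (length(breaks) == 1L) breaks <- c(0L, 50L)
  counts <- table(cut(overlaps, breaks = breaks, right = FALSE,
                      include.lowest = FALSE))
  # right-open bins [b, b+50); overlaps are >= 1 so none fall at 0
  structure(list(
    n = length(overlaps),
    median_nt = stats::median(overlaps),
    mean_nt = mean(overlaps),
    min_nt = min(overlaps),
    max_nt = max(overlaps),
    histogram = data.frame(bin_start = utils::head(breaks, -1),
                           bin_end = breaks[-1],
                           count = as.integer(counts))
  ), class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf(
    "overlap_stats: n=%d, median=%g nt, mean=%.1f nt, range %d-%d nt\n",
    x$n, x$median_nt, x$mean_nt, x$min_nt, x$max_nt))
  invisible(x)
}
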