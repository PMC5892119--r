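#' Construct a genome annotation
#'
#' A `genome_annotation` holds strand-aware gene models for one or more
#' replicons. Each gene has a full span, a CDS, and optional 5'/3' UTRs
#' that abut the CDS on the strand-appropriate sides. Leaderless mRNAs —
#' the majority in haloarchaea — simply lack the 5' UTR. All coordinates
#' are 0-based half-open; GFF3/GTF I/O converts at the boundary.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `cds_start`, `cds_end`, `utr5_start`, `utr5_end`,
#'   `utr3_start`, `utr3_end` (UTR columns `NA` when absent) and optional
#'   `product`.
#' @param replicon_lengths named integer vector, replicon id -> length (bp).
#' @return a `genome_annotation` object.
#' @export
genome_annotation <- function(genes, replicon_lengths) {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "chrom", "start", "end", "strand",
                "cds_start", "cds_end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols))
    stop("genes table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (utr in c("utr5_start", "utr5_end", "utr3_start", "utr3_end"))
    if (is.null(genes[[utr]])) genes[[utr]] <- rep(NA_integer_, nrow(genes))
  if (is.null(genes$product)) genes$product <- rep(NA_character_, nrow(genes))
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  genes$cds_start <- as.integer(genes$cds_start)
  genes$cds_end <- as.integer(genes$cds_end)
  for (utr in c("utr5_start", "utr5_end", "utr3_start", "utr3_end"))
    genes[[utr]] <- as.integer(genes[[utr]])

  if (nrow(genes)) {
    if (anyDuplicated(genes$gene_id))
      stop("duplicate gene_id: ",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                 collapse = ", "), call. = FALSE)
    check_interval(genes$start, genes$end, "gene")
    check_strand(genes$strand, "gene")
    check_interval(genes$cds_start, genes$cds_end, "CDS")
    if (any(genes$cds_start < genes$start | genes$cds_end > genes$end))
      stop("CDS must lie within the gene span", call. = FALSE)
    bad_chrom <- setdiff(unique(genes$chrom), names(replicon_lengths))
    if (length(bad_chrom))
      stop("genes on unknown replicon(s): ",
           paste(bad_chrom, collapse = ", "), call. = FALSE)
    if (any(genes$end > replicon_lengths[genes$chrom]))
      stop("gene extends beyond replicon end", call. = FALSE)
    .check_utrs(genes)
  }
  structure(
    list(genes = genes,
         replicon_lengths = stats::setNames(as.integer(replicon_lengths),
                                            names(replicon_lengths))),
    class = "genome_annotation"
  )
}

# UTRs, when present, must abut the CDS on the strand-appropriate side
# and stay within the gene span. On '+' the 5' UTR precedes the CDS; on
# '-' it follows it (upstream in transcription direction).
.check_utrs <- function(genes) {
  has5 <- !is.na(genes$utr5_start)
  has3 <- !is.na(genes$utr3_start)
  if (any(has5)) {
    g <- genes[has5, ]
    check_interval(g$utr5_start, g$utr5_end, "5' UTR")
    up <- g$strand == "+"
    ok <- ifelse(up,
                 g$utr5_end == g$cds_start & g$utr5_start >= g$start,
                 g$utr5_start == g$cds_end & g$utr5_end <= g$end)
    if (!all(ok)) stop("5' UTR must abut the CDS upstream", call. = FALSE)
  }
  if (any(has3)) {
    g <- genes[has3, ]
    check_interval(g$utr3_start, g$utr3_end, "3' UTR")
    up <- g$strand == "+"
    ok <- ifelse(up,
                 g$utr3_start == g$cds_end & g$utr3_end <= g$end,
                 g$utr3_end == g$cds_start & g$utr3_start >= g$start)
    if (!all(ok)) stop("3' UTR must abut the CDS downstream", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(x$replicon_lengths), "replicon(s)\n")
  cat("  replicons:",
      paste0(names(x$replicon_lengths), " (", x$replicon_lengths, " bp)",
             collapse = ", "), "\n")
  invisible(x)
}

# Light structural validation of a 9-column GFF/GTF before handing the
# file to the importer, so malformed lines fail with a line number.
.check_nine_columns <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8)) {
    lineno <- which(body)[which(nf < 8)[1]]
    stop("malformed feature line (fewer than 9 columns) at line ", lineno,
         " of ", path, call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a genome annotation from GFF3 or GTF
#'
#' Gene features are linked to their `CDS`, `five_prime_UTR` and
#' `three_prime_UTR` children (by `Parent` in GFF3, by shared `gene_id` in
#' GTF). Genes lacking UTR children get zero-length (absent) UTRs; genes
#' lacking an explicit CDS take the full span as CDS. Replicon lengths come
#' from `##sequence-region` pragmas where present, otherwise from the
#' maximum feature end per replicon.
#'
#' @param path GFF3 or GTF file.
#' @param dialect `"gff3"` or `"gtf"`; default guessed from the extension.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(path, dialect = c("auto", "gff3", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  .check_nine_columns(path)
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  meta <- S4Vectors::mcols(gr)

  id_col <- if (dialect == "gtf") meta$gene_id else meta$ID
  parent <- if (dialect == "gtf") meta$gene_id else {
    p <- meta$Parent
    if (is.null(p)) rep(NA_character_, length(gr))
    else vapply(as.list(p), function(v) if (length(v)) v[[1]] else NA_character_, "")
  }

  is_gene <- meta$type == "gene"
  if (!any(is_gene)) stop("annotation contains no gene features", call. = FALSE)
  gidx <- which(is_gene)
  gene_id <- as.character(id_col[gidx])
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "),
         call. = FALSE)

  child_of <- function(type) {
    sel <- which(meta$type == type)
    stats::setNames(sel, as.character(parent[sel]))
  }
  cds_of <- child_of("CDS")
  utr5_of <- child_of("five_prime_UTR")
  utr3_of <- child_of("three_prime_UTR")

  s0 <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  e0 <- GenomicRanges::end(gr)
  pick <- function(map, ids) unname(map[match(ids, names(map))])
  ci <- pick(cds_of, gene_id); u5 <- pick(utr5_of, gene_id)
  u3 <- pick(utr3_of, gene_id)

  genes <- data.frame(
    gene_id = gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)[gidx]),
    start = s0[gidx], end = e0[gidx],
    strand = as.character(GenomicRanges::strand(gr)[gidx]),
    cds_start = ifelse(is.na(ci), s0[gidx], s0[ci]),
    cds_end = ifelse(is.na(ci), e0[gidx], e0[ci]),
    utr5_start = ifelse(is.na(u5), NA_integer_, s0[u5]),
    utr5_end = ifelse(is.na(u5), NA_integer_, e0[u5]),
    utr3_start = ifelse(is.na(u3), NA_integer_, s0[u3]),
    utr3_end = ifelse(is.na(u3), NA_integer_, e0[u3]),
    product = if (!is.null(meta$product)) as.character(meta$product[gidx])
              else NA_character_,
    stringsAsFactors = FALSE
  )

  # replicon lengths: ##sequence-region pragmas, else max feature end
  hdr <- grep("^##sequence-region", readLines(path, warn = FALSE),
              value = TRUE)
  sl <- tapply(e0, as.character(GenomicRanges::seqnames(gr)), max)
  sl <- stats::setNames(as.integer(sl), names(sl))
  if (length(hdr)) {
    parts <- strsplit(trimws(hdr), "\\s+")
    for (p in parts) sl[p[2]] <- as.integer(p[4])
  }
  genome_annotation(genes, sl)
}

#' Write a genome annotation to GFF3
#'
#' Emits `##sequence-region` pragmas, one `gene` feature per gene and
#' `CDS` / `five_prime_UTR` / `three_prime_UTR` children. Inverse of
#' [read_annotation()] (round trips exactly).
#'
#' @param ann a [genome_annotation()].
#' @param path output file.
#' @export
write_annotation_gff3 <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     names(ann$replicon_lengths), ann$replicon_lengths))
  fmt <- function(chrom, type, s0, e0, strand, attrs) {
    sprintf("%s\tsrnascape\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s0 + 1L, e0, strand, attrs)
  }
  esc <- function(x) gsub("([;=,\t])", "%", x)  # conservative attr escaping
  for (i in seq_len(nrow(g))) {
    attrs <- sprintf("ID=%s", g$gene_id[i])
    if (!is.na(g$product[i]))
      attrs <- paste0(attrs, ";product=", esc(g$product[i]))
    lines <- c(lines,
               fmt(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i], attrs),
               fmt(g$chrom[i], "CDS", g$cds_start[i], g$cds_end[i], g$strand[i],
                   sprintf("ID=%s.cds;Parent=%s", g$gene_id[i], g$gene_id[i])))
    if (!is.na(g$utr5_start[i]))
      lines <- c(lines, fmt(g$chrom[i], "five_prime_UTR",
                            g$utr5_start[i], g$utr5_end[i], g$strand[i],
                            sprintf("ID=%s.utr5;Parent=%s",
                                    g$gene_id[i], g$gene_id[i])))
    if (!is.na(g$utr3_start[i]))
      lines <- c(lines, fmt(g$chrom[i], "three_prime_UTR",
                            g$utr3_start[i], g$utr3_end[i], g$strand[i],
                            sprintf("ID=%s.utr3;Parent=%s",
                                    g$gene_id[i], g$gene_id[i])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read assembled transcripts from GTF
#'
#' Expects single-exon transcripts (unspliced, as in archaeal assemblies).
#' `transcript` features are read directly; if only `exon` features are
#' present, one exon per transcript is required, and a transcript with
#' more than one exon raises an unsupported-feature error.
#'
#' @param path GTF file.
#' @return data.frame with `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`, `length_nt` (0-based half-open coordinates), in file order.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  .check_nine_columns(path)
  n_body <- sum(!startsWith(readLines(path, warn = FALSE), "#") &
                  nzchar(readLines(path, warn = FALSE)))
  if (n_body == 0) {
    return(data.frame(transcript_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      length_nt = integer(), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  tid <- as.character(meta$transcript_id)

  ex <- type == "exon"
  if (any(ex)) {
    per_tx <- table(tid[ex])
    if (any(per_tx > 1))
      stop("multi-exon transcript(s) not supported: ",
           paste(names(per_tx)[per_tx > 1], collapse = ", "), call. = FALSE)
  }
  keep <- if (any(type == "transcript")) which(type == "transcript")
          else which(ex)
  tx <- data.frame(
    transcript_id = tid[keep],
    chrom = as.character(GenomicRanges::seqnames(gr)[keep]),
    start = GenomicRanges::start(gr)[keep] - 1L,
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr)[keep]),
    stringsAsFactors = FALSE
  )
  tx$length_nt <- tx$end - tx$start
  check_interval(tx$start, tx$end, "transcript")
  check_strand(tx$strand, "transcript")
  rownames(tx) <- NULL
  tx
}

#' Write transcripts to GTF
#'
#' Inverse of [read_transcripts()]: one `transcript` feature per record,
#' 1-based inclusive coordinates.
#'
#' @param tx transcript data.frame (see [read_transcripts()]).
#' @param path output file.
#' @export
write_transcripts_gtf <- function(tx, path) {
  lines <- sprintf(
    '%s\tsrnascape\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    tx$chrom, tx$start + 1L, tx$end, tx$strand, tx$transcript_id,
    tx$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write classified sRNAs to GFF3
#'
#' Stores the sRNA class and, for antisense sRNAs, the primary cis target,
#' binding region and overlap length as GFF3 attributes.
#'
#' @param srnas data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, `srna_class` and optional `cis_target`,
#'   `binding_region`, `overlap_nt`.
#' @param path output file.
#' @export
write_srna_gff <- function(srnas, path) {
  lines <- "##gff-version 3"
  if (nrow(srnas)) {
    attrs <- sprintf("ID=%s;srna_class=%s", srnas$transcript_id,
                     srnas$srna_class)
    if (!is.null(srnas$cis_target)) {
      has <- !is.na(srnas$cis_target)
      attrs[has] <- sprintf("%s;cis_target=%s;binding_region=%s;overlap_nt=%d",
                            attrs[has], srnas$cis_target[has],
                            srnas$binding_region[has],
                            as.integer(srnas$overlap_nt[has]))
    }
    lines <- c(lines, sprintf("%s\tsrnascape\tncRNA\t%d\t%d\t.\t%s\t.\t%s",
                              srnas$chrom, srnas$start + 1L, srnas$end,
                              srnas$strand, attrs))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read classified sRNAs back from GFF3
#'
#' @param path a file written by [write_srna_gff()].
#' @return data.frame mirroring the input of [write_srna_gff()].
#' @export
read_srna_gff <- function(path) {
  .check_nine_columns(path)
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  out <- data.frame(
    transcript_id = as.character(meta$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    srna_class = as.character(meta$srna_class),
    stringsAsFactors = FALSE
  )
  out$cis_target <- if (!is.null(meta$cis_target))
    as.character(meta$cis_target) else NA_character_
  out$binding_region <- if (!is.null(meta$binding_region))
    as.character(meta$binding_region) else NA_character_
  out$overlap_nt <- if (!is.null(meta$overlap_nt))
    as.integer(meta$overlap_nt) else NA_integer_
  rownames(out) <- NULL
  out
}
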