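# Basal promoter motif analysis: TSS-proximal window extraction, PWM
# scanning for the archaeal BRE and TATA box, centroid estimation and
# promoter-fraction summaries.
#
# TSS-relative convention: the TSS parameter is the transcript's 5'
# boundary in half-open coordinates (start for '+', end for '-').
# Position 0 is the first transcribed base, upstream positions are
# negative, and windows are reported 5'->3' in transcription direction.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Build a motif model from an IUPAC consensus
#'
#' The position weight matrix assigns probability (1 - soft) / |S| to
#' each base allowed at a position (S = the IUPAC set) and soft / (4 -
#' |S|) to the others, scored as log2 odds against a uniform background.
#' The default threshold is the score of any string matching the
#' consensus, so a scan hit is exactly an IUPAC match; lower thresholds
#' admit near-matches. The shipped defaults (see
#' [default_motif_models()]) are high-information octamers around the
#' purine-rich BRE core and the A/T-rich TATA box; for real genomes,
#' supply organism-specific consensus strings or matrices.
#'
#' @param name motif name.
#' @param consensus IUPAC consensus string.
#' @param expected_centroid expected TSS-relative position of the motif
#'   centre (upstream negative).
#' @param tolerance centroid tolerance in nt for promoter calls.
#' @param threshold log2-odds score threshold; default the minimal
#'   consensus-match score.
#' @param soft total probability spread over disallowed bases per
#'   position.
#' @return a `motif_model` list: `name`, `consensus`, `width`, `pwm`
#'   (4 x width log2-odds), `threshold`, `expected_centroid`, `tolerance`.
#' @export
motif_model <- function(name, consensus, expected_centroid,
                        tolerance = 3L, threshold = NULL, soft = 0.04) {
  letters_ <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters_, names(IUPAC_SETS))
  if (length(bad))
    stop("not IUPAC: ", paste(bad, collapse = ", "), call. = FALSE)
  w <- length(letters_)
  pwm <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
  min_match <- 0
  for (j in seq_len(w)) {
    allowed <- IUPAC_SETS[[letters_[j]]]
    k <- length(allowed)
    prob <- rep(if (k < 4) soft / (4 - k) else 0.25, 4)
    names(prob) <- DNA_BASES
    if (k < 4) prob[allowed] <- (1 - soft) / k
    pwm[, j] <- log2(prob / 0.25)
    min_match <- min_match + min(pwm[allowed, j])
  }
  if (is.null(threshold)) threshold <- min_match - 1e-9
  structure(list(name = name, consensus = toupper(consensus), width = w,
                 pwm = pwm, threshold = threshold,
                 expected_centroid = as.integer(expected_centroid),
                 tolerance = as.integer(tolerance)),
            class = "motif_model")
}

#' Default BRE and TATA promoter models
#'
#' Archaeal basal promoters carry a TATA box bound by TBP and, just
#' upstream, the purine-rich transcription-factor-B recognition element
#' (BRE). The defaults are high-specificity octamer consensus models
#' with expected centroids 38 nt (BRE) and 29 nt (TATA) upstream of the
#' TSS; both consensus and centroid are user-configurable.
#'
#' @param bre_centroid,tata_centroid expected TSS-relative centre
#'   positions.
#' @param tolerance centroid tolerance in nt.
#' @return named list of two [motif_model()]s.
#' @export
default_motif_models <- function(bre_centroid = -38L, tata_centroid = -29L,
                                 tolerance = 3L) {
  list(
    BRE = motif_model("BRE", "CGAAAGTT", bre_centroid, tolerance),
    TATA = motif_model("TATA", "TTTATATA", tata_centroid, tolerance)
  )
}

#' Extract a TSS-proximal window
#'
#' Returns the window from `upstream` nt before to `downstream` nt after
#' the TSS, 5'->3' in the transcript's transcription direction (reverse
#' complement of the genomic sequence for minus-strand transcripts),
#' truncated at replicon edges with the truncation recorded. The `tss`
#' argument is the transcript's 5' boundary in 0-based half-open
#' coordinates: its `start` on '+', its `end` on '-'.
#'
#' @param genome_seq named character vector (or `Biostrings::DNAStringSet`)
#'   of replicon sequences.
#' @param chrom replicon id.
#' @param tss TSS boundary coordinate (see above).
#' @param strand `"+"` or `"-"`.
#' @param upstream,downstream window half-widths in nt.
#' @return list: `seq` (character), `rel_start` (TSS-relative position of
#'   the window's first base, normally `-upstream`), `truncated`
#'   (logical).
#' @export
extract_window <- function(genome_seq, chrom, tss, strand,
                           upstream = 100L, downstream = 100L) {
  seqs <- .as_seq_vector(genome_seq)
  if (!chrom %in% names(seqs)) stop("unknown replicon: ", chrom,
                                    call. = FALSE)
  L <- nchar(seqs[[chrom]])
  check_strand(strand)
  if (tss < 0 || tss > L)
    stop("TSS outside replicon [0, ", L, "]", call. = FALSE)

  if (strand == "+") {
    g0 <- max(0L, tss - upstream)
    g1 <- min(L, tss + downstream)
    win <- substr(seqs[[chrom]], g0 + 1L, g1)
    rel_start <- g0 - tss
    truncated <- (tss - upstream < 0) || (tss + downstream > L)
  } else {
    # rel i maps to genomic base tss - 1 - i
    g0 <- max(0L, tss - downstream)
    g1 <- min(L, tss + upstream)
    win <- .revcomp(substr(seqs[[chrom]], g0 + 1L, g1))
    rel_start <- tss - g1
    truncated <- (tss + upstream > L) || (tss - downstream < 0)
  }
  list(seq = win, rel_start = as.integer(rel_start),
       truncated = truncated)
}

.as_seq_vector <- function(genome_seq) {
  if (methods::is(genome_seq, "DNAStringSet"))
    stats::setNames(as.character(genome_seq), names(genome_seq))
  else genome_seq
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a window with a motif model
#'
#' Slides the PWM over the window in the given orientation only (basal
#' promoter elements are directional relative to the TSS) and reports
#' the best-scoring offset if it reaches the model threshold; ties go to
#' the most-upstream position. The hit position is the TSS-relative
#' position of the motif centre (start + width %/% 2).
#'
#' @param window a window from [extract_window()] (or a list with `seq`
#'   and `rel_start`).
#' @param model a [motif_model()].
#' @return list: `hit` (logical), `center` (TSS-relative, `NA` if no
#'   hit), `score`, `flag` (`"ok"` or `"window_too_short"`).
#' @export
scan_motif <- function(window, model) {
  s <- toupper(window$seq)
  w <- model$width
  n <- nchar(s) - w + 1L
  if (n < 1L)
    return(list(hit = FALSE, center = NA_integer_, score = NA_real_,
                flag = "window_too_short"))
  x <- match(strsplit(s, "")[[1]], DNA_BASES)
  scores <- vapply(seq_len(n), function(i) {
    idx <- x[i:(i + w - 1L)]
    if (anyNA(idx)) return(-Inf)  # ambiguous base: never a hit
    sum(model$pwm[cbind(idx, seq_len(w))])
  }, numeric(1))
  best <- which.max(scores)      # ties: first (most upstream)
  if (scores[best] < model$threshold)
    return(list(hit = FALSE, center = NA_integer_, score = scores[best],
                flag = "ok"))
  list(hit = TRUE,
       center = window$rel_start + (best - 1L) + w %/% 2L,
       score = scores[best], flag = "ok")
}

#' Scan promoter windows of many sRNAs
#'
#' Extracts the upstream/downstream window around each sRNA's TSS and
#' scans it with every model.
#'
#' @param genome_seq replicon sequences (named vector or `DNAStringSet`).
#' @param tx transcript data.frame (`transcript_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param models list of [motif_model()]s (default
#'   [default_motif_models()]).
#' @param upstream,downstream window half-widths.
#' @return data.frame, one row per sRNA: `srna_id`, then per model
#'   `<name>_hit`, `<name>_center`, `<name>_score`.
#' @export
scan_promoters <- function(genome_seq, tx, models = default_motif_models(),
                           upstream = 100L, downstream = 100L) {
  tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  rows <- lapply(seq_len(nrow(tx)), function(i) {
    win <- extract_window(genome_seq, tx$chrom[i], tss[i], tx$strand[i],
                          upstream, downstream)
    row <- list(srna_id = tx$transcript_id[i])
    for (m in models) {
      hit <- scan_motif(win, m)
      row[[paste0(m$name, "_hit")]] <- hit$hit
      row[[paste0(m$name, "_center")]] <- hit$center
      row[[paste0(m$name, "_score")]] <- hit$score
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Centroid of motif hit positions
#'
#' Arithmetic mean (and sd) of the TSS-relative motif-centre positions
#' over sRNAs where the motif was found.
#'
#' @param scans output of [scan_promoters()].
#' @param motif_name model name (e.g. `"TATA"`).
#' @return list `n`, `centroid`, `sd`; `n = 0` with `NA`s when no hits.
#' @export
motif_centroid <- function(scans, motif_name) {
  centers <- scans[[paste0(motif_name, "_center")]]
  centers <- centers[!is.na(centers)]
  if (!length(centers))
    return(list(n = 0L, centroid = NA_real_, sd = NA_real_))
  list(n = length(centers), centroid = mean(centers),
       sd = if (length(centers) > 1) stats::sd(centers) else 0)
}

#' Fraction of sRNAs with a basal promoter
#'
#' An sRNA has a promoter when every model has a hit whose centre lies
#' within that model's tolerance of its expected centroid. The relaxed
#' mode widens each tolerance by `relaxed_shift` nt on both sides, so
#' the relaxed fraction can never fall below the strict one.
#'
#' @param scans output of [scan_promoters()].
#' @param models the models used for scanning.
#' @param relaxed_shift extra tolerance in nt for the relaxed call.
#' @return list: `n`, `strict` (fraction), `relaxed` (fraction),
#'   `strict_ids`, `relaxed_ids`.
#' @export
fraction_with_promoter <- function(scans, models, relaxed_shift = 3L) {
  n <- nrow(scans)
  ok <- function(extra) {
    all_ok <- rep(TRUE, n)
    for (m in models) {
      centers <- scans[[paste0(m$name, "_center")]]
      within <- !is.na(centers) &
        abs(centers - m$expected_centroid) <= m$tolerance + extra
      all_ok <- all_ok & within
    }
    all_ok
  }
  strict <- ok(0L); relaxed <- ok(relaxed_shift)
  list(n = n,
       strict = if (n) mean(strict) else 0,
       relaxed = if (n) mean(relaxed) else 0,
       strict_ids = scans$srna_id[strict],
       relaxed_ids = scans$srna_id[relaxed])
}

#' Read / write genome sequences as FASTA
#'
#' Thin wrappers over `Biostrings` keeping the package's plain character
#' representation (named vector of replicon sequences).
#'
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  .as_seq_vector(Biostrings::readDNAStringSet(path))
}

#' @rdname read_genome_fasta
#' @param seqs named character vector of sequences.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}
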