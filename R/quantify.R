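#' Construct a count matrix with sample metadata
#'
#' The central expression container: a non-negative integer matrix of
#' features (rows) by samples (columns), feature lengths in nt, and a
#' sample sheet giving each sample's condition and replicate index.
#'
#' @param counts integer matrix, features x samples, with rownames
#'   (feature ids) and colnames (sample ids).
#' @param lengths named integer vector of feature lengths (nt), one per
#'   row of `counts`.
#' @param samples data.frame with columns `sample`, `condition`,
#'   `replicate`; one row per column of `counts`.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, lengths, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have rownames (features) and colnames (samples)",
         call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(is.na(counts))) stop("counts must not contain NA", call. = FALSE)
  if (!setequal(names(lengths), rownames(counts)) ||
      length(lengths) != nrow(counts))
    stop("lengths must be named by the count matrix's features",
         call. = FALSE)
  lengths <- lengths[rownames(counts)]
  if (any(lengths < 1)) stop("feature lengths must be >= 1", call. = FALSE)
  req <- c("sample", "condition", "replicate")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!identical(as.character(samples$sample), colnames(counts)))
    stop("sample sheet rows must match count matrix columns in order",
         call. = FALSE)
  structure(list(counts = counts,
                 lengths = stats::setNames(as.numeric(lengths),
                                           names(lengths)),
                 samples = as.data.frame(samples)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("  conditions:",
      paste(sprintf("%s (n=%d)", names(table(x$samples$condition)),
                    table(x$samples$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Transcripts-per-million normalisation
#'
#' Per sample: each feature's count is divided by its length to give a
#' read rate, and rates are rescaled to sum to one million. TPM is
#' independent of the mean expressed transcript length, which matters
#' here because sRNAs are systematically shorter than mRNAs. Every
#' non-degenerate sample column sums to exactly 1e6 (up to floating
#' point); an all-zero sample yields an all-zero column with a warning.
#'
#' @param x a [count_matrix()], or a numeric matrix if `lengths` is given.
#' @param lengths feature lengths in nt (only when `x` is a bare matrix).
#' @return numeric matrix of TPM values, same dimnames as the input.
#' @export
tpm <- function(x, lengths = NULL) {
  if (inherits(x, "count_matrix")) {
    counts <- x$counts
    lengths <- x$lengths
  } else {
    counts <- as.matrix(x)
    if (is.null(lengths)) stop("lengths required for a bare matrix",
                               call. = FALSE)
    lengths <- lengths[rownames(counts)]
  }
  if (any(is.na(lengths)) || any(lengths < 1))
    stop("feature lengths must be >= 1 for every feature", call. = FALSE)
  rate <- counts / lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero sample(s): ",
            paste(colnames(counts)[zero], collapse = ", "))
    denom[zero] <- 1  # column stays all zero
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Per-condition mean and standard deviation of TPM
#'
#' @param tpm_mat TPM matrix (features x samples).
#' @param samples sample sheet (`sample`, `condition`, `replicate`).
#' @param condition condition to summarise.
#' @return data.frame `feature_id`, `mean_tpm`, `sd_tpm` (sample standard
#'   deviation, n-1 denominator).
#' @export
condition_summary <- function(tpm_mat, samples, condition) {
  cols <- samples$sample[samples$condition == condition]
  if (length(cols) < 2)
    stop("need >= 2 replicates in condition '", condition, "'",
         call. = FALSE)
  sub <- tpm_mat[, cols, drop = FALSE]
  data.frame(feature_id = rownames(tpm_mat),
             mean_tpm = rowMeans(sub),
             sd_tpm = apply(sub, 1, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-pronged presence/expression filter for candidate sRNAs
#'
#' A candidate sRNA passes in a condition when (i) it is present —
#' nonzero TPM — in at least `min_replicates` of that condition's
#' replicate libraries, and (ii) its condition mean TPM reaches the
#' class-specific threshold: 40 TPM for antisense sRNAs, 14 TPM for
#' intergenic sRNAs by default. Filtering is per condition: an sRNA may
#' pass under one condition only.
#'
#' @param tpm_mat TPM matrix (features x samples).
#' @param classes named character vector, feature id -> sRNA class
#'   (`"antisense"` or `"intergenic"`); only these features are evaluated.
#' @param samples sample sheet.
#' @param condition condition to evaluate.
#' @param min_replicates presence threshold (default 4, of 5 replicates).
#' @param thresholds named numeric: mean-TPM threshold per class.
#' @param on `"mean"` applies the expression threshold to the condition
#'   mean (default); `"per_replicate"` requires `min_replicates`
#'   replicates to individually reach it.
#' @return data.frame: `feature_id`, `srna_class`, `condition`,
#'   `n_detected`, `mean_tpm`, `sd_tpm`, `pass`, `reason`.
#' @export
filter_srnas <- function(tpm_mat, classes, samples, condition,
                         min_replicates = 4L,
                         thresholds = c(antisense = 40, intergenic = 14),
                         on = c("mean", "per_replicate")) {
  on <- match.arg(on)
  ids <- names(classes)
  if (is.null(ids)) stop("classes must be a named vector", call. = FALSE)
  unknown_class <- setdiff(unique(classes), names(thresholds))
  if (length(unknown_class))
    stop("no threshold for class(es): ",
         paste(unknown_class, collapse = ", "), call. = FALSE)
  missing_feat <- setdiff(ids, rownames(tpm_mat))
  if (length(missing_feat))
    stop("feature(s) absent from TPM matrix: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  cols <- samples$sample[samples$condition == condition]
  if (length(cols) < min_replicates)
    stop("condition '", condition, "' has fewer samples than min_replicates",
         call. = FALSE)
  sub <- tpm_mat[ids, cols, drop = FALSE]
  n_det <- rowSums(sub > 0)
  mean_tpm <- rowMeans(sub)
  sd_tpm <- apply(sub, 1, stats::sd)
  thr <- thresholds[classes]
  expressed <- if (on == "mean") mean_tpm >= thr
               else rowSums(sweep(sub, 1, thr, ">=")) >= min_replicates
  detected <- n_det >= min_replicates
  pass <- detected & expressed
  reason <- rep("pass", length(ids))
  reason[!expressed] <- "expression"
  reason[!detected] <- "detection"  # detection failure reported first
  data.frame(feature_id = ids, srna_class = unname(classes),
             condition = condition, n_detected = unname(n_det),
             mean_tpm = unname(mean_tpm), sd_tpm = unname(sd_tpm),
             pass = unname(pass), reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a count matrix as TSV with a sidecar sample sheet
#'
#' The counts table has feature ids in the first column (`feature_id`),
#' then a `length_nt` column, then one column per sample. The sample
#' sheet has columns `sample`, `condition`, `replicate`.
#'
#' @param x a [count_matrix()].
#' @param counts_path,samples_path output TSV paths.
#' @export
write_counts_tsv <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(feature_id = rownames(x$counts),
                   length_nt = x$lengths[rownames(x$counts)],
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("feature_id", "length_nt")),
                         drop = FALSE])
  rownames(counts) <- df$feature_id
  storage.mode(counts) <- "integer"
  count_matrix(counts,
               stats::setNames(df$length_nt, df$feature_id),
               samples)
}
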