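#' Paired expression test between an sRNA and its cis target
#'
#' Two-sided t test on the per-replicate differences d = sRNA - target:
#' t = mean(d) / (sd(d)/sqrt(n)) on n - 1 degrees of freedom. When every
#' difference is exactly zero the test degenerates to t = 0, p = 1; when
#' the differences are constant but nonzero, p = 0 with infinite t.
#' Direction follows the sign of the mean difference. An unpaired
#' (Welch) alternative is available for designs without replicate
#' pairing.
#'
#' @param srna_tpm,target_tpm per-replicate expression vectors, aligned by
#'   replicate, length >= 2.
#' @param alpha significance level for the `significant` flag (p < alpha).
#' @param paired paired-by-replicate test (default) or Welch two-sample.
#' @param log_transform test log2(TPM + 1) instead of raw TPM.
#' @return list: `n`, `mean_srna`, `mean_target`, `mean_ratio`, `t_stat`,
#'   `p_value`, `direction` (`"srna_higher"`, `"target_higher"`,
#'   `"none"`), `significant`.
#' @export
paired_expression_test <- function(srna_tpm, target_tpm, alpha = 0.05,
                                   paired = TRUE, log_transform = FALSE) {
  if (length(srna_tpm) != length(target_tpm))
    stop("sRNA and target vectors must have equal length", call. = FALSE)
  n <- length(srna_tpm)
  if (n < 2) stop("need >= 2 replicates", call. = FALSE)
  x <- srna_tpm; y <- target_tpm
  if (log_transform) { x <- log2(x + 1); y <- log2(y + 1) }

  if (paired) {
    d <- x - y
    md <- mean(d); s <- stats::sd(d)
    if (s == 0) {
      if (md == 0) { t_stat <- 0; p <- 1 }
      else { t_stat <- sign(md) * Inf; p <- 0 }
    } else {
      t_stat <- md / (s / sqrt(n))
      p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
    }
  } else {
    wt <- stats::t.test(x, y)  # Welch
    t_stat <- unname(wt$statistic); p <- wt$p.value
    md <- mean(x) - mean(y)
  }

  direction <- if (md > 0) "srna_higher" else if (md < 0) "target_higher"
               else "none"
  list(n = n,
       mean_srna = mean(srna_tpm), mean_target = mean(target_tpm),
       mean_ratio = mean(srna_tpm) / mean(target_tpm),
       t_stat = t_stat, p_value = p, direction = direction,
       significant = p < alpha)
}

#' Run the paired test over all primary cis pairs
#'
#' One test per primary cis pair, comparing the asRNA's TPM replicates
#' against its cis target's under one condition, with a summary of
#' significant sRNA-higher / target-higher / non-significant counts.
#'
#' @param tpm_mat TPM matrix (features x samples) containing both sRNA
#'   transcripts and genes.
#' @param pairs cis-pair data.frame (see [find_cis_targets()]); only rows
#'   with `primary = TRUE` are tested.
#' @param samples sample sheet.
#' @param condition condition whose replicates are compared.
#' @param alpha significance level.
#' @param paired,log_transform passed to [paired_expression_test()].
#' @return list with `results` (data.frame: pair ids, means, sds, ratio,
#'   t, p, direction, significant) and `summary` (named counts).
#' @export
run_all_pairs <- function(tpm_mat, pairs, samples, condition, alpha = 0.05,
                          paired = TRUE, log_transform = FALSE) {
  prim <- pairs[pairs$primary, , drop = FALSE]
  cols <- samples$sample[samples$condition == condition]
  empty <- data.frame(srna_id = character(), gene_id = character(),
                      mean_srna = numeric(), sd_srna = numeric(),
                      mean_target = numeric(), sd_target = numeric(),
                      mean_ratio = numeric(), t_stat = numeric(),
                      p_value = numeric(), direction = character(),
                      significant = logical(), stringsAsFactors = FALSE)
  if (!nrow(prim)) {
    return(list(results = empty,
                summary = c(srna_higher = 0L, target_higher = 0L,
                            not_significant = 0L)))
  }
  missing_feat <- setdiff(unique(c(prim$srna_id, prim$gene_id)),
                          rownames(tpm_mat))
  if (length(missing_feat))
    stop("pair member(s) absent from TPM matrix: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)

  res <- lapply(seq_len(nrow(prim)), function(i) {
    sv <- tpm_mat[prim$srna_id[i], cols]
    tv <- tpm_mat[prim$gene_id[i], cols]
    r <- paired_expression_test(sv, tv, alpha = alpha, paired = paired,
                                log_transform = log_transform)
    data.frame(srna_id = prim$srna_id[i], gene_id = prim$gene_id[i],
               mean_srna = r$mean_srna, sd_srna = stats::sd(sv),
               mean_target = r$mean_target, sd_target = stats::sd(tv),
               mean_ratio = r$mean_ratio, t_stat = r$t_stat,
               p_value = r$p_value, direction = r$direction,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  list(results = results,
       summary = c(
         srna_higher = sum(results$significant &
                             results$direction == "srna_higher"),
         target_higher = sum(results$significant &
                               results$direction == "target_higher"),
         not_significant = sum(!results$significant)))
}
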