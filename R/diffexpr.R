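# Negative-binomial two-condition differential expression.
#
# A deliberately transparent count-based pipeline: median-of-ratios size
# factors, method-of-moments dispersion pooled within conditions, a
# delta-method Wald test on log2 fold changes, and Benjamini-Hochberg
# FDR control. The NB model is parameterised by (mean, dispersion):
# variance = mu + alpha * mu^2.

#' Median-of-ratios size factors
#'
#' Per-sample sequencing-depth normalisers: the reference is each
#' feature's geometric mean across samples (features with any zero count
#' are excluded from the reference); a sample's factor is the median over
#' features of its count divided by the reference, rescaled so the
#' factors have geometric mean 1.
#'
#' @param counts integer matrix (features x samples) or [count_matrix()].
#' @return named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  usable <- rowSums(counts == 0) == 0
  if (!any(usable))
    stop("no feature has nonzero counts in every sample; ",
         "filter features or supply a pseudo-reference", call. = FALSE)
  lc <- log(counts[usable, , drop = FALSE])
  ref <- rowMeans(lc)                       # log geometric mean
  f <- exp(apply(lc - ref, 2, stats::median))
  f <- f / exp(mean(log(f)))                # geometric mean 1
  stats::setNames(f, colnames(counts))
}

#' Normalise counts by size factors
#'
#' @param counts matrix or [count_matrix()].
#' @param sf size factors (default estimated by [size_factors()]).
#' @return numeric matrix of depth-normalised counts.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  sweep(as.matrix(counts), 2, sf, "/")
}

#' Method-of-moments NB dispersion per feature
#'
#' Within each condition the dispersion is estimated as
#' alpha = (s^2 - mu) / mu^2 from the sample mean and variance of
#' normalised counts; estimates are pooled across conditions weighted by
#' degrees of freedom and floored at 1e-8 (the Poisson limit).
#'
#' @param norm_counts normalised count matrix (features x samples).
#' @param condition character vector of condition labels per sample.
#' @param floor lower bound on the estimate.
#' @return named numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(norm_counts, condition, floor = 1e-8) {
  condition <- as.character(condition)
  conds <- unique(condition)
  if (any(table(condition) < 2))
    stop("need >= 2 replicates per condition", call. = FALSE)
  num <- 0; den <- 0
  for (cc in conds) {
    sub <- norm_counts[, condition == cc, drop = FALSE]
    n <- ncol(sub)
    mu <- rowMeans(sub)
    s2 <- apply(sub, 1, stats::var)
    a <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
    num <- num + (n - 1) * a
    den <- den + (n - 1)
  }
  alpha <- pmax(floor, num / den)
  stats::setNames(alpha, rownames(norm_counts))
}

#' Wald test for NB differential expression
#'
#' The log2 fold change is log2((mean_stress + c) / (mean_control + c))
#' on normalised counts with pseudo-count c = 0.5 for stability at zero.
#' Its standard error comes from the delta method on the NB variance
#' mu + alpha mu^2 of each condition mean (evaluated at the
#' pseudo-count-shifted mean so it is always positive); the two-sided
#' p-value uses the normal reference.
#'
#' @param norm_counts normalised count matrix.
#' @param condition per-sample condition labels.
#' @param dispersion per-feature dispersion (default
#'   [estimate_dispersion()]).
#' @param ref reference (control) condition; default the first label.
#' @param pseudo pseudo-count added to condition means.
#' @return data.frame `feature_id`, `base_mean`, `log2fc`, `se_log2fc`,
#'   `wald_p`.
#' @export
nb_wald_test <- function(norm_counts, condition,
                         dispersion = estimate_dispersion(norm_counts,
                                                          condition),
                         ref = NULL, pseudo = 0.5) {
  condition <- as.character(condition)
  conds <- unique(condition)
  if (length(conds) != 2)
    stop("exactly two conditions required", call. = FALSE)
  if (is.null(ref)) ref <- conds[1]
  alt <- setdiff(conds, ref)
  if (any(table(condition) < 2))
    stop("need >= 2 replicates per condition", call. = FALSE)

  m_ref <- rowMeans(norm_counts[, condition == ref, drop = FALSE])
  m_alt <- rowMeans(norm_counts[, condition == alt, drop = FALSE])
  n_ref <- sum(condition == ref); n_alt <- sum(condition == alt)
  a <- dispersion[rownames(norm_counts)]

  lfc <- log2((m_alt + pseudo) / (m_ref + pseudo))
  # Var(log2(mean + c)) ~ Var(mean) / ((mean + c)^2 ln(2)^2), with
  # Var(mean) = (mu + alpha mu^2)/n evaluated at mu = mean + c.
  vlog <- function(m, n) {
    mu <- m + pseudo
    (mu + a * mu^2) / n / (mu^2 * log(2)^2)
  }
  se <- sqrt(vlog(m_ref, n_ref) + vlog(m_alt, n_alt))
  z <- lfc / se
  data.frame(feature_id = rownames(norm_counts),
             base_mean = (m_ref + m_alt) / 2,
             log2fc = unname(lfc), se_log2fc = unname(se),
             wald_p = unname(2 * stats::pnorm(-abs(z))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, preserving the
#' input order: q_(i) = min over j >= i of m * p_(j) / j, capped at 1.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Call differential expression at an FDR threshold
#'
#' The threshold comparison is inclusive: features at exactly the FDR
#' threshold are called.
#'
#' @param de data.frame with `log2fc` and `fdr_q` columns.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return `de` with a `call` column in `{"up", "down", "ns"}`.
#' @export
call_de <- function(de, fdr_threshold = 0.05) {
  sig <- de$fdr_q <= fdr_threshold
  de$call <- ifelse(sig & de$log2fc > 0, "up",
                    ifelse(sig & de$log2fc < 0, "down", "ns"))
  de
}

#' Full differential-expression pipeline
#'
#' Size factors, normalisation, dispersion estimation, Wald test, BH
#' adjustment and calling, in one step.
#'
#' @param counts a [count_matrix()].
#' @param ref reference (control) condition.
#' @param fdr_threshold FDR cutoff.
#' @return data.frame of per-feature results (see [nb_wald_test()]) plus
#'   `fdr_q` and `call`.
#' @export
run_de <- function(counts, ref = NULL, fdr_threshold = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  sf <- size_factors(counts)
  nc <- normalize_counts(counts, sf)
  de <- nb_wald_test(nc, counts$samples$condition, ref = ref)
  de$fdr_q <- bh_adjust(de$wald_p)
  call_de(de, fdr_threshold)
}
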