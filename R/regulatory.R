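#' Cross-tabulate sRNA and cis-target differential-expression calls
#'
#' Each primary cis pair is assigned the combination of its asRNA's and
#' its target mRNA's DE calls (up/down/ns). Discordant combinations
#' (up-sRNA/down-target and down-sRNA/up-target) flag candidate negative
#' regulation. Pairs whose members lack a DE call are listed, not
#' silently dropped.
#'
#' @param srna_de DE results (with `feature_id`, `call`) for sRNAs.
#' @param mrna_de DE results for genes.
#' @param pairs cis-pair data.frame; only `primary = TRUE` rows are used.
#' @return list: `table` (data.frame `srna_call`, `target_call`, `count`,
#'   `fraction`), `pairs` (per-pair calls), `n_pairs`, `discordant`
#'   (count), `discordant_fraction`, `excluded` (unresolvable pair ids).
#' @export
cross_tabulate <- function(srna_de, mrna_de, pairs) {
  prim <- pairs[pairs$primary, , drop = FALSE]
  s_call <- srna_de$call[match(prim$srna_id, srna_de$feature_id)]
  t_call <- mrna_de$call[match(prim$gene_id, mrna_de$feature_id)]
  unresolved <- is.na(s_call) | is.na(t_call)
  if (any(unresolved))
    warning(sum(unresolved), " pair(s) lack a DE call for a member; ",
            "listed in $excluded")
  keep <- !unresolved
  per_pair <- data.frame(srna_id = prim$srna_id[keep],
                         gene_id = prim$gene_id[keep],
                         srna_call = s_call[keep], target_call = t_call[keep],
                         stringsAsFactors = FALSE)
  lev <- c("up", "down", "ns")
  tab <- as.data.frame(table(
    srna_call = factor(per_pair$srna_call, lev),
    target_call = factor(per_pair$target_call, lev)),
    stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  n <- nrow(per_pair)
  tab$fraction <- if (n) tab$count / n else 0
  disc <- sum(per_pair$srna_call == "up" & per_pair$target_call == "down") +
    sum(per_pair$srna_call == "down" & per_pair$target_call == "up")
  list(table = tab, pairs = per_pair, n_pairs = n,
       discordant = disc,
       discordant_fraction = if (n) disc / n else 0,
       excluded = prim$srna_id[unresolved])
}

#' Hypergeometric enrichment of a target gene set
#'
#' For each category, tests whether the target set contains more category
#' members than expected by drawing `n` genes from the universe without
#' replacement: one-sided upper-tail p = P[X >= k] with
#' X ~ Hypergeom(N, K, n), BH-adjusted across categories. A transparent,
#' reproducible replacement for web-service enrichment tools.
#'
#' @param target_set character vector of gene ids (must lie in the
#'   universe).
#' @param category_map data.frame with columns `gene_id`, `category`; a
#'   gene may carry several categories.
#' @param universe character vector of gene ids defining the background
#'   (typically all genes with a DE call).
#' @return data.frame `category`, `k` (targets in category), `K`
#'   (category size in universe), `n` (target-set size), `N` (universe
#'   size), `p_value`, `fdr_q`, sorted by p.
#' @export
hypergeom_enrichment <- function(target_set, category_map, universe) {
  target_set <- unique(target_set)
  universe <- unique(universe)
  outside <- setdiff(target_set, universe)
  if (length(outside))
    stop("target gene(s) outside the universe: ",
         paste(outside, collapse = ", "), call. = FALSE)
  cm <- category_map[category_map$gene_id %in% universe, , drop = FALSE]
  cats <- unique(cm$category)
  if (!length(cats))
    stop("no category overlaps the universe", call. = FALSE)
  N <- length(universe); n <- length(target_set)
  rows <- lapply(cats, function(cat) {
    members <- unique(cm$gene_id[cm$category == cat])
    K <- length(members)
    k <- length(intersect(members, target_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
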