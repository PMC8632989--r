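# Comparative statistics: Pearson correlations, rank-sum median
# comparisons, threshold proportions, and the degree-preserving
# randomization test for shared-gene symptom pairs.

#' Pearson correlation with two-sided significance
#'
#' Standard Pearson r with the two-sided p-value from the t transform
#' (through [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-degenerate.
#' @return list with `n`, `pcc`, `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    stop("pearson_correlation: need at least 3 complete pairs", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("pearson_correlation: zero variance, correlation undefined",
         call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(n = length(x), pcc = unname(ct$estimate), p_value = ct$p.value)
}

#' Rank-sum comparison of two groups
#'
#' Mann-Whitney/Wilcoxon rank-sum test with normal approximation,
#' continuity and tie correction, reporting both medians. The published
#' median contrasts never name their test; the rank-sum test is the
#' conventional choice for such skewed diversity distributions, two-sided
#' by default with one-sided options for directional claims.
#'
#' @param a,b numeric vectors (non-empty).
#' @param tail one of "two.sided", "less", "greater" (alternative: a vs b).
#' @return list with `median_a`, `median_b`, `n_a`, `n_b`, `statistic`,
#'   `p_value`, `tail`.
#' @export
rank_sum_compare <- function(a, b, tail = c("two.sided", "less", "greater")) {
  tail <- match.arg(tail)
  stopifnot(length(a) > 0, length(b) > 0)
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = tail, exact = FALSE, correct = TRUE))
  list(median_a = median(a), median_b = median(b),
       n_a = length(a), n_b = length(b),
       statistic = unname(wt$statistic), p_value = wt$p.value, tail = tail)
}

#' Proportion of values at or above a threshold
#'
#' @param values numeric vector (non-empty).
#' @param threshold inclusive threshold.
#' @return list with `proportion` (fraction) and `percent` (half-up, 2
#'   decimals).
#' @export
proportion_ge <- function(values, threshold) {
  stopifnot(length(values) > 0)
  p <- mean(values >= threshold)
  list(proportion = p, percent = round_half_up(100 * p))
}

#' Shared-gene pair randomization test
#'
#' Tests whether co-occurring symptom pairs share associated genes more
#' often than expected under a degree-preserving null. The observed count
#' is the number of SCN edges whose endpoint symptoms have intersecting
#' gene sets ([enumerate_shared_gene_pairs()]). Each permutation rewires
#' the bipartite phenotype-gene graph by double-edge swaps (default 10 x
#' |edges| attempted swaps), preserving every phenotype's gene count and
#' every gene's phenotype count, then recounts sharing pairs. The
#' empirical p-value uses the (1 + exceedances) / (n_perm + 1) convention
#' and can never be 0; a normal-approximation z p-value is reported
#' alongside, clearly labeled, since analytic approximations are how
#' extremely small significance levels arise.
#'
#' @param assoc an [association_table()] keyed by SCN terms.
#' @param scn phenotype co-occurrence network.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; the run is fully reproducible from it.
#' @param tail "greater" (default; sharing enrichment), "less" or
#'   "two.sided".
#' @param swap_factor attempted swaps per permutation as a multiple of the
#'   edge count.
#' @return object of class `randomization_result`: list with `observed`,
#'   `null_counts`, `n_perm`, `empirical_p`, `z`, `z_p`, `tail`, `seed`.
#' @export
shared_pair_randomization <- function(assoc, scn, n_perm = 1000, seed = 1,
                                      tail = c("greater", "less", "two.sided"),
                                      swap_factor = 10) {
  tail <- match.arg(tail)
  stopifnot(inherits(assoc, "assoc_table"), n_perm >= 1)
  rec <- assoc$records
  if (nrow(rec) < 2) {
    stop("shared_pair_randomization: degenerate bipartite graph (< 2 edges)",
         call. = FALSE)
  }
  phen_levels <- names(assoc$index)
  gene_levels <- names(assoc$reverse_index)
  phen_idx <- match(rec$phenotype_id, phen_levels)
  gene_idx <- match(rec$gene, gene_levels)

  ed <- igraph::as_data_frame(scn, what = "edges")
  both <- ed$from %in% phen_levels & ed$to %in% phen_levels
  pa <- match(ed$from[both], phen_levels)
  pb <- match(ed$to[both], phen_levels)

  observed <- nrow(suppressMessages(enumerate_shared_gene_pairs(scn, assoc)))

  set.seed(seed)
  null_counts <- .cpp_null_shared_counts(phen_idx, gene_idx,
                                         length(phen_levels),
                                         pa, pb, as.integer(n_perm),
                                         swap_factor)
  ge <- sum(null_counts >= observed)
  le <- sum(null_counts <= observed)
  empirical_p <- switch(tail,
    greater = (1 + ge) / (n_perm + 1),
    less = (1 + le) / (n_perm + 1),
    two.sided = min(1, 2 * (1 + min(ge, le)) / (n_perm + 1)))
  mu <- mean(null_counts)
  s <- sd(null_counts)
  z <- if (is.na(s) || s == 0) NA_real_ else (observed - mu) / s
  z_p <- if (is.na(z)) NA_real_ else switch(tail,
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z),
    two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  structure(list(observed = observed, null_counts = as.integer(null_counts),
                 n_perm = as.integer(n_perm), empirical_p = empirical_p,
                 z = z, z_p = z_p, tail = tail, seed = seed),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Shared-gene pair randomization (%s tail)\n",
    "  observed pairs: %d\n",
    "  null (n_perm = %d): mean %.2f, 95th pct %.1f\n",
    "  empirical p: %.4g   normal-approx p: %.4g\n"),
    x$tail, x$observed, x$n_perm, mean(x$null_counts),
    quantile(x$null_counts, 0.95), x$empirical_p, x$z_p))
  invisible(x)
}

#' Randomize a bipartite association table once
#'
#' One degree-preserving rewiring of the phenotype-gene graph (the same
#' move set as [shared_pair_randomization()]); exposed so the null can be
#' inspected and its degree-preservation property asserted directly.
#'
#' @param assoc an [association_table()].
#' @param seed integer seed.
#' @param swap_factor attempted swaps as a multiple of the edge count.
#' @return an [association_table()] with permuted gene assignments.
#' @export
randomize_associations <- function(assoc, seed = 1, swap_factor = 10) {
  stopifnot(inherits(assoc, "assoc_table"))
  rec <- assoc$records
  if (nrow(rec) < 2) {
    stop("randomize_associations: degenerate bipartite graph (< 2 edges)",
         call. = FALSE)
  }
  phen_levels <- names(assoc$index)
  gene_levels <- names(assoc$reverse_index)
  set.seed(seed)
  new_gene <- .cpp_swap_bipartite(match(rec$phenotype_id, phen_levels),
                                  match(rec$gene, gene_levels),
                                  as.integer(swap_factor * nrow(rec)))
  association_table(data.frame(phenotype_id = rec$phenotype_id,
                               phenotype_label = rec$phenotype_label,
                               gene = gene_levels[new_gene],
                               stringsAsFactors = FALSE))
}

#' Serialize a statistics result as a JSON record
#'
#' @param result a list or classed result from this module.
#' @param path output path.
#' @param name test name recorded in the JSON.
#' @param provenance optional named list of input provenance tags.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(result, path, name, provenance = NULL) {
  rec <- c(list(test = name), unclass(result),
           if (!is.null(provenance)) list(provenance = provenance))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
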