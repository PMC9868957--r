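#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by the number of
#' positive-negative pairs, with ties handled by midranks; equivalently the
#' probability that a random positive outscores a random negative, counting
#' ties as one half. Invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (0/1 or logical).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  r <- rank(scores)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise integration over distinct score thresholds in decreasing order:
#' the curve moves to recall r_i and precision p_i at each threshold and the
#' area is the sum of (r_i - r_(i-1)) * p_i. The baseline value for a random
#' predictor equals the positive-class prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1].
#' @export
auprc <- function(scores, labels) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- !duplicated(s, fromLast = TRUE)  # last index of each distinct threshold
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / sum(y)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Rank-uniformity test for a candidate gene list
#'
#' Tests whether an external candidate gene list is skewed towards high model
#' probabilities for a phenotype, relative to the uniform distribution of
#' ranks of all remaining genes. Candidates that were training positives for
#' the term are excluded first; the test is a two-sided Mann-Whitney
#' comparison of the candidates' probabilities against those of all remaining
#' non-training genes.
#'
#' @param candidate_genes character vector of candidate gene symbols.
#' @param probabilities named numeric vector of per-gene model probabilities.
#' @param training_genes genes that were positives in the term's training set.
#' @return A list with the Mann-Whitney \code{statistic}, two-sided
#'   \code{p_value}, and the candidate/background sizes used.
#' @export
rank_uniformity_test <- function(candidate_genes, probabilities, training_genes = character()) {
  universe <- setdiff(names(probabilities), training_genes)
  cand <- intersect(candidate_genes, universe)
  if (!length(cand)) stop("no candidate genes remain after excluding training positives")
  rest <- setdiff(universe, cand)
  if (!length(rest)) stop("no background genes remain")
  wt <- stats::wilcox.test(probabilities[cand], probabilities[rest],
                           alternative = "two.sided", exact = FALSE, correct = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_candidates = length(cand), n_background = length(rest))
}
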