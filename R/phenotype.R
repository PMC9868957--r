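#' Feature matrix for the machine-learning models
#'
#' The 83 predictors used by the classifier bench: the somatic-mutation
#' variable, evolutionary age, and the 81 genomic/epigenomic features in raw
#' (unrotated) form. Tree ensembles are scale-invariant, so no
#' standardization is applied here.
#'
#' @param table a \code{gene_feature_table}.
#' @return Numeric matrix with genes as row names.
#' @export
ml_feature_matrix <- function(table) {
  fn <- c("tsm", "age", genomic_feature_names())
  m <- as.matrix(as.data.frame(table)[, fn, drop = FALSE])
  rownames(m) <- table$gene
  m
}

#' Train one classifier per phenotype term
#'
#' For every ontology term with at least \code{min_genes} associated genes in
#' the expanded annotation set (restricted to the feature-table universe), a
#' separate classifier is trained to predict that term's gene associations
#' from the 83 features. Each term gets a stratified cross-validation report
#' with the AUPRC gain computed against that term's own prevalence baseline,
#' out-of-fold per-gene probabilities (leakage-free, used downstream for rank
#' transforms), and a final model fitted on all genes.
#'
#' @param table a \code{gene_feature_table}.
#' @param expanded an expanded \code{\link{annotation_set}}.
#' @param min_genes minimum associated-gene count for a term to be modelled
#'   (default 100).
#' @param paradigm registered paradigm name (default random forest).
#' @param grid hyperparameter grid; the default single-row grid skips inner
#'   tuning (see \code{\link{nested_cv}} for the tuned variant).
#' @param folds outer fold count.
#' @param seed master seed.
#' @param terms optional restriction of the candidate term set.
#' @return An object of class \code{phenotype_model_set}: per-term entries
#'   \code{(model, cv, probabilities, positives)} plus bookkeeping.
#' @export
train_per_phenotype <- function(table, expanded, min_genes = 100L,
                                paradigm = "random_forest", grid = NULL,
                                folds = 10L, seed = 1L, terms = NULL) {
  stopifnot(inherits(expanded, "annotation_set"))
  if (attr(expanded, "state") != "expanded") stop("annotations must be expanded first")
  X <- ml_feature_matrix(table)
  genes <- table$gene
  ann <- expanded[expanded$gene %in% genes, , drop = FALSE]
  counts <- table(ann$term)
  cand <- names(counts)[counts >= min_genes]
  if (!is.null(terms)) cand <- intersect(cand, terms)
  # a term annotated to (nearly) every gene cannot be modelled: need negatives
  cand <- cand[counts[cand] <= length(genes) - folds]
  if (!length(cand)) stop("no term has >= ", min_genes, " associated genes (and enough negatives)")
  pd <- get_paradigm(paradigm)
  grid <- if (is.null(grid)) default_phenotype_grid(paradigm) else as.data.frame(grid)
  models <- stats::setNames(vector("list", length(cand)), cand)
  for (i in seq_along(cand)) {
    t <- cand[[i]]
    pos <- unique(ann$gene[ann$term == t])
    y <- as.integer(genes %in% pos)
    cv <- nested_cv(X, y, paradigm = paradigm, outer_folds = folds, grid = grid,
                    seed = seed + i)
    final_params <- cv$chosen_params[[1L]]
    final_params$importance <- TRUE
    use <- oversample_indices(y, seed = seed + i)
    final <- pd$fit(X[use, , drop = FALSE], y[use], final_params, seed = seed + 7L * i)
    prob <- stats::setNames(cv$oof_scores, genes)
    models[[i]] <- list(term = t, model = final, cv = cv, probabilities = prob,
                        positives = pos, n_positives = length(pos))
  }
  structure(list(models = models, min_genes = min_genes, paradigm = paradigm,
                 genes = genes, seed = seed),
            class = "phenotype_model_set")
}

default_phenotype_grid <- function(paradigm) {
  switch(paradigm,
         random_forest = data.frame(num_trees = 100L, max_depth = 0L, min_node_size = 10L),
         logistic = data.frame(lambda = 1e-3),
         get_paradigm(paradigm)$default_grid[1L, , drop = FALSE])
}

#' @export
print.phenotype_model_set <- function(x, ...) {
  aurocs <- vapply(x$models, function(m) m$cv$mean_auroc, numeric(1))
  gains <- vapply(x$models, function(m) m$cv$auprc_gain, numeric(1))
  cat(sprintf("Per-phenotype models [%s]: %d terms (>= %d associated genes), %d genes\n",
              x$paradigm, length(x$models), x$min_genes, length(x$genes)))
  cat(sprintf("  median CV AUROC %.3f | median AUPRC gain %+.0f%%\n",
              stats::median(aurocs), 100 * stats::median(gains)))
  invisible(x)
}

#' @export
predict.phenotype_model_set <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(vapply(object$models, function(m) m$probabilities,
                  numeric(length(object$genes))))
  }
  X <- ml_feature_matrix(newdata)
  pd <- get_paradigm(object$paradigm)
  out <- vapply(object$models, function(m) pd$predict(m$model, X), numeric(nrow(X)))
  rownames(out) <- newdata$gene
  out
}

#' Per-term probability table
#'
#' @param x a \code{phenotype_model_set}.
#' @return Matrix of out-of-fold probabilities, genes x terms.
#' @export
phenotype_probabilities <- function(x) {
  stopifnot(inherits(x, "phenotype_model_set"))
  m <- vapply(x$models, function(m) m$probabilities, numeric(length(x$genes)))
  rownames(m) <- x$genes
  m
}

#' Temporal holdout validation against a newer annotation release
#'
#' Genes that gained phenotype involvement between two annotation releases
#' form the positive test set; negatives are sampled from genes negative in
#' both releases — either one negative per positive (\code{balanced}) or
#' enough negatives to reach a configured positive fraction
#' (\code{prevalence_matched}). All remaining genes train a fresh model on the
#' old release's labels, and the held-out AUROC is reported with a
#' Mann-Whitney p-value.
#'
#' @param old,new positive gene sets of the two releases: either character
#'   vectors of involved genes or \code{annotation_set}s (their unique genes).
#' @param table a \code{gene_feature_table} defining the gene universe.
#' @param mode \code{"balanced"} or \code{"prevalence_matched"}.
#' @param positive_fraction target positive fraction for prevalence-matched
#'   mode (default 0.22, the real-data prevalence).
#' @param paradigm,grid,seed model configuration (see
#'   \code{\link{train_per_phenotype}}); multi-row grids re-tune on the
#'   training portion by 3-fold search.
#' @return An object of class \code{temporal_holdout}: \code{auroc},
#'   \code{p_value}, test composition and sizes.
#' @export
temporal_holdout <- function(old, new, table, mode = c("balanced", "prevalence_matched"),
                             positive_fraction = 0.22, paradigm = "random_forest",
                             grid = NULL, seed = 1L) {
  mode <- match.arg(mode)
  as_genes <- function(a) if (inherits(a, "annotation_set")) unique(a$gene) else as.character(a)
  genes <- table$gene
  old_pos <- intersect(as_genes(old), genes)
  new_pos <- intersect(as_genes(new), genes)
  if (length(setdiff(old_pos, new_pos))) {
    stop("new release must contain every positive of the old release on this universe")
  }
  gained <- setdiff(new_pos, old_pos)
  if (!length(gained)) stop("no newly positive genes between releases; empty test set")
  never <- setdiff(genes, new_pos)
  n_neg <- if (mode == "balanced") length(gained) else {
    round(length(gained) * (1 - positive_fraction) / positive_fraction)
  }
  if (n_neg > length(never)) stop("not enough never-positive genes to sample ", n_neg, " negatives")
  set.seed(seed)
  neg_test <- sample(never, n_neg)
  test_genes <- c(gained, neg_test)
  train_genes <- setdiff(genes, test_genes)
  X <- ml_feature_matrix(table)
  y_train <- as.integer(train_genes %in% old_pos)
  itr <- match(train_genes, genes); ite <- match(test_genes, genes)
  pd <- get_paradigm(paradigm)
  grid <- if (is.null(grid)) default_phenotype_grid(paradigm) else as.data.frame(grid)
  best <- 1L
  if (nrow(grid) > 1L) {
    inner <- stratified_folds(y_train, 3L, seed = seed + 11L)
    sc <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(1:3, function(j) {
        a <- which(inner != j); b <- which(inner == j)
        use <- a[oversample_indices(y_train[a], seed = seed + 20L + j)]
        m <- pd$fit(X[itr[use], , drop = FALSE], y_train[use],
                    grid[g, , drop = FALSE], seed = seed + 30L + g * 10L + j)
        auroc(pd$predict(m, X[itr[b], , drop = FALSE]), y_train[b])
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(sc)
  }
  use <- oversample_indices(y_train, seed = seed + 1L)
  fit <- pd$fit(X[itr[use], , drop = FALSE], y_train[use],
                grid[best, , drop = FALSE], seed = seed + 2L)
  s <- pd$predict(fit, X[ite, , drop = FALSE])
  y_test <- as.integer(test_genes %in% gained)
  wt <- stats::wilcox.test(s[y_test == 1L], s[y_test == 0L], exact = FALSE)
  structure(list(auroc = auroc(s, y_test), p_value = wt$p.value,
                 n_test = length(test_genes), n_train = length(train_genes),
                 n_new_positives = length(gained), mode = mode,
                 test_genes = test_genes, scores = stats::setNames(s, test_genes),
                 chosen_params = grid[best, , drop = FALSE]),
            class = "temporal_holdout")
}

#' @export
print.temporal_holdout <- function(x, ...) {
  cat(sprintf("Temporal holdout (%s): %d new positives, test n = %d, train n = %d\n",
              x$mode, x$n_new_positives, x$n_test, x$n_train))
  cat(sprintf("  AUROC %.3f (Mann-Whitney p = %.3g)\n", x$auroc, x$p_value))
  invisible(x)
}

#' Feature importance of a fitted phenotype model
#'
#' Impurity importance is read from the fitted forest; permutation importance
#' is computed by score-degradation under column permutation of the
#' out-of-fold design (for any paradigm).
#'
#' @param model_entry one element of \code{phenotype_model_set$models}, or a
#'   fitted model with a \code{variable.importance} field.
#' @param X,y optional design and labels for permutation importance.
#' @param type \code{"impurity"} or \code{"permutation"}.
#' @param paradigm registered paradigm used for permutation scoring.
#' @param seed RNG seed for permutation importance.
#' @return Named numeric vector, decreasing.
#' @export
feature_importance <- function(model_entry, X = NULL, y = NULL,
                               type = c("impurity", "permutation"),
                               paradigm = "random_forest", seed = 1L) {
  type <- match.arg(type)
  model <- if (is.list(model_entry) && !is.null(model_entry$model)) model_entry$model else model_entry
  if (type == "impurity") {
    vi <- model$variable.importance
    if (is.null(vi)) stop("model carries no impurity importance (refit with importance)")
    return(sort(vi, decreasing = TRUE))
  }
  if (is.null(X) || is.null(y)) stop("permutation importance needs X and y")
  pd <- get_paradigm(paradigm)
  base <- auroc(pd$predict(model, X), y)
  set.seed(seed)
  drop <- vapply(colnames(X), function(cn) {
    Xp <- X; Xp[, cn] <- sample(Xp[, cn])
    base - auroc(pd$predict(model, Xp), y)
  }, numeric(1))
  sort(drop, decreasing = TRUE)
}
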