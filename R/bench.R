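# Classifier bench: a registry of pluggable paradigms evaluated under nested
# cross-validation with within-fold random oversampling. The two paradigms the
# pipeline depends on (logistic regression, random forest) ship built in;
# further ones can be registered at run time.

.paradigms <- new.env(parent = emptyenv())

#' Register a classification paradigm
#'
#' A paradigm bundles a fit function, a predict function, and a default
#' hyperparameter grid, and becomes available to \code{\link{nested_cv}} and
#' \code{\link{train_per_phenotype}} under its name.
#'
#' @param name paradigm name.
#' @param fit function \code{(X, y, params, seed)} returning a fitted model.
#' @param predict function \code{(model, X)} returning numeric scores.
#' @param default_grid data frame of hyperparameter combinations (one row per
#'   candidate; single-row grids skip the inner tuning loop).
#' @return \code{name}, invisibly.
#' @export
register_paradigm <- function(name, fit, predict, default_grid) {
  assign(name, list(name = name, fit = fit, predict = predict,
                    default_grid = as.data.frame(default_grid)),
         envir = .paradigms)
  invisible(name)
}

#' @rdname register_paradigm
#' @export
list_paradigms <- function() sort(ls(.paradigms))

get_paradigm <- function(name) {
  if (!exists(name, envir = .paradigms, inherits = FALSE)) {
    stop("unknown paradigm '", name, "'; registered: ",
         paste(list_paradigms(), collapse = ", "))
  }
  get(name, envir = .paradigms, inherits = FALSE)
}

# built-in paradigms, registered at load time
register_builtin_paradigms <- function() {
  register_paradigm(
    "logistic",
    fit = function(X, y, params, seed) {
      glmnet::glmnet(as.matrix(X), factor(y), family = "binomial",
                     alpha = 0, lambda = params$lambda, standardize = TRUE)
    },
    predict = function(model, X) {
      as.numeric(stats::predict(model, newx = as.matrix(X), type = "response"))
    },
    default_grid = data.frame(lambda = 10^seq(-4, -1))  # 4-point log grid of L2 strength
  )
  register_paradigm(
    "random_forest",
    fit = function(X, y, params, seed) {
      ranger::ranger(x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = params$num_trees,
                     max.depth = params$max_depth, min.node.size = params$min_node_size,
                     respect.unordered.factors = TRUE,
                     seed = seed, num.threads = 1L,
                     importance = if (isTRUE(params$importance)) "impurity" else "none")
    },
    predict = function(model, X) {
      stats::predict(model, data = as.data.frame(X), num.threads = 1L)$predictions[, "1"]
    },
    default_grid = expand.grid(num_trees = c(100L, 300L), max_depth = c(0L, 10L),
                               min_node_size = c(1L, 5L))
  )
}

#' Stratified fold assignment
#'
#' Assigns each observation to one of \code{k} folds so that class prevalence
#' is preserved per fold. Errors when either class has fewer members than
#' folds (a fold would be single-class).
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  if (min(table(y)) < k) stop("class with fewer members (", min(table(y)),
                              ") than folds (", k, "); cannot stratify")
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Random oversampling of the minority class
#'
#' Returns row indices in which the minority class is resampled with
#' replacement up to parity with the majority class. Applied only inside
#' training partitions, never to validation or test data.
#'
#' @param y binary labels of the training partition.
#' @param seed RNG seed.
#' @return Integer vector of indices into \code{y} (original order first,
#'   resampled minority appended).
#' @export
oversample_indices <- function(y, seed = 1L) {
  y <- as.integer(y)
  tab <- table(y)
  if (length(tab) < 2L || tab[[1L]] == tab[[2L]]) return(seq_along(y))
  minority <- as.integer(names(tab)[which.min(tab)])
  extra <- max(tab) - min(tab)
  set.seed(seed)
  c(seq_along(y), sample(which(y == minority), extra, replace = TRUE))
}

#' Nested cross-validation of a classification paradigm
#'
#' The data are split into \code{outer_folds} stratified folds used in turn as
#' test sets. On the remaining folds, hyperparameters are chosen by
#' \code{inner_folds}-fold grid search maximizing AUROC (skipped for
#' single-row grids); the winning configuration is refit on the whole outer
#' training portion and evaluated on the held-out fold. Random oversampling
#' of the minority class is applied inside every training partition only. The
#' average AUROC across the outer folds is the performance measure.
#'
#' @param X numeric feature matrix (genes x features).
#' @param y binary labels.
#' @param paradigm a name registered via \code{\link{register_paradigm}}.
#' @param outer_folds,inner_folds fold counts (defaults 10 and 3).
#' @param grid hyperparameter grid; \code{NULL} uses the paradigm default.
#' @param oversample apply within-fold random oversampling (default TRUE).
#' @param seed master seed for folds, oversampling and model fits.
#' @return An object of class \code{cv_report}: per-fold AUROC/AUPRC, their
#'   means, a normal-approximation 95\% CI on the mean AUROC, the baseline
#'   AUPRC (prevalence) and fractional AUPRC gain, chosen parameters per
#'   fold, out-of-fold scores, fold ids and oversampled training indices.
#' @export
nested_cv <- function(X, y, paradigm = "random_forest", outer_folds = 10L,
                      inner_folds = 3L, grid = NULL, oversample = TRUE, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  pd <- get_paradigm(paradigm)
  grid <- if (is.null(grid)) pd$default_grid else as.data.frame(grid)
  if (!nrow(grid)) stop("empty hyperparameter grid")
  folds <- stratified_folds(y, outer_folds, seed = seed)
  fold_auroc <- fold_auprc <- numeric(outer_folds)
  oof <- rep(NA_real_, length(y))
  chosen <- vector("list", outer_folds)
  train_idx_used <- vector("list", outer_folds)
  for (k in seq_len(outer_folds)) {
    test <- which(folds == k); train <- which(folds != k)
    best <- 1L
    if (nrow(grid) > 1L) {
      inner <- stratified_folds(y[train], inner_folds, seed = seed + 100L + k)
      score <- vapply(seq_len(nrow(grid)), function(g) {
        mean(vapply(seq_len(inner_folds), function(j) {
          itr <- train[inner != j]; iva <- train[inner == j]
          use <- if (oversample) itr[oversample_indices(y[itr], seed = seed + 1000L + k * 10L + j)] else itr
          m <- pd$fit(X[use, , drop = FALSE], y[use], grid[g, , drop = FALSE],
                      seed = seed + 2000L + k * 100L + j * 10L + g)
          auroc(pd$predict(m, X[iva, , drop = FALSE]), y[iva])
        }, numeric(1)))
      }, numeric(1))
      best <- which.max(score)
    }
    use <- if (oversample) train[oversample_indices(y[train], seed = seed + 500L + k)] else train
    train_idx_used[[k]] <- use
    m <- pd$fit(X[use, , drop = FALSE], y[use], grid[best, , drop = FALSE],
                seed = seed + 3000L + k)
    s <- pd$predict(m, X[test, , drop = FALSE])
    oof[test] <- s
    fold_auroc[k] <- auroc(s, y[test])
    fold_auprc[k] <- auprc(s, y[test])
    chosen[[k]] <- grid[best, , drop = FALSE]
  }
  base <- mean(y)
  zq <- stats::qnorm(0.975)
  semean <- stats::sd(fold_auroc) / sqrt(outer_folds)
  structure(list(paradigm = paradigm,
                 fold_aurocs = fold_auroc, mean_auroc = mean(fold_auroc),
                 auroc_ci = c(mean(fold_auroc) - zq * semean, mean(fold_auroc) + zq * semean),
                 fold_auprcs = fold_auprc, mean_auprc = mean(fold_auprc),
                 baseline_auprc = base, auprc_gain = mean(fold_auprc) / base - 1,
                 chosen_params = chosen, oof_scores = oof, folds = folds,
                 train_indices = train_idx_used, oversample = oversample, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Nested CV [%s], %d outer folds:\n", x$paradigm, length(x$fold_aurocs)))
  cat(sprintf("  mean AUROC %.3f (95%% CI %.3f-%.3f)\n",
              x$mean_auroc, x$auroc_ci[1L], x$auroc_ci[2L]))
  cat(sprintf("  mean AUPRC %.3f (baseline %.3f, gain %+.0f%%)\n",
              x$mean_auprc, x$baseline_auprc, 100 * x$auprc_gain))
  invisible(x)
}
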