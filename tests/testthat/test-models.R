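test_that("univariable logistic fit recovers a planted odds ratio with Wald inference", {
  set.seed(41)
  x <- stats::rnorm(20000)
  y <- stats::rbinom(20000, 1, stats::plogis(-1.2 + log(1.9) * x))
  fit <- fit_univariable(x, y)
  r <- summary(fit)
  expect_equal(r$odds_ratio, 1.9, tolerance = 0.06)
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  expect_lt(r$p_value, 1e-10)
  expect_gt(r$odds_ratio, 0)

  expect_error(fit_univariable(1:10, rep(1, 10)), "both classes")
  # x identical to y on a balanced sample: complete separation
  yy <- rep(c(0, 1), each = 20)
  expect_error(fit_univariable(yy, yy), "separation")
})

test_that("multivariable fit handles PCs, age coding, covariates and rank checks", {
  cfg <- synthetic_config(n_genes = 600L, n_terms = 30L, seed = 5)
  g <- gen_genes(cfg, records = FALSE)
  lab <- gen_labels_and_annotations(cfg, g, NULL, annotations = FALSE)
  tab <- assemble_feature_table(g$tsm, g$age, g$features, ipa = lab$ipa)
  pcs <- standardize_and_pca(tab)
  m1 <- fit_multivariable(tab$tsm, tab$age, pcs, tab$ipa)
  expect_equal(nrow(summary(m1)), 82L) # tsm + age + 80 PCs
  expect_true(all(summary(m1)$odds_ratio > 0))
  expect_true(all(summary(m1)$ci_low <= summary(m1)$odds_ratio &
                    summary(m1)$odds_ratio <= summary(m1)$ci_high))

  # re-orthogonalizing the (already orthogonal) PC block must not move tsm
  qj <- qr.Q(qr(pcs$scores))
  m2 <- fit_multivariable(tab$tsm, tab$age, qj, tab$ipa)
  expect_equal(coef(m1)[["tsm"]], coef(m2)[["tsm"]], tolerance = 1e-6)

  # categorical age: one dummy per non-reference level
  m3 <- fit_multivariable(tab$tsm, tab$age, pcs, tab$ipa, age_mode = "categorical")
  expect_equal(nrow(summary(m3)), 1L + (length(unique(tab$age)) - 1L) + 80L)

  # a binary driver covariate passes through untouched; duplicating it is aliased
  drv <- as.integer(tab$tsm > stats::median(tab$tsm))
  m4 <- fit_multivariable(tab$tsm, tab$age, pcs, tab$ipa,
                          extra_covariates = list(driver = drv))
  expect_true("driver" %in% summary(m4)$term)
  expect_error(fit_multivariable(tab$tsm, tab$age, pcs, tab$ipa,
                                 extra_covariates = list(driver = drv, driver2 = drv)),
               "rank deficient")
})

test_that("stratified folds preserve classes and oversampling touches only training rows", {
  y <- c(rep(1L, 30), rep(0L, 170))
  folds <- stratified_folds(y, 10L, seed = 3)
  for (k in 1:10) expect_setequal(unique(y[folds == k]), c(0L, 1L))
  expect_error(stratified_folds(c(1, rep(0, 50)), 5L), "cannot stratify")

  idx <- oversample_indices(y, seed = 1)
  expect_equal(sum(y[idx] == 1L), sum(y[idx] == 0L)) # parity
  expect_true(all(seq_along(y) %in% idx)) # originals kept
  # balanced labels: oversampling is a no-op
  expect_identical(oversample_indices(rep(c(0L, 1L), 20)), seq_len(40L))
})

test_that("nested CV is calibrated on null labels and leak-free", {
  set.seed(61)
  X <- matrix(stats::rnorm(400 * 10), 400, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- stats::rbinom(400, 1, 0.3)
  cv <- nested_cv(X, y, paradigm = "logistic", grid = data.frame(lambda = 0.01),
                  seed = 2)
  se <- stats::sd(cv$fold_aurocs) / sqrt(10)
  expect_lt(abs(cv$mean_auroc - 0.5), 3 * se + 0.02)
  expect_equal(cv$baseline_auprc, mean(y))
  expect_equal(cv$auprc_gain, cv$mean_auprc / mean(y) - 1)
  # oversampled training indices never intersect the fold's test rows
  for (k in 1:10) {
    expect_length(intersect(cv$train_indices[[k]], which(cv$folds == k)), 0L)
  }
  # with balanced labels, oversampling on/off gives identical fold assignments
  yb <- rep(c(0L, 1L), 200)
  cv_on <- nested_cv(X, yb, "logistic", grid = data.frame(lambda = 0.01), seed = 4)
  cv_off <- nested_cv(X, yb, "logistic", grid = data.frame(lambda = 0.01),
                      oversample = FALSE, seed = 4)
  expect_identical(cv_on$folds, cv_off$folds)
  expect_equal(cv_on$mean_auroc, cv_off$mean_auroc)

  # planted signal: random forest clears the null comfortably
  ys <- stats::rbinom(400, 1, stats::plogis(-1 + 1.5 * X[, 1] + X[, 2]))
  cvs <- nested_cv(X, ys, "random_forest",
                   grid = data.frame(num_trees = 100L, max_depth = 0L,
                                     min_node_size = 5L), seed = 5)
  expect_gt(cvs$mean_auroc, 0.65)
})

test_that("full-data logistic AUROC dominates its cross-validated estimate on average", {
  set.seed(71)
  diffs <- replicate(5, {
    X <- matrix(stats::rnorm(300 * 20), 300, 20,
                dimnames = list(NULL, paste0("f", 1:20)))
    y <- stats::rbinom(300, 1, stats::plogis(-0.5 + 0.6 * X[, 1]))
    fit <- fit_univariable(X[, 1], y)
    full <- fit$auroc
    cv <- nested_cv(X, y, "logistic", grid = data.frame(lambda = 1e-3), seed = 8)
    full - cv$mean_auroc
  })
  expect_gt(mean(diffs), -0.01)
})

test_that("per-phenotype training applies the 100-gene threshold exactly", {
  cfg <- synthetic_config(n_genes = 500L, n_terms = 20L, prevalence = 0.5, seed = 11)
  g <- gen_genes(cfg, records = FALSE, cds = TRUE)
  lab <- gen_labels_and_annotations(cfg, g, NULL, annotations = FALSE)
  tab <- assemble_feature_table(g$tsm, g$age, g$features, ipa = lab$ipa)
  # hand-built expanded set: one term with exactly 100 genes, one with 99
  set.seed(12)
  g100 <- sample(tab$gene, 100L); g99 <- sample(tab$gene, 99L)
  ex <- annotation_set(c(g100, g99), c(rep("T_A", 100L), rep("T_B", 99L)),
                       state = "expanded")
  pms <- train_per_phenotype(tab, ex, min_genes = 100L, paradigm = "logistic",
                             folds = 5L, seed = 1)
  expect_identical(names(pms$models), "T_A")
  expect_equal(pms$models$T_A$n_positives, 100L)
  expect_true(all(pms$models$T_A$probabilities >= 0 & pms$models$T_A$probabilities <= 1))
  cv <- pms$models$T_A$cv
  expect_equal(cv$baseline_auprc, 100 / nrow(tab))
  expect_error(train_per_phenotype(tab, ex, min_genes = 200L), "no term")
})

test_that("temporal holdout builds its test set and errors on identical releases", {
  cfg <- synthetic_config(n_genes = 4000L, n_terms = 30L, seed = 13)
  g <- gen_genes(cfg, records = FALSE)
  lab <- gen_labels_and_annotations(cfg, g, NULL, annotations = FALSE)
  tab <- assemble_feature_table(g$tsm, g$age, g$features, ipa = lab$ipa)
  rel <- gen_release_pair(lab$ipa, n_new = 435L, seed = 14)
  th <- temporal_holdout(rel$old_genes, rel$new_genes, tab, mode = "balanced",
                         paradigm = "logistic", seed = 15)
  expect_equal(th$n_test, 870L)
  expect_equal(th$n_new_positives, 435L)
  expect_gt(th$auroc, 0.5)
  expect_lt(th$p_value, 0.05)

  thp <- temporal_holdout(rel$old_genes, rel$new_genes, tab,
                          mode = "prevalence_matched", positive_fraction = 0.22,
                          paradigm = "logistic", seed = 16)
  expect_equal(435L / thp$n_test, 0.22, tolerance = 0.01)

  expect_error(temporal_holdout(rel$new_genes, rel$new_genes, tab,
                                paradigm = "logistic"), "no newly positive")
})

test_that("paradigm registry rejects unknown names and accepts new entries", {
  expect_true(all(c("logistic", "random_forest") %in% list_paradigms()))
  expect_error(nested_cv(matrix(1:20, 10), rep(0:1, 5), paradigm = "adaboost"),
               "unknown paradigm")
  register_paradigm("prevalence_stub",
                    fit = function(X, y, params, seed) mean(y),
                    predict = function(model, X) rep(model, nrow(X)),
                    default_grid = data.frame(dummy = 1))
  expect_true("prevalence_stub" %in% list_paradigms())
})
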