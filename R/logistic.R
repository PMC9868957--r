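#' Univariable logistic regression for phenotype involvement
#'
#' Maximum-likelihood logistic fit of a binary label on a single predictor.
#' The odds ratio is reported per one standard deviation of the predictor
#' (the predictor is standardized internally unless \code{standardize =
#' FALSE}), with a two-sided Wald p-value and 95\% confidence interval.
#'
#' @param x numeric predictor.
#' @param y binary labels (0/1 or logical).
#' @param standardize rescale \code{x} to zero mean and unit SD first.
#' @param name coefficient name used in the results table.
#' @return An object of class \code{ipa_fit}; see
#'   \code{\link{fit_multivariable}}.
#' @export
fit_univariable <- function(x, y, standardize = TRUE, name = "x") {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  if (standardize) x <- as.numeric(scale(x))
  X <- matrix(x, ncol = 1L, dimnames = list(NULL, name))
  ipa_logistic(X, y)
}

#' Multivariable logistic regression on TSM, age and feature principal components
#'
#' Fits the binary phenotype-involvement label on the (standardized) somatic
#' mutation count, the evolutionary age (numeric 1-20 standardized, or a
#' 20-level categorical with the first level as reference), the 80 principal
#' components of the genomic/epigenomic features (each standardized so odds
#' ratios are per SD), and any extra covariates (binary covariates such as a
#' cancer-driver flag enter untouched; continuous ones are standardized).
#'
#' @param tsm numeric somatic-mutation variable (TSM or mean mutation rate).
#' @param age integer 1-20 evolutionary age.
#' @param pcs a \code{pc_view} from \code{\link{standardize_and_pca}}, or a
#'   numeric matrix of component scores.
#' @param y binary labels.
#' @param extra_covariates optional named list/data frame of extra columns.
#' @param age_mode \code{"numeric"} or \code{"categorical"}.
#' @return An object of class \code{ipa_fit} with a \code{results} table
#'   (term, estimate, se, odds_ratio, ci_low, ci_high, p_value), the
#'   underlying \code{glm} fit, and the in-sample AUROC.
#' @export
fit_multivariable <- function(tsm, age, pcs, y, extra_covariates = NULL,
                              age_mode = c("numeric", "categorical")) {
  age_mode <- match.arg(age_mode)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  scores <- if (inherits(pcs, "pc_view")) pcs$scores else as.matrix(pcs)
  X <- cbind(tsm = as.numeric(scale(tsm)))
  if (age_mode == "numeric") {
    X <- cbind(X, age = as.numeric(scale(as.numeric(age))))
  } else {
    f <- factor(age, levels = sort(unique(age)))
    mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0("age_", levels(f)[-1L])
    X <- cbind(X, mm)
  }
  X <- cbind(X, apply(scores, 2L, function(col) as.numeric(scale(col))))
  if (!is.null(extra_covariates)) {
    ec <- as.data.frame(extra_covariates)
    for (nm in names(ec)) {
      v <- ec[[nm]]
      if (!all(v %in% c(0, 1))) v <- as.numeric(scale(v))
      X <- cbind(X, stats::setNames(data.frame(v), nm))
    }
    X <- as.matrix(X)
  }
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)]) - 1L]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  ipa_logistic(X, y)
}

# shared ML fit with Wald inference and separation diagnostics
ipa_logistic <- function(X, y) {
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  mu <- stats::fitted(fit)
  if (!fit$converged || any(abs(stats::coef(fit)[-1L]) > 15) ||
      (all(mu[y == 1L] > 1 - 1e-8) && all(mu[y == 0L] < 1e-8))) {
    stop("logistic fit did not converge to a finite MLE (complete or ",
         "quasi-complete separation); largest |coefficient| = ",
         format(max(abs(stats::coef(fit)[-1L])), digits = 3))
  }
  sm <- summary(fit)$coefficients
  est <- sm[-1L, 1L]; se <- sm[-1L, 2L]; p <- sm[-1L, 4L]
  zq <- stats::qnorm(0.975)
  results <- data.frame(term = colnames(X), estimate = unname(est), se = unname(se),
                        odds_ratio = exp(unname(est)),
                        ci_low = exp(unname(est - zq * se)),
                        ci_high = exp(unname(est + zq * se)),
                        p_value = unname(p), stringsAsFactors = FALSE)
  structure(list(results = results, glm = fit,
                 auroc = auroc(mu, y), n = length(y), prevalence = mean(y)),
            class = "ipa_fit")
}

#' @export
print.ipa_fit <- function(x, top = 10L, ...) {
  cat("Logistic model of phenotype involvement: n =", x$n,
      sprintf("(prevalence %.1f%%), in-sample AUROC %.3f\n", 100 * x$prevalence, x$auroc))
  r <- x$results[order(x$results$p_value), , drop = FALSE]
  r <- utils::head(r, top)
  cat("Top predictors by p-value (OR per SD, 95% CI):\n")
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-12s OR %.3f (%.3f-%.3f)  p = %.3g\n", r$term[i],
                r$odds_ratio[i], r$ci_low[i], r$ci_high[i], r$p_value[i]))
  }
  invisible(x)
}

#' @export
summary.ipa_fit <- function(object, ...) object$results

#' @export
coef.ipa_fit <- function(object, ...) {
  stats::setNames(object$results$estimate, object$results$term)
}

#' @export
confint.ipa_fit <- function(object, ...) {
  m <- cbind(low = object$results$ci_low, high = object$results$ci_high)
  rownames(m) <- object$results$term
  m
}

#' @export
predict.ipa_fit <- function(object, newdata = NULL, type = "response", ...) {
  if (is.null(newdata)) return(stats::fitted(object$glm))
  stats::predict(object$glm, newdata = as.data.frame(newdata), type = type)
}
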