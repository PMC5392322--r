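#' Fit a binary logistic risk model
#'
#' Maximum-likelihood logistic regression of a binary outcome (by default
#' occult nodal status) on the requested covariates, via iteratively
#' reweighted least squares. The covariance of the estimates is the
#' inverse observed information.
#'
#' @param cohort data.frame with the outcome and covariate columns.
#' @param variables character vector of covariate column names (factors
#'   allowed; expanded by treatment coding).
#' @param outcome name of the 0/1 outcome column; default `node_binary`.
#' @return An object of class `risk_model`: list with `variables`,
#'   `coefficients` (named, intercept first), `intercept`, `vcov`, `n`,
#'   `loglik`, `iterations`, `outcome` and the underlying `fit`.
#' @export
fit_logistic <- function(cohort, variables, outcome = "node_binary") {
  y <- cohort[[outcome]]
  if (is.null(y)) stop2("outcome column '", outcome, "' not found")
  if (nrow(cohort) < 10) stop2("need at least 10 patients")
  if (length(unique(y)) < 2)
    stop2("outcome '", outcome, "' has a single class")
  for (v in variables) {
    x <- cohort[[v]]
    if (is.null(x)) stop2("variable '", v, "' not found in cohort")
    if (length(unique(x)) < 2) stop2("variable '", v, "' is constant")
  }
  fml <- if (length(variables))
    as.formula(paste(outcome, "~", paste(variables, collapse = " + ")))
  else as.formula(paste(outcome, "~ 1"))
  fit <- glm(fml, data = cohort, family = binomial(),
             control = list(epsilon = 1e-10, maxit = 100))
  cf <- coef(fit)
  if (anyNA(cf))
    stop2("singular design: coefficient(s) not estimable: ",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  if (!fit$converged || any(abs(cf[-1]) > 15))
    stop2("logistic fit did not converge (possible complete separation ",
          "in: ", paste(names(cf[-1])[abs(cf[-1]) > 15], collapse = ", "),
          ")")
  structure(list(variables = variables, coefficients = cf,
                 intercept = unname(cf[1]), vcov = vcov(fit),
                 n = nrow(cohort), loglik = as.numeric(logLik(fit)),
                 iterations = fit$iter, outcome = outcome, fit = fit),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> outcome %s, n = %d, logLik = %.2f\n",
              x$outcome, x$n, x$loglik))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted risk from a fitted model
#'
#' @param object a `risk_model`.
#' @param newdata data.frame of covariates; defaults to the training data.
#' @param ... unused.
#' @return Vector of predicted probabilities.
#' @export
predict.risk_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) unname(fitted(object$fit))
  else unname(predict(object$fit, newdata = newdata, type = "response"))
}

# likelihood-ratio p-value for adding `candidate` to `base` variables
.lr_add_p <- function(cohort, base, candidate, outcome) {
  f0 <- fit_logistic(cohort, base, outcome)
  f1 <- fit_logistic(cohort, c(base, candidate), outcome)
  df <- length(f1$coefficients) - length(f0$coefficients)
  stat <- 2 * (f1$loglik - f0$loglik)
  pchisq(max(stat, 0), df, lower.tail = FALSE)
}

#' Forward stepwise selection for the logistic risk model
#'
#' At each step the candidate with the smallest likelihood-ratio p-value
#' enters if that p-value is below `entry_p`; selection stops otherwise.
#' Ties are broken by candidate order, so the procedure is deterministic.
#' May return an intercept-only model.
#'
#' @param cohort data.frame of outcome and candidates.
#' @param candidates character vector of candidate variable names.
#' @param entry_p entry threshold on the LR p-value; default 0.05.
#' @param outcome outcome column name.
#' @return A `risk_model` fitted on the selected variables, with the
#'   selection path in attribute `selection`.
#' @export
forward_select <- function(cohort, candidates, entry_p = 0.05,
                           outcome = "node_binary") {
  if (length(candidates) == 0) stop2("`candidates` must be non-empty")
  selected <- character()
  remaining <- candidates
  path <- list()
  repeat {
    if (length(remaining) == 0) break
    ps <- vapply(remaining, function(v)
      .lr_add_p(cohort, selected, v, outcome), 0)
    best <- which.min(ps)  # first minimum: deterministic tie-break
    if (ps[best] >= entry_p) break
    path[[length(path) + 1]] <- data.frame(variable = remaining[best],
                                           p = ps[best])
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  fit <- fit_logistic(cohort, selected, outcome)
  attr(fit, "selection") <- if (length(path)) do.call(rbind, path) else
    data.frame(variable = character(), p = numeric())
  fit
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC as the Mann-Whitney probability that a random positive scores
#' higher than a random negative (ties counted one half), with the DeLong
#' nonparametric variance for the 95% confidence interval, truncated to
#' `[0, 1]`.
#'
#' @param labels 0/1 vector.
#' @param scores numeric risk scores, higher = more likely positive.
#' @param conf_level confidence level; default 0.95.
#' @return An object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `method`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(labels, scores, conf_level = 0.95) {
  if (length(labels) != length(scores))
    stop2("`labels` and `scores` must have the same length")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop2("AUC undefined: need both classes present")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(
    pROC::ci.auc(r, conf.level = conf_level, method = "delong")))
  structure(list(auc = as.numeric(r$auc),
                 ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
                 method = "DeLong", n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (95%% CI %.3f-%.3f, %s; %d+/%d-)\n",
              x$auc, x$ci_low, x$ci_high, x$method, x$n_pos, x$n_neg))
  invisible(x)
}

# stratified fold assignment: within each class, shuffled round-robin
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated AUC of the risk model
#'
#' Stratified k-fold cross-validation: the model (including forward
#' selection, when requested, re-run inside every training fold) is refit
#' k times and out-of-fold predicted probabilities are pooled into a
#' single ROC, so the reported AUC is honest about model selection.
#'
#' @param cohort data.frame of outcome and covariates.
#' @param variables covariate names (the candidate list when
#'   `select = TRUE`).
#' @param k number of folds; default 10.
#' @param seed integer seed for the fold split.
#' @param select re-run [forward_select()] within each fold?
#' @param entry_p entry p-value when selecting.
#' @param outcome outcome column name.
#' @return A `roc_result` on the pooled out-of-fold predictions, with the
#'   fold assignment in attribute `folds`.
#' @export
cross_validated_auc <- function(cohort, variables, k = 10, seed = 1L,
                                select = FALSE, entry_p = 0.05,
                                outcome = "node_binary") {
  if (k < 2) stop2("`k` must be at least 2")
  y <- cohort[[outcome]]
  if (min(sum(y == 1), sum(y == 0)) < k)
    stop2("a class is too rare to stratify into ", k,
          " folds; use a smaller k")
  fold <- with_seed(seed, .stratified_folds(y, k))
  probs <- numeric(nrow(cohort))
  for (f in seq_len(k)) {
    train <- cohort[fold != f, , drop = FALSE]
    test <- cohort[fold == f, , drop = FALSE]
    m <- if (select) forward_select(train, variables, entry_p, outcome)
    else fit_logistic(train, variables, outcome)
    probs[fold == f] <- predict(m, test)
  }
  out <- roc_auc(y, probs)
  attr(out, "folds") <- fold
  attr(out, "cv_probs") <- probs
  out
}

# quantile bins of predicted risk with ties kept together; may return
# fewer than g bins
.risk_bins <- function(probs, g) {
  br <- unique(quantile(probs, seq(0, 1, length.out = g + 1), names = FALSE))
  if (length(br) < 2) return(factor(rep(1, length(probs))))
  cut(probs, br, include.lowest = TRUE)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups patients into `g` quantile bins of predicted risk (ties kept
#' together) and compares observed and expected event counts;
#' `chi2 = sum (O - E)^2 / (E (1 - E/n_bin))` referred to a chi-square
#' with `g - 2` degrees of freedom (reduced when tied probabilities merge
#' bins, with a warning).
#'
#' @param labels 0/1 outcome vector.
#' @param probs predicted probabilities.
#' @param g number of risk groups; default 10.
#' @return An object of class `htest` with `statistic`, `parameter` (df)
#'   and `p.value`.
#' @export
hosmer_lemeshow <- function(labels, probs, g = 10) {
  if (g < 3) stop2("`g` must be at least 3")
  n <- length(labels)
  if (n < 5 * g) stop2("need at least 5 observations per group")
  bins <- .risk_bins(probs, g)
  nb <- nlevels(droplevels(bins))
  if (nb < g)
    warning("tied probabilities merged risk groups: ", nb, " bins, df = ",
            max(nb - 2, 1), call. = FALSE)
  bins <- droplevels(bins)
  O <- tapply(labels, bins, sum)
  E <- tapply(probs, bins, sum)
  nn <- tabulate(bins)
  v <- E * (1 - E / nn)
  ok <- v > 0
  chi2 <- sum((O[ok] - E[ok])^2 / v[ok])
  df <- max(sum(ok) - 2, 1)
  structure(list(statistic = c("X-squared" = chi2),
                 parameter = c(df = df),
                 p.value = pchisq(chi2, df, lower.tail = FALSE),
                 method = "Hosmer-Lemeshow goodness-of-fit test",
                 data.name = deparse(substitute(probs)),
                 observed = O, expected = E, bin_n = nn),
            class = "htest")
}

#' Calibration curve of predicted risk
#'
#' Quantile-bins the predictions and reports the mean predicted risk and
#' the observed event fraction (with an exact binomial confidence
#' interval) per bin.
#'
#' @param labels 0/1 outcome vector.
#' @param probs predicted probabilities in `[0, 1]`.
#' @param bins number of quantile bins; default 10. Constant predictions
#'   collapse into a single bin.
#' @return data.frame with `bin`, `n`, `mean_predicted`,
#'   `observed_fraction`, `ci_low`, `ci_high`.
#' @export
calibration_curve <- function(labels, probs, bins = 10) {
  if (length(probs) && (min(probs) < 0 || max(probs) > 1))
    stop2("`probs` must lie in [0, 1]")
  if (length(labels) == 0)
    return(data.frame(bin = integer(), n = integer(),
                      mean_predicted = numeric(),
                      observed_fraction = numeric(),
                      ci_low = numeric(), ci_high = numeric()))
  bn <- droplevels(.risk_bins(probs, bins))
  out <- lapply(seq_len(nlevels(bn)), function(b) {
    sel <- as.integer(bn) == b
    nb <- sum(sel)
    ev <- sum(labels[sel])
    ci <- binom.test(ev, nb)$conf.int
    data.frame(bin = b, n = nb, mean_predicted = mean(probs[sel]),
               observed_fraction = ev / nb, ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, out)
}
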