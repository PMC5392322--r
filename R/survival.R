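#' Assign tertiles
#'
#' Cuts a numeric vector at its empirical 33.3% and 66.7% percentiles
#' (linear-interpolation quantiles). The lower boundary is inclusive
#' upward (`value <= q1` is tertile 1, `q1 < value <= q2` tertile 2), so
#' tied values always share a tertile.
#'
#' @param values numeric vector with at least 3 distinct values.
#' @return Integer vector of labels in `{1, 2, 3}`.
#' @export
assign_tertiles <- function(values) {
  if (length(unique(values)) < 3)
    stop2("need at least 3 distinct values to form tertiles")
  q <- quantile(values, c(1, 2) / 3, names = FALSE, type = 7)
  1L + (values > q[1]) + (values > q[2])
}

.endpoint_cols <- function(endpoint) {
  endpoint <- match.arg(endpoint, c("os", "pfs"))
  list(time = paste0(endpoint, "_time"), event = paste0(endpoint, "_event"))
}

#' Kaplan-Meier survival curves with at-risk counts
#'
#' Product-limit estimates per group, plus the numbers at risk at fixed
#' landmark times (default 0, 1, 3 and 5 years) for the at-risk table
#' under the plot.
#'
#' @param times follow-up times (years), non-negative.
#' @param events 0/1 event indicators.
#' @param groups optional grouping vector; a single pooled curve when
#'   omitted.
#' @param at_risk_times landmark times for at-risk counts.
#' @return An object of class `km_curves`: list with `curves` (data.frame
#'   `group`, `time`, `n_risk`, `n_event`, `n_censor`, `surv`) and
#'   `at_risk` (data.frame `group`, `time`, `n_risk`).
#' @export
kaplan_meier <- function(times, events, groups = NULL,
                         at_risk_times = c(0, 1, 3, 5)) {
  if (any(times < 0)) stop2("survival times must be non-negative")
  if (is.null(groups)) groups <- rep("all", length(times))
  df <- data.frame(t = times, e = events, g = factor(groups))
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  strat_of <- function(s) {
    if (is.null(s$strata)) rep(levels(df$g)[1], length(s$time))
    else sub("^g=", "", rep(names(s$strata), s$strata))
  }
  s <- summary(fit, censored = TRUE)
  curves <- data.frame(group = strat_of(s), time = s$time,
                       n_risk = s$n.risk, n_event = s$n.event,
                       n_censor = s$n.censor, surv = s$surv)
  a <- summary(fit, times = at_risk_times, extend = TRUE)
  at_risk <- data.frame(group = strat_of(a), time = a$time,
                        n_risk = a$n.risk)
  structure(list(curves = curves, at_risk = at_risk),
            class = "km_curves")
}

#' Log-rank test
#'
#' @param times,events,groups as in [kaplan_meier()]; at least two groups
#'   and one event overall.
#' @return List with `chi2`, `df` (groups - 1) and `p`.
#' @export
logrank <- function(times, events, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop2("log-rank test needs at least 2 groups")
  if (sum(events) < 1) stop2("log-rank test needs at least one event")
  df <- data.frame(t = times, e = events, g = g)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g, data = df)
  k <- length(sd$n) - 1
  list(chi2 = as.numeric(sd$chisq), df = k,
       p = pchisq(as.numeric(sd$chisq), k, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood maximization (Newton-Raphson) with Efron handling of
#' tied event times by default (Breslow available for compatibility with
#' older software defaults), Wald confidence intervals and p-values.
#'
#' @param cohort data.frame containing the endpoint and covariate columns.
#' @param variables covariate names (factors allowed).
#' @param endpoint `"os"` (columns `os_time`/`os_event`) or `"pfs"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_result`: list with `terms` (data.frame
#'   `term`, `hr`, `ci_low`, `ci_high`, `p`), `loglik` (log partial
#'   likelihood at the estimate), `n`, `n_event`, `endpoint` and `fit`.
#' @export
cox_fit <- function(cohort, variables, endpoint = "os",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  ec <- .endpoint_cols(endpoint)
  if (is.null(cohort[[ec$time]]) || is.null(cohort[[ec$event]]))
    stop2("cohort lacks ", ec$time, "/", ec$event, " columns")
  if (sum(cohort[[ec$event]]) < 1) stop2("no events for endpoint ", endpoint)
  for (v in variables)
    if (length(unique(cohort[[v]])) < 2)
      stop2("variable '", v, "' is constant")
  fml <- as.formula(paste0("survival::Surv(", ec$time, ", ", ec$event,
                           ") ~ ", paste(variables, collapse = " + ")))
  fit <- survival::coxph(fml, data = cohort, ties = ties)
  cf <- coef(fit)
  if (anyNA(cf) || any(abs(cf) > 15))
    stop2("Cox fit did not converge (monotone likelihood in: ",
          paste(names(cf)[is.na(cf) | abs(cf) > 15], collapse = ", "), ")")
  sm <- summary(fit)
  terms <- data.frame(term = rownames(sm$coefficients),
                      hr = sm$conf.int[, 1],
                      ci_low = sm$conf.int[, 3],
                      ci_high = sm$conf.int[, 4],
                      p = sm$coefficients[, "Pr(>|z|)"])
  rownames(terms) <- NULL
  structure(list(terms = terms, loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, n_event = fit$nevent, endpoint = endpoint,
                 ties = ties, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> endpoint %s, n = %d, events = %d (%s ties)\n",
              x$endpoint, x$n, x$n_event, x$ties))
  print(transform(x$terms, hr = round(hr, 3), ci_low = round(ci_low, 3),
                  ci_high = round(ci_high, 3), p = signif(p, 3)))
  invisible(x)
}

# log partial likelihood of a variable set (NULL model allowed)
.cox_ll <- function(cohort, variables, endpoint, ties) {
  ec <- .endpoint_cols(endpoint)
  if (length(variables) == 0) {
    fml <- as.formula(paste0("survival::Surv(", ec$time, ", ", ec$event,
                             ") ~ 1"))
    fit <- survival::coxph(fml, data = cohort, ties = ties)
    return(fit$loglik[1])
  }
  cox_fit(cohort, variables, endpoint, ties)$loglik
}

.cox_lr_p <- function(cohort, base, extra, endpoint, ties) {
  ll0 <- .cox_ll(cohort, base, endpoint, ties)
  ll1 <- .cox_ll(cohort, c(base, extra), endpoint, ties)
  x1 <- cohort[[extra]]
  df <- if (is.factor(x1) || is.character(x1))
    length(unique(x1)) - 1 else 1
  pchisq(max(2 * (ll1 - ll0), 0), df, lower.tail = FALSE)
}

#' Multivariate Cox model with conditional forward elimination
#'
#' Stepwise model building in the style of conditional forward selection:
#' at each step the candidate with the smallest likelihood-ratio p-value
#' enters if below `entry_p`; after every entry the included variables are
#' re-tested by likelihood ratio and the least significant is removed
#' while its p-value exceeds `removal_p`. Ties break by candidate order
#' and the procedure iterates to a fixed point, so it is deterministic.
#'
#' @inheritParams cox_fit
#' @param candidates candidate variable names, non-empty.
#' @param entry_p LR p-value required to enter; default 0.05.
#' @param removal_p LR p-value above which an included variable is
#'   dropped; default 0.10.
#' @return A `cox_result` on the selected variables (`NULL` terms when no
#'   variable enters), with the selected set in `variables`.
#' @export
cox_forward <- function(cohort, candidates, endpoint = "os",
                        entry_p = 0.05, removal_p = 0.10,
                        ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (length(candidates) == 0) stop2("`candidates` must be non-empty")
  ec <- .endpoint_cols(endpoint)
  if (sum(cohort[[ec$event]]) < 10)
    warning("fewer than 10 events; stepwise selection is unstable",
            call. = FALSE)
  selected <- character()
  remaining <- candidates
  seen <- character()
  for (step in seq_len(50)) {
    # entry
    entered <- FALSE
    if (length(remaining)) {
      ps <- vapply(remaining, function(v)
        .cox_lr_p(cohort, selected, v, endpoint, ties), 0)
      best <- which.min(ps)
      if (ps[best] < entry_p) {
        selected <- c(selected, remaining[best])
        remaining <- remaining[-best]
        entered <- TRUE
      }
    }
    # conditional removal of previously included variables
    repeat {
      if (length(selected) < 2) break
      pr <- vapply(selected, function(v)
        .cox_lr_p(cohort, setdiff(selected, v), v, endpoint, ties), 0)
      worst <- which.max(pr)
      if (pr[worst] <= removal_p) break
      remaining <- c(remaining, selected[worst])
      selected <- selected[-worst]
    }
    key <- paste(sort(selected), collapse = "|")
    if (!entered || key %in% seen) break
    seen <- c(seen, key)
  }
  if (length(selected) == 0) {
    return(structure(list(terms = data.frame(term = character(),
                                             hr = numeric(),
                                             ci_low = numeric(),
                                             ci_high = numeric(),
                                             p = numeric()),
                          loglik = .cox_ll(cohort, character(), endpoint,
                                           ties),
                          n = nrow(cohort),
                          n_event = sum(cohort[[ec$event]]),
                          endpoint = endpoint, ties = ties, fit = NULL,
                          variables = character()),
                     class = "cox_result"))
  }
  out <- cox_fit(cohort, selected, endpoint, ties)
  out$variables <- selected
  out
}

#' Prognostic value of the bud count across bud-size definitions
#'
#' For each candidate bud definition of `n` cells, assigns tertiles of the
#' corresponding count and fits a Cox model with the tertile as an ordinal
#' covariate, giving a hazard ratio per tertile increment; a least-squares
#' line of log HR on `n` summarizes the trend of prognostic value with bud
#' size. Definitions whose counts cannot form tertiles (for example when
#' more than a third of patients share a count of zero at small `n`) are
#' flagged and skipped with a warning.
#'
#' @param sweep_counts output of [sweep_bud_definitions()]; `patient` must
#'   match `cohort$id`.
#' @param cohort data.frame with `id` and the endpoint columns.
#' @param endpoint `"os"` or `"pfs"`.
#' @param ties tie handling for the Cox fits.
#' @return List of class `budsize_sweep` with `per_n` (data.frame
#'   `n_cells`, `threshold_um2`, `hr_per_tertile`, `ci_low`, `ci_high`,
#'   `p`, `skipped`) and `trend` (list `slope`, `se`, `p` of the log-HR
#'   regression, or `NULL` when fewer than 2 usable definitions).
#' @export
budsize_prognosis_sweep <- function(sweep_counts, cohort, endpoint = "os",
                                    ties = "efron") {
  ec <- .endpoint_cols(endpoint)
  ns <- sort(unique(sweep_counts$n_cells))
  rows <- lapply(ns, function(nc) {
    sub <- sweep_counts[sweep_counts$n_cells == nc, ]
    m <- match(cohort$id, sub$patient)
    if (anyNA(m)) stop2("sweep counts missing for some patients at n = ", nc)
    cnt <- sub$count[m]
    row <- data.frame(n_cells = nc, threshold_um2 = sub$threshold_um2[1],
                      hr_per_tertile = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p = NA_real_, skipped = TRUE)
    tert <- tryCatch(assign_tertiles(cnt), error = function(e) NULL)
    if (is.null(tert) || length(unique(tert)) < 2) {
      warning("bud definition n = ", nc,
              " skipped: counts do not form tertiles", call. = FALSE)
      return(row)
    }
    cc <- cohort
    cc$..tert <- as.numeric(tert)
    fit <- tryCatch(cox_fit(cc, "..tert", endpoint, ties),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("bud definition n = ", nc, " skipped: Cox fit failed",
              call. = FALSE)
      return(row)
    }
    row$hr_per_tertile <- fit$terms$hr[1]
    row$ci_low <- fit$terms$ci_low[1]
    row$ci_high <- fit$terms$ci_high[1]
    row$p <- fit$terms$p[1]
    row$skipped <- FALSE
    row
  })
  per_n <- do.call(rbind, rows)
  ok <- !per_n$skipped
  trend <- NULL
  if (sum(ok) >= 2) {
    lf <- lm(log(hr_per_tertile) ~ n_cells, data = per_n[ok, ])
    sm <- summary(lf)$coefficients
    trend <- list(slope = sm["n_cells", "Estimate"],
                  se = sm["n_cells", "Std. Error"],
                  p = sm["n_cells", "Pr(>|t|)"])
  }
  structure(list(per_n = per_n, trend = trend), class = "budsize_sweep")
}
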