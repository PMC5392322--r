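#' Net benefit of a risk-guided treatment strategy
#'
#' A patient is treated (neck dissection) when the predicted probability
#' of occult nodal disease reaches the threshold probability `pt`. The net
#' benefit weighs false positives by the odds of the threshold:
#' `NB = TP/n - (FP/n) * pt / (1 - pt)`.
#'
#' @param labels 0/1 outcome vector.
#' @param probs predicted probabilities (any scores on the probability
#'   scale; `probs >= pt` means treat).
#' @param pt threshold probability, strictly inside (0, 1).
#' @return Net benefit (true positives gained per patient, net of
#'   threshold-weighted overtreatment).
#' @export
net_benefit <- function(labels, probs, pt) {
  if (length(labels) != length(probs))
    stop2("`labels` and `probs` must have the same length")
  if (!is.numeric(pt) || length(pt) != 1 || pt <= 0 || pt >= 1)
    stop2("`pt` must lie strictly inside (0, 1)")
  n <- length(labels)
  treat <- probs >= pt
  tp <- sum(treat & labels == 1)
  fp <- sum(treat & labels == 0)
  tp / n - (fp / n) * pt / (1 - pt)
}

#' Net benefit of treating everyone
#'
#' Closed form `prevalence - (1 - prevalence) * pt / (1 - pt)`; zero
#' exactly at `pt = prevalence`.
#'
#' @param prevalence positive fraction in `[0, 1]`.
#' @param pt threshold probability in (0, 1).
#' @return Net benefit of the treat-all strategy.
#' @export
net_benefit_all <- function(prevalence, pt) {
  if (prevalence < 0 || prevalence > 1)
    stop2("`prevalence` must lie in [0, 1]")
  if (pt <= 0 || pt >= 1) stop2("`pt` must lie strictly inside (0, 1)")
  prevalence - (1 - prevalence) * pt / (1 - pt)
}

#' Net reduction in unnecessary interventions per 100 patients
#'
#' Interventions avoided, relative to treating everyone, without missing
#' any true positives:
#' `(NB_model - NB_all) * (1 - pt) / pt * 100`.
#'
#' @inheritParams net_benefit
#' @return Net reduction in interventions per 100 patients.
#' @export
net_reduction <- function(labels, probs, pt) {
  nb_model <- net_benefit(labels, probs, pt)
  nb_all <- net_benefit_all(mean(labels == 1), pt)
  (nb_model - nb_all) * (1 - pt) / pt * 100
}

#' Decision curve over a threshold-probability grid
#'
#' Tabulates net benefit and net reduction (vs treat-all) for each named
#' strategy plus the treat-all and treat-none references, over the
#' clinically relevant threshold range (default 1-50%).
#'
#' @param labels 0/1 outcome vector.
#' @param strategy_scores named list of probability vectors, one per
#'   strategy.
#' @param pt_grid thresholds; default `seq(0.01, 0.50, by = 0.01)`.
#' @return A data.frame of class `decision_curve` with columns `strategy`,
#'   `threshold_pt`, `net_benefit`, `net_reduction_per100`.
#' @export
decision_curve <- function(labels, strategy_scores,
                           pt_grid = seq(0.01, 0.50, by = 0.01)) {
  if (length(strategy_scores) == 0 || is.null(names(strategy_scores)))
    stop2("`strategy_scores` must be a non-empty named list")
  if (length(pt_grid) == 0) stop2("`pt_grid` must be non-empty")
  n <- length(labels)
  all_strats <- c(strategy_scores,
                  list(treat_all = rep(1, n), treat_none = rep(0, n)))
  rows <- lapply(names(all_strats), function(s) {
    nb <- vapply(pt_grid, function(pt)
      net_benefit(labels, all_strats[[s]], pt), 0)
    nr <- vapply(pt_grid, function(pt)
      net_reduction(labels, all_strats[[s]], pt), 0)
    data.frame(strategy = s, threshold_pt = pt_grid, net_benefit = nb,
               net_reduction_per100 = nr)
  })
  structure(do.call(rbind, rows),
            class = c("decision_curve", "data.frame"))
}

#' Plot a decision curve
#'
#' @param x a [decision_curve()].
#' @param what `"net_benefit"` or `"net_reduction_per100"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot.decision_curve <- function(x, what = c("net_benefit",
                                            "net_reduction_per100"), ...) {
  what <- match.arg(what)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop2("plotting requires the ggplot2 package")
  df <- data.frame(pt = x$threshold_pt, y = x[[what]],
                   strategy = x$strategy)
  ggplot2::ggplot(df, ggplot2::aes(pt, y, colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "threshold probability",
                  y = gsub("_", " ", what)) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("pt", "y", "strategy"))
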