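#' Specification of a synthetic patient cohort
#'
#' Generates early-stage oral squamous cell carcinoma cohorts with the
#' statistical structure needed downstream: a right-skewed
#' (negative-binomial) digital tumor bud count, clinicopathological
#' covariates with realistic category frequencies, occult nodal status
#' drawn from a logistic model on the log-odds scale, and overall /
#' progression-free survival from exponential proportional-hazards models
#' with uniform administrative censoring.
#'
#' Coefficients in `node_model`, `os_model` and `pfs_model` are named by
#' the numeric design columns of the generated table: `dtbc_tertile`,
#' `depth_mm`, `depth_gt4`, `grade_moderate`, `grade_poor`,
#' `front_noncohesive`, `pni`, `ct2`, `site_tongue`, `site_other`,
#' `age_c` (age in decades, centered at 64), `male`, `smoking_high`,
#' and (for the survival models) `node_binary`.
#'
#' @param n_patients cohort size; default 222.
#' @param dtbc list `mean`, `dispersion` (negative-binomial size).
#' @param depth list `meanlog`, `sdlog` of lognormal invasion depth (mm).
#' @param grade_probs,site_probs named probability vectors (sum to 1).
#' @param p_noncohesive,p_pni,p_ct2,p_male,p_smoking_high scalar
#'   probabilities.
#' @param age list `mean`, `sd` (years).
#' @param node_model list `intercept` (log-odds) and named `coefficients`;
#'   defaults give a marginal node-positive fraction near 0.34.
#' @param p_micro_given_pos probability that a node-positive patient has
#'   only isolated tumor cells / micrometastases (vs macrometastases).
#' @param os_model,pfs_model lists `baseline_rate` (events per year at
#'   design zero) and named `coefficients` (log hazard ratios).
#' @param censor_years administrative censoring window; censoring times
#'   are uniform on `[0, censor_years]`.
#' @param seed integer seed; the only source of randomness.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_patients = 222,
    dtbc = list(mean = 400, dispersion = 0.9),
    depth = list(meanlog = log(4), sdlog = 0.7),
    grade_probs = c(well = 0.26, moderate = 0.59, poor = 0.15),
    site_probs = c(floor = 0.47, tongue = 0.42, other = 0.11),
    p_noncohesive = 0.60, p_pni = 0.29, p_ct2 = 0.35,
    p_male = 0.57, p_smoking_high = 0.78,
    age = list(mean = 64, sd = 13),
    node_model = list(
      intercept = -3.16,
      coefficients = c(dtbc_tertile = 0.9, depth_gt4 = 0.6,
                       front_noncohesive = 0.5)),
    p_micro_given_pos = 0.35,
    os_model = list(
      baseline_rate = 0.025,
      coefficients = c(dtbc_tertile = log(1.6), node_binary = log(1.7),
                       age_c = 0.35)),
    pfs_model = list(
      baseline_rate = 0.012,
      coefficients = c(dtbc_tertile = log(2.3), node_binary = log(1.5))),
    censor_years = 8, seed = 1L) {
  fields <- list(
    n_patients = n_patients, dtbc = dtbc, depth = depth,
    grade_probs = grade_probs, site_probs = site_probs,
    p_noncohesive = p_noncohesive, p_pni = p_pni, p_ct2 = p_ct2,
    p_male = p_male, p_smoking_high = p_smoking_high, age = age,
    node_model = node_model, p_micro_given_pos = p_micro_given_pos,
    os_model = os_model, pfs_model = pfs_model,
    censor_years = censor_years, seed = as.integer(seed))
  for (p in list(grade_probs, site_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop2("categorical probabilities must be non-negative and sum to 1")
  }
  for (p in c(p_noncohesive, p_pni, p_ct2, p_male, p_smoking_high,
              p_micro_given_pos))
    if (p < 0 || p > 1) stop2("probabilities must lie in [0, 1]")
  if (!is_count(n_patients) || n_patients < 1)
    stop2("`n_patients` must be a positive integer")
  if (censor_years < 0) stop2("`censor_years` must be non-negative")
  structure(fields, class = "cohort_spec")
}

# linear predictor over the numeric design columns; every coefficient name
# must resolve to a numeric column
.linpred <- function(df, intercept, coefficients) {
  lp <- rep(intercept, nrow(df))
  for (nm in names(coefficients)) {
    x <- df[[nm]]
    if (is.null(x) || !is.numeric(x))
      stop2("model coefficient '", nm, "' does not match a numeric column")
    lp <- lp + coefficients[[nm]] * x
  }
  if (any(!is.finite(lp))) stop2("non-finite linear predictor")
  lp
}

#' Simulate a patient cohort
#'
#' Draws covariates, nodal status (Bernoulli with logistic link) and
#' survival endpoints (exponential event times under proportional hazards,
#' censored by a uniform administrative window) per the spec. Deterministic
#' given the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with one row per patient; factor covariates plus
#'   the numeric design columns listed in [cohort_spec()], `node_status`
#'   (`N0` / `ITC-micro` / `macro`), `node_binary`, and
#'   `os_time`/`os_event`/`pfs_time`/`pfs_event` (years, 0/1 flags).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    d <- data.frame(id = sprintf("pt_%04d", seq_len(n)))
    d$dtbc <- rnbinom(n, size = spec$dtbc$dispersion,
                      mu = spec$dtbc$mean)
    d$dtbc_tertile <- if (length(unique(d$dtbc)) >= 3)
      assign_tertiles(d$dtbc) else rep(1L, n)
    d$depth_mm <- rlnorm(n, spec$depth$meanlog, spec$depth$sdlog)
    d$depth_gt4 <- as.integer(d$depth_mm > 4)
    d$grade <- factor(sample(names(spec$grade_probs), n, TRUE,
                             spec$grade_probs),
                      levels = names(spec$grade_probs))
    d$grade_moderate <- as.integer(d$grade == "moderate")
    d$grade_poor <- as.integer(d$grade == "poor")
    d$front <- factor(ifelse(runif(n) < spec$p_noncohesive,
                             "non-cohesive", "cohesive"),
                      levels = c("cohesive", "non-cohesive"))
    d$front_noncohesive <- as.integer(d$front == "non-cohesive")
    d$pni <- rbinom(n, 1, spec$p_pni)
    d$ct_stage <- factor(ifelse(runif(n) < spec$p_ct2, "cT2", "cT1"),
                         levels = c("cT1", "cT2"))
    d$ct2 <- as.integer(d$ct_stage == "cT2")
    d$site <- factor(sample(names(spec$site_probs), n, TRUE,
                            spec$site_probs),
                     levels = names(spec$site_probs))
    d$site_tongue <- as.integer(d$site == "tongue")
    d$site_other <- as.integer(d$site == "other")
    d$age <- rnorm(n, spec$age$mean, spec$age$sd)
    d$age_c <- (d$age - 64) / 10
    d$sex <- factor(ifelse(runif(n) < spec$p_male, "male", "female"),
                    levels = c("female", "male"))
    d$male <- as.integer(d$sex == "male")
    d$smoking <- factor(ifelse(runif(n) < spec$p_smoking_high,
                               "high", "low"), levels = c("low", "high"))
    d$smoking_high <- as.integer(d$smoking == "high")

    lp_node <- .linpred(d, spec$node_model$intercept,
                        spec$node_model$coefficients)
    d$node_binary <- rbinom(n, 1, plogis(lp_node))
    micro <- runif(n) < spec$p_micro_given_pos
    d$node_status <- factor(
      ifelse(d$node_binary == 0, "N0",
             ifelse(micro, "ITC-micro", "macro")),
      levels = c("N0", "ITC-micro", "macro"))

    cens <- runif(n, 0, spec$censor_years)
    for (ep in c("os", "pfs")) {
      m <- spec[[paste0(ep, "_model")]]
      rate <- m$baseline_rate * exp(.linpred(d, 0, m$coefficients))
      t_event <- if (all(rate > 0)) rexp(n, rate) else rep(Inf, n)
      d[[paste0(ep, "_time")]] <- pmin(t_event, cens)
      d[[paste0(ep, "_event")]] <- as.integer(t_event <= cens)
    }
    d
  })
}

#' Cohort with a known optimal AUC
#'
#' Builds a two-class cohort in which a single standardized composite
#' score carries all the signal. Controls score `N(0, 1)` and cases
#' `N(delta, 1)` with `delta = sqrt(2) * qnorm(target_auc)`, the binormal
#' identity, so the Bayes-optimal AUC of the score equals `target_auc`
#' exactly; equivalently the true log-odds are linear in the score with
#' slope `delta`.
#'
#' @param n_patients cohort size.
#' @param target_auc target AUC, strictly inside (0.5, 1).
#' @param prevalence marginal positive fraction; default 0.34.
#' @param seed integer seed.
#' @return data.frame with `id`, `score` and `node_binary`; the implied
#'   logistic slope is attached as attribute `delta`.
#' @export
cohort_with_target_auc <- function(n_patients, target_auc,
                                   prevalence = 0.34, seed = 1L) {
  if (!is.numeric(target_auc) || length(target_auc) != 1 ||
      target_auc <= 0.5 || target_auc >= 1)
    stop2("`target_auc` must lie strictly inside (0.5, 1)")
  delta <- sqrt(2) * qnorm(target_auc)
  with_seed(seed, {
    y <- rbinom(n_patients, 1, prevalence)
    score <- rnorm(n_patients) + delta * y
    structure(data.frame(id = sprintf("pt_%05d", seq_len(n_patients)),
                         score = score, node_binary = y),
              delta = delta)
  })
}
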