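#' Run configuration for the end-to-end pipeline
#'
#' Bundles the stage parameters for [run_pipeline()]. Either a cohort CSV
#' path or a [cohort_spec()] must supply the patient table; phantom specs
#' are optional and exercised for image scoring when present.
#'
#' @param cohort_csv path to a cohort CSV (see [simulate_cohort()] for the
#'   column dictionary), or `NULL`.
#' @param cohort_spec a [cohort_spec()] used when no CSV is given.
#' @param phantoms list of [phantom_spec()] objects to score (may be
#'   empty).
#' @param stain a [stain_params()].
#' @param bud a [bud_params()].
#' @param risk_variables candidate covariates for the nodal risk model.
#' @param select use forward selection (`TRUE`) or fit all candidates.
#' @param cv_folds folds for the cross-validated AUC.
#' @param seed integer seed for fold splitting.
#' @param pt_grid decision-curve threshold grid.
#' @param endpoints survival endpoints to analyze.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort_csv = NULL, cohort_spec = NULL,
                       phantoms = list(), stain = stain_params(),
                       bud = bud_params(),
                       risk_variables = c("dtbc_tertile", "depth_gt4",
                                          "front_noncohesive", "pni",
                                          "ct2", "age_c"),
                       select = TRUE, cv_folds = 10, seed = 1L,
                       pt_grid = seq(0.01, 0.5, by = 0.01),
                       endpoints = c("os", "pfs")) {
  if (is.null(cohort_csv) && is.null(cohort_spec))
    stop2("supply `cohort_csv` or `cohort_spec`")
  if (!is_count(seed)) stop2("`seed` must be an integer")
  structure(list(cohort_csv = cohort_csv, cohort_spec = cohort_spec,
                 phantoms = phantoms, stain = stain, bud = bud,
                 risk_variables = risk_variables, select = select,
                 cv_folds = cv_folds, seed = as.integer(seed),
                 pt_grid = pt_grid, endpoints = endpoints),
            class = "run_config")
}

#' Demo configuration on generated data
#'
#' Three small phantoms with known island geometry plus a simulated
#' cohort, so the whole pipeline runs in seconds with no external input.
#'
#' @param seed integer seed.
#' @return A [run_config()].
#' @export
demo_config <- function(seed = 1L) {
  ph <- lapply(1:3, function(i)
    phantom_spec(canvas = c(220, 220),
                 island_areas_um2 = c(rep(400, 3 + i), 2000),
                 artifact_areas_um2 = c(60, 90),
                 seed = seed + i))
  run_config(cohort_spec = cohort_spec(seed = seed), phantoms = ph,
             stain = stain_params(analysis_scale_factor = 1L),
             seed = seed)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: phantom scoring (when phantoms are configured),
#' cohort assembly, the nodal risk model with cross-validated AUC and
#' Hosmer-Lemeshow calibration, decision-curve analysis, and tertile-based
#' survival analysis (Kaplan-Meier, log-rank, univariate and stepwise Cox).
#' Every artifact is written under `out_dir` together with a config
#' snapshot; reruns with the same config are byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @param quiet suppress progress messages.
#' @return The run report (named list), invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[dtbc] ", ...)
  report <- list(seed = config$seed)

  # stage 1: image scoring on configured phantoms
  if (length(config$phantoms)) {
    say("scoring ", length(config$phantoms), " phantom image(s)")
    report$phantoms <- lapply(seq_along(config$phantoms), function(i) {
      ph <- generate_phantom(config$phantoms[[i]])
      res <- compute_dtbc(ph$image, ph$rois, config$stain, config$bud)
      list(phantom = i, dtbc = res$dtbc,
           dtbc_ground_truth = sum(ph$ground_truth$is_bud),
           n_regions = res$n_regions_total)
    })
  }

  # stage 2: cohort assembly
  cohort <- if (!is.null(config$cohort_csv)) {
    say("reading cohort from ", config$cohort_csv)
    utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
  } else {
    say("simulating cohort (n = ", config$cohort_spec$n_patients, ")")
    simulate_cohort(config$cohort_spec)
  }
  missing <- setdiff(c("node_binary", config$risk_variables), names(cohort))
  if (length(missing))
    stop2("cohort lacks required column(s): ",
          paste(missing, collapse = ", "))

  # stage 3: risk model
  say("fitting nodal risk model")
  model <- if (config$select)
    forward_select(cohort, config$risk_variables)
  else fit_logistic(cohort, config$risk_variables)
  apparent <- roc_auc(cohort$node_binary, predict(model))
  cv <- cross_validated_auc(cohort, config$risk_variables,
                            k = config$cv_folds, seed = config$seed,
                            select = config$select)
  hl <- hosmer_lemeshow(cohort$node_binary, predict(model))
  report$risk_model <- list(
    variables = model$variables,
    coefficients = as.list(model$coefficients),
    auc_apparent = apparent$auc,
    auc_apparent_ci = c(apparent$ci_low, apparent$ci_high),
    auc_cv = cv$auc, auc_cv_ci = c(cv$ci_low, cv$ci_high),
    hosmer_lemeshow = list(chi2 = unname(hl$statistic),
                           df = unname(hl$parameter),
                           p = hl$p.value))

  # stage 4: decision curves
  say("decision-curve analysis")
  dca <- decision_curve(cohort$node_binary,
                        list(risk_model = predict(model)),
                        config$pt_grid)
  report$decision_curve <- list(
    pt_range = range(config$pt_grid),
    max_net_reduction_per100 =
      max(dca$net_reduction_per100[dca$strategy == "risk_model"]))

  # stage 5: survival
  surv_cols <- paste0(rep(config$endpoints, each = 2),
                      c("_time", "_event"))
  if (all(surv_cols %in% names(cohort)) &&
      "dtbc_tertile" %in% names(cohort)) {
    report$survival <- lapply(setNames(nm = config$endpoints),
                              function(ep) {
      say("survival analysis (", ep, ")")
      ec <- .endpoint_cols(ep)
      lr <- logrank(cohort[[ec$time]], cohort[[ec$event]],
                    cohort$dtbc_tertile)
      uni <- cox_fit(cohort, "dtbc_tertile", ep)
      multi <- suppressWarnings(
        cox_forward(cohort, unique(c("dtbc_tertile",
                                     config$risk_variables)), ep))
      list(logrank = lr,
           hr_per_tertile = uni$terms$hr[1],
           multivariate_terms = multi$terms,
           multivariate_variables = multi$variables)
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(dca, file.path(out_dir, "decision_curve.csv"),
              row.names = FALSE)
    write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
    say("report written to ", out_dir)
    return(invisible(report))
  }
  report
}
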