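#' Pipeline configuration
#'
#' Collects every effective parameter of an end-to-end run: input paths (or
#' synthetic generation when they are `NULL`), HU thresholds, Brunelli
#' coefficient overrides, the resection plan, output directory and seed.
#' Validation happens here, before any computation.
#'
#' @param ct,labels NIfTI paths of the HU volume and label map; `NULL` means
#'   generate a synthetic phantom.
#' @param cohort_csv patient cohort CSV path; `NULL` means generate a
#'   synthetic cohort.
#' @param resection segments to remove: a lobe keyword (`"RUL"`, `"RML"`,
#'   `"RLL"`, `"left_lung"`), segment names (`c("S1","S2")`) or integer codes.
#'   Lobe keywords are expanded against the label table here, keeping the
#'   volumetric core nomenclature-agnostic.
#' @param theta_emph,theta_well_max HU thresholds (see [classify_volume()]);
#'   `theta_emph` must be below `theta_well_max`.
#' @param brunelli a [brunelli_coefficients()] object.
#' @param n_patients synthetic cohort size when `cohort_csv` is `NULL`.
#' @param phantom_shape grid of the synthetic phantom when `ct` is `NULL`.
#' @param seed integer seed driving all synthetic generation.
#' @param out_dir output directory (created if absent).
#' @param ties tie rule of [split_by_response()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(ct = NULL, labels = NULL, cohort_csv = NULL,
                            resection = "RUL",
                            theta_emph = -900, theta_well_max = -501,
                            brunelli = brunelli_coefficients(),
                            n_patients = 20, phantom_shape = c(64, 64, 60),
                            seed = 1, out_dir = tempfile("ppolung_run_"),
                            ties = "decrease") {
  if (theta_emph >= theta_well_max)
    stop("invalid thresholds: 'theta_emph' must be below 'theta_well_max'")
  if (!is.null(ct) && is.null(labels))
    stop("a CT volume requires a co-registered label map")
  stopifnot(inherits(brunelli, "brunelli_coefficients"), n_patients >= 1)
  structure(list(ct = ct, labels = labels, cohort_csv = cohort_csv,
                 resection = resection, theta_emph = theta_emph,
                 theta_well_max = theta_well_max, brunelli = brunelli,
                 n_patients = as.integer(n_patients),
                 phantom_shape = as.integer(phantom_shape),
                 seed = as.integer(seed), out_dir = out_dir,
                 ties = match.arg(ties, c("decrease", "increase"))),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys mirror the arguments of [pipeline_config()]; Brunelli
#' coefficient overrides sit under a `brunelli:` block with `fev1:` and
#' `dlco:` named maps.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$brunelli)) {
    def <- brunelli_coefficients()
    fev1 <- def$fev1; dlco <- def$dlco
    if (!is.null(raw$brunelli$fev1))
      fev1[names(raw$brunelli$fev1)] <- unlist(raw$brunelli$fev1)
    if (!is.null(raw$brunelli$dlco))
      dlco[names(raw$brunelli$dlco)] <- unlist(raw$brunelli$dlco)
    raw$brunelli <- brunelli_coefficients(fev1 = fev1, dlco = dlco)
  }
  if (!is.null(raw$resection)) raw$resection <- unlist(raw$resection)
  if (!is.null(raw$phantom_shape)) raw$phantom_shape <- unlist(raw$phantom_shape)
  do.call(pipeline_config, raw)
}

# lobe keyword -> member segment names; anything else passes through
expand_resection <- function(resection, table) {
  if (is.character(resection) && length(resection) == 1L &&
      resection %in% table$lobe) {
    return(table$segment[table$lobe == resection])
  }
  resection
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: load or synthesize the CT volume,
#' label map and patient cohort; classify tissue by HU thresholds; compute
#' region volumetrics; simulate the planned resection; predict postoperative
#' FEV1/DLCO per patient under the 5% rule, the Brunelli regressions and the
#' volumetric model; split the cohort by FEV1 response and compare the
#' groups. Writes `volumetrics.csv`, `predictions.csv`, `comparison.json`
#' and `run.log` into the output directory; given a seed the CSV/JSON
#' payloads are fully deterministic.
#'
#' Per-patient removed functional fractions come from the cohort's
#' `truth_removed_functional_fraction` column when present, otherwise the
#' CT-derived fraction of the simulated resection is used for every patient.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory results and `paths` of the
#'   written artifacts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(config$out_dir, 2) != 0)
    stop("output directory not writable: ", config$out_dir)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
    invisible(NULL)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  say("ppolung %s", as.character(utils::packageVersion("ppolung")))
  say("seed: %d", config$seed)
  say("thresholds: theta_emph=%g theta_well_max=%g",
      config$theta_emph, config$theta_well_max)
  say("brunelli fev1: %s", paste(sprintf("%s=%g", names(config$brunelli$fev1),
                                         config$brunelli$fev1), collapse = " "))
  say("brunelli dlco: %s", paste(sprintf("%s=%g", names(config$brunelli$dlco),
                                         config$brunelli$dlco), collapse = " "))

  inputs <- stage("inputs", {
    if (is.null(config$ct)) {
      say("ct: synthetic phantom %s (seed %d)",
          paste(config$phantom_shape, collapse = "x"), config$seed)
      ph <- make_phantom(phantom_spec(shape = config$phantom_shape,
                                      seed = config$seed))
      list(vol = ph$volume, labels = ph$labels)
    } else {
      say("ct: %s / labels: %s", config$ct, config$labels)
      list(vol = read_hu_volume(config$ct),
           labels = read_lung_label_map(config$labels))
    }
  })
  cohort <- stage("cohort", {
    if (is.null(config$cohort_csv)) {
      say("cohort: synthetic n=%d (seed %d)", config$n_patients,
          config$seed + 1L)
      make_cohort(cohort_spec(n = config$n_patients, seed = config$seed + 1L))
    } else {
      say("cohort: %s", config$cohort_csv)
      read_cohort_csv(config$cohort_csv)
    }
  })

  classmap <- stage("classify", classify_volume(
    inputs$vol, inputs$labels,
    theta_emph = config$theta_emph, theta_well_max = config$theta_well_max))
  volumetrics <- stage("volumetrics",
                       region_volumetrics(classmap, inputs$labels, inputs$vol))
  plan <- stage("resection_plan", resection_plan(
    expand_resection(config$resection, inputs$labels$table),
    inputs$labels$table))
  sim <- stage("simulate_resection", simulate_resection(volumetrics, plan))
  say("resection: segments %s -> removed %.2f%% total, %.2f%% functional",
      paste(plan$codes, collapse = ","), 100 * sim$removed_total_fraction,
      100 * sim$removed_functional_fraction)

  rff <- if ("truth_removed_functional_fraction" %in% names(cohort)) {
    cohort$truth_removed_functional_fraction
  } else rep(sim$removed_functional_fraction, nrow(cohort))
  predictions <- stage("predict", predict_ppo(
    preop_fev1 = cohort$preop_fev1_l, preop_dlco = cohort$preop_dlco,
    age = cohort$age, fev1_pct_pred = cohort$preop_fev1_pct / 100,
    fev1_fvc = cohort$preop_fev1_fvc,
    segments_removed = cohort$segments_removed,
    removed_functional_fraction = rff, coefficients = config$brunelli))

  analysis <- stage("analyze", {
    groups <- split_by_response(cohort, ties = config$ties)
    vars <- intersect(
      c("preop_fev1_l", "postop_fev1_l", "preop_dlco", "postop_dlco",
        "preop_rv_l", "postop_rv_l", "truth_healthy_over_total",
        "truth_removed_healthy_over_removed_total"),
      names(cohort))
    comparisons <- lapply(vars, function(v)
      compare_groups(groups$increase, groups$decrease, v))
    names(comparisons) <- vars
    fit <- fit_pre_post_line(cohort, "fev1_l")
    list(groups = groups, comparisons = comparisons, fit = fit)
  })

  paths <- stage("write", {
    p_vol <- file.path(config$out_dir, "volumetrics.csv")
    write_volumetrics_csv(volumetrics, p_vol)
    p_pred <- file.path(config$out_dir, "predictions.csv")
    utils::write.csv(cbind(id = cohort$id, as.data.frame(predictions)),
                     p_pred, row.names = FALSE)
    p_json <- file.path(config$out_dir, "comparison.json")
    report <- list(
      provenance = list(
        package = "ppolung",
        version = as.character(utils::packageVersion("ppolung")),
        seed = config$seed,
        thresholds = list(theta_emph = config$theta_emph,
                          theta_well_max = config$theta_well_max),
        brunelli = list(fev1 = as.list(config$brunelli$fev1),
                        dlco = as.list(config$brunelli$dlco)),
        resection = config$resection, ties = config$ties,
        n_patients = nrow(cohort)),
      resection_simulation = list(
        removed_total_fraction = sim$removed_total_fraction,
        removed_functional_fraction = sim$removed_functional_fraction,
        healthy_over_total = sim$healthy_over_total,
        ipsi_remaining_healthy_over_total = sim$ipsi_remaining_healthy_over_total,
        removed_healthy_over_removed_total = sim$removed_healthy_over_removed_total),
      groups = list(n_increase = nrow(analysis$groups$increase),
                    n_decrease = nrow(analysis$groups$decrease)),
      comparisons = lapply(analysis$comparisons, function(cc)
        list(variable = cc$variable, n = cc$n, mean = cc$mean, sd = cc$sd,
             t = cc$t, df = cc$df, p = cc$p, significant = cc$significant)),
      pre_post_fit = list(slope = analysis$fit$slope,
                          intercept = analysis$fit$intercept))
    jsonlite::write_json(report, p_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    writeLines(log_lines, log_path)
    list(volumetrics = p_vol, predictions = p_pred, comparison = p_json,
         log = log_path)
  })

  invisible(list(volume = inputs$vol, labels = inputs$labels, cohort = cohort,
                 classmap = classmap, volumetrics = volumetrics, plan = plan,
                 resection = sim, predictions = predictions,
                 analysis = analysis, paths = paths))
}
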