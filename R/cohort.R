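#' Split a cohort by postoperative FEV1 response
#'
#' Partitions patients into an "increase" group (postoperative FEV1 strictly
#' greater than preoperative, in liters) and a "decrease" group (everyone
#' else). Ties go to the decrease group by default ("showed an increase" read
#' strictly); set `ties` to `"increase"` to flip that. Patients with a
#' missing postoperative FEV1 are excluded with a warning.
#'
#' @param cohort data.frame with columns `preop_fev1_l` and `postop_fev1_l`
#'   (e.g. from [make_cohort()] or [read_cohort_csv()]).
#' @param ties which group receives exact ties; default `"decrease"`.
#' @return list with data.frames `increase` and `decrease`; together they
#'   partition the non-excluded cohort.
#' @export
split_by_response <- function(cohort, ties = c("decrease", "increase")) {
  ties <- match.arg(ties)
  stopifnot(all(c("preop_fev1_l", "postop_fev1_l") %in% names(cohort)))
  ok <- !is.na(cohort$postop_fev1_l) & !is.na(cohort$preop_fev1_l)
  if (any(!ok)) {
    warning(sum(!ok), " patient(s) excluded: missing pre/postoperative FEV1")
    cohort <- cohort[ok, , drop = FALSE]
  }
  d <- cohort$postop_fev1_l - cohort$preop_fev1_l
  up <- if (ties == "decrease") d > 0 else d >= 0
  list(increase = cohort[up, , drop = FALSE],
       decrease = cohort[!up, , drop = FALSE])
}

#' Mean/SD summary of cohort variables
#'
#' Continuous variables summarised as arithmetic means with sample standard
#' deviations (n - 1 denominator), the convention of clinical baseline
#' tables.
#'
#' @param cohort data.frame of patients.
#' @param variables character vector of numeric column names.
#' @param group label recorded on the output.
#' @return data.frame of class `cohort_summary`: `group`, `variable`, `n`,
#'   `mean`, `sd`. Errors if fewer than 2 patients (SD undefined).
#' @export
summarize_cohort <- function(cohort, variables, group = "all") {
  if (nrow(cohort) < 2)
    stop("SD undefined: need at least 2 patients, got ", nrow(cohort))
  missing <- setdiff(variables, names(cohort))
  if (length(missing))
    stop("unknown variable(s): ", paste(missing, collapse = ", "))
  out <- data.frame(
    group = group,
    variable = variables,
    n = nrow(cohort),
    mean = vapply(variables, function(v) mean(cohort[[v]]), 0),
    sd = vapply(variables, function(v) stats::sd(cohort[[v]]), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Two-group comparison by unpaired Student's t-test
#'
#' Pooled-variance (equal-variance) two-sample t-test with
#' `n1 + n2 - 2` degrees of freedom and a two-sided p-value — the classical
#' unpaired Student test, not Welch. Degenerate inputs are handled
#' explicitly: zero pooled variance with equal means gives t = 0, p = 1;
#' zero pooled variance with unequal means gives an infinite t and p = 0
#' with a warning.
#'
#' @param a,b numeric vectors (each of length >= 2), or data.frames combined
#'   with `variable`.
#' @param variable column name when `a`/`b` are data.frames.
#' @param alpha significance level for the `significant` flag; default 0.05.
#' @return object of class `group_comparison`: `variable`, per-group `n`,
#'   `mean`, `sd`, `t`, `df`, `p`, `significant`.
#' @export
compare_groups <- function(a, b, variable = NULL, alpha = 0.05) {
  if (is.data.frame(a)) {
    stopifnot(!is.null(variable), is.data.frame(b))
    x <- a[[variable]]; y <- b[[variable]]
  } else {
    x <- as.numeric(a); y <- as.numeric(b)
  }
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 observations")
  m1 <- mean(x); m2 <- mean(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (m1 == m2) {
      tstat <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means: t is infinite, p = 0")
      tstat <- sign(m1 - m2) * Inf; p <- 0
    }
  } else {
    tstat <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(
    variable = if (is.null(variable)) NA_character_ else variable,
    n = c(n1, n2), mean = c(m1, m2),
    sd = c(stats::sd(x), stats::sd(y)),
    t = tstat, df = df, p = p, alpha = alpha,
    significant = is.finite(p) && p < alpha
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s\n",
              if (is.na(x$variable)) "" else paste0(" ", x$variable)))
  cat(sprintf("  group 1: n = %d, mean %.3f (SD %.3f)\n", x$n[1], x$mean[1], x$sd[1]))
  cat(sprintf("  group 2: n = %d, mean %.3f (SD %.3f)\n", x$n[2], x$mean[2], x$sd[2]))
  cat(sprintf("  Student t = %.4f, df = %d, two-sided p = %.4g%s\n",
              x$t, x$df, x$p,
              if (isTRUE(x$significant)) sprintf(" (significant at %.2g)", x$alpha) else ""))
  invisible(x)
}

#' Measured-versus-predicted deviation
#'
#' Difference between a measured group mean and a model prediction,
#' `measured - predicted`. For FEV1 report parity, `report = "ml10"` converts
#' liters to milliliters and rounds to the nearest 10 mL (how such deviations
#' are quoted clinically); `"native"` returns the unrounded difference in the
#' input units.
#'
#' @param measured_mean measured group mean.
#' @param predicted_mean model-predicted group mean, same units.
#' @param report `"native"` (default) or `"ml10"` (liters in, rounded mL out).
#' @return numeric difference.
#' @export
model_deviation <- function(measured_mean, predicted_mean,
                            report = c("native", "ml10")) {
  report <- match.arg(report)
  d <- measured_mean - predicted_mean
  if (report == "ml10") round(d * 1000 / 10) * 10 else d
}

#' Best-fit line of postoperative on preoperative values
#'
#' Ordinary least-squares fit of postoperative on preoperative values — the
#' "line of best fit" of a pre/post scatter plot — together with per-patient
#' residuals from the line of no change (identity), `postop - preop`.
#'
#' @param cohort data.frame of patients.
#' @param variable base name; columns `preop_<variable>` and
#'   `postop_<variable>` must exist. Default `"fev1_l"`.
#' @return object of class `pre_post_fit`: `slope`, `intercept`,
#'   `identity_residuals`, the underlying `lm` fit, and the data. Errors for
#'   n < 3 or zero preoperative variance.
#' @export
fit_pre_post_line <- function(cohort, variable = "fev1_l") {
  pre_col <- paste0("preop_", variable); post_col <- paste0("postop_", variable)
  stopifnot(all(c(pre_col, post_col) %in% names(cohort)))
  dat <- data.frame(pre = cohort[[pre_col]], post = cohort[[post_col]])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 3) stop("need at least 3 patients for a best-fit line")
  if (stats::var(dat$pre) == 0) stop("zero preoperative variance: line undefined")
  fit <- stats::lm(post ~ pre, data = dat)
  structure(list(
    variable = variable,
    slope = unname(stats::coef(fit)[["pre"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    identity_residuals = dat$post - dat$pre,
    fit = fit, data = dat
  ), class = "pre_post_fit")
}

#' @export
print.pre_post_fit <- function(x, ...) {
  cat(sprintf("<pre_post_fit> %s: postop = %.4f * preop + %.4f (n = %d)\n",
              x$variable, x$slope, x$intercept, nrow(x$data)))
  cat(sprintf("  mean identity-line residual %.4f (postop - preop)\n",
              mean(x$identity_residuals)))
  invisible(x)
}

#' @export
#' @rdname fit_pre_post_line
#' @param x a `pre_post_fit`.
#' @param ... passed to [graphics::plot()].
plot.pre_post_fit <- function(x, ...) {
  graphics::plot(x$data$pre, x$data$post,
                 xlab = paste("preoperative", x$variable),
                 ylab = paste("postoperative", x$variable), ...)
  graphics::abline(a = 0, b = 1, lty = 2, col = "grey40")   # line of no change
  graphics::abline(x$fit, col = "firebrick")                # best fit
  invisible(x)
}

#' Read/write a patient cohort CSV
#'
#' Plain CSV, one row per patient. Expected columns (the dictionary used by
#' [make_cohort()]): `id`, `age`, `sex`, `bmi`, `segments_removed`,
#' `resected_segments`, `preop_fev1_l`, `preop_fev1_pct`, `preop_fev1_fvc`,
#' `preop_dlco`, `preop_dlco_pct`, `preop_rv_l`, `preop_rv_pct`, and the
#' matching `postop_*` columns; generator ground truth travels in columns
#' prefixed `truth_`.
#'
#' @param path CSV path.
#' @param cohort data.frame of patients.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
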