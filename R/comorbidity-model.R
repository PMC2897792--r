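#' Fit a baseline-plus-comorbidity mortality model
#'
#' The package's central fitting function. It fits a logistic regression of
#' the chosen mortality outcome on the four baseline covariates (age in
#' years, male, aborigine, surgery) and, unless \code{method} is
#' \code{NULL}, the binary comorbidity indicators of one classification
#' method under one ascertainment period. Comorbidity columns with 0% or
#' 100% prevalence are dropped before fitting and recorded. The fit is
#' compared to the nested baseline model via the G-squared statistic, and
#' model discrimination is summarized by the tie-aware c-statistic, with a
#' patient-resampling bootstrap percentile confidence interval when
#' \code{n_bootstrap > 0}.
#'
#' @param cohort a cohort data.frame from [build_cohort()].
#' @param dataset the source [claims_dataset()]; required when a profile
#'   matrix has to be computed.
#' @param outcome \code{"in_hospital"} or \code{"one_year"}.
#' @param method \code{NULL} for the baseline model, or a method name /
#'   [load_method()] object.
#' @param period a [data_period()] or its kind string.
#' @param profile optional precomputed [profile_matrix()] (rows aligned
#'   with \code{cohort}).
#' @param n_bootstrap bootstrap replications for the c-statistic CI
#'   (0 = point estimate only; the conventional choice is 1000).
#' @param seed seed for the bootstrap.
#' @return object of class \code{comorbidity_model}.
#' @examples
#' cfg <- load_scenario("ami", n_patients = 500, seed = 7)
#' sim <- simulate_population(cfg)
#' cohort <- build_cohort(sim$dataset, disease_definition("AMI"))
#' fit <- comorbidity_model(cohort, sim$dataset, outcome = "in_hospital",
#'                          method = "elixhauser", period = "index_only")
#' fit
#' @export
comorbidity_model <- function(cohort, dataset = NULL,
                              outcome = c("in_hospital", "one_year"),
                              method = NULL, period = "index_only",
                              profile = NULL,
                              n_bootstrap = 0L, seed = 1L) {
  outcome <- match.arg(outcome)
  y <- as.numeric(if (outcome == "in_hospital") cohort$died_in_hospital
                  else cohort$died_within_1yr)
  base_design <- cbind(age = cohort$age_years,
                       male = as.numeric(cohort$male),
                       aborigine = as.numeric(cohort$aborigine),
                       surgery = as.numeric(cohort$surgery))
  period <- as_data_period(period)

  dropped <- character(0)
  method_name <- NULL
  if (!is.null(method)) {
    if (is.character(method)) method <- load_method(method)
    method_name <- method$name
    if (is.null(profile)) {
      if (is.null(dataset)) {
        stop("dataset needed to compute the comorbidity profile matrix",
             call. = FALSE)
      }
      profile <- profile_matrix(cohort, dataset, method, period)
    }
    stopifnot(nrow(profile) == nrow(cohort))
    red <- drop_degenerate_columns(profile)
    dropped <- red$dropped
    design <- cbind(base_design, red$design)
  } else {
    design <- base_design
  }

  base_fit <- fit_logistic(base_design, y)
  fit <- if (is.null(method)) base_fit else fit_logistic(design, y)
  g2 <- if (is.null(method)) NULL else g2_statistic(fit, base_fit)

  boot <- NULL
  if (n_bootstrap > 0L) {
    boot <- bootstrap_c_ci(design, y, n_reps = n_bootstrap, seed = seed)
  }
  c_point <- c_statistic(stats::fitted(fit$glm), y)

  structure(list(call = match.call(),
                 outcome = outcome,
                 method = method_name,
                 period = period$kind,
                 fit = fit, base_fit = base_fit,
                 g2 = g2,
                 c_statistic = c_point,
                 ci = if (is.null(boot)) c(NA_real_, NA_real_) else
                   c(boot$ci_low, boot$ci_high),
                 n_bootstrap = as.integer(n_bootstrap),
                 bootstrap = boot,
                 dropped = dropped,
                 design = design, y = y),
            class = "comorbidity_model")
}

#' @export
print.comorbidity_model <- function(x, ...) {
  lab <- if (is.null(x$method)) "baseline" else
    paste0("baseline + ", x$method, " (", x$period, ")")
  cat("<comorbidity_model> ", lab, ", outcome: ", x$outcome, "\n", sep = "")
  cat("  n = ", x$fit$n, ", events = ", sum(x$y), "\n", sep = "")
  if (!is.null(x$g2)) {
    cat(sprintf("  G2 = %.1f on %d df (total df %d), p %s\n",
                x$g2$g2, x$g2$df_diff, x$g2$df_total,
                format.pval(x$g2$p, digits = 3)))
  }
  ci <- if (all(is.na(x$ci))) "" else
    sprintf(" (%.3f-%.3f, %d bootstrap reps)",
            x$ci[1], x$ci[2], x$n_bootstrap)
  cat(sprintf("  c-statistic = %.3f%s\n", x$c_statistic, ci))
  if (length(x$dropped)) {
    cat("  dropped (0%/100% prevalence):",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.comorbidity_model <- function(object, ...) {
  cf <- object$fit$coefficients
  tab <- data.frame(estimate = cf, se = object$fit$se,
                    z = cf / object$fit$se,
                    row.names = names(cf))
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  out <- list(model = object, coefficients = tab)
  class(out) <- "summary.comorbidity_model"
  out
}

#' @export
print.summary.comorbidity_model <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.comorbidity_model <- function(object, ...) object$fit$coefficients

#' @export
residuals.comorbidity_model <- function(object, ...) {
  stats::residuals(object$fit$glm, ...)
}

#' @param object,newdata,type standard \code{predict} arguments;
#'   \code{newdata} is a data.frame/matrix with the model's covariate
#'   columns (omit for fitted values).
#' @rdname comorbidity_model
#' @export
predict.comorbidity_model <- function(object, newdata = NULL,
                                      type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    return(stats::predict(object$fit$glm, type = type))
  }
  stats::predict(object$fit$glm, newdata = as.data.frame(newdata),
                 type = type)
}

#' ROC curve of a fitted comorbidity model
#'
#' Plots the empirical ROC curve of the model's fitted probabilities
#' against the observed outcome, annotated with the c-statistic (= area
#' under the curve).
#'
#' @param x a \code{comorbidity_model}.
#' @param ... passed to \code{plot}.
#' @export
plot.comorbidity_model <- function(x, ...) {
  sc <- stats::fitted(x$fit$glm)
  y <- x$y
  th <- sort(unique(sc), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(sc[y == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(sc[y == 0] >= t), numeric(1))
  plot(c(0, fpr, 1), c(0, tpr, 1), type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC, c = %.3f", x$c_statistic), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
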