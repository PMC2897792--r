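#' Drop comorbidity columns with degenerate prevalence
#'
#' Binary indicator columns whose prevalence in the analytic cohort is
#' exactly 0% or 100% carry no information and make the logistic fit
#' rank-deficient; they are removed before modelling and their names
#' recorded (e.g. in an AMI cohort the myocardial-infarction category is
#' all-1 under a lookback period, and AIDS is typically all-0).
#'
#' @param design numeric matrix or data.frame of 0/1 comorbidity columns.
#' @return list with \code{design} (reduced) and \code{dropped} (character
#'   vector of removed column names).
#' @export
drop_degenerate_columns <- function(design) {
  design <- as.matrix(design)
  if (ncol(design) == 0L) {
    return(list(design = design, dropped = character(0)))
  }
  m <- colMeans(design)
  drop <- m == 0 | m == 1
  list(design = design[, !drop, drop = FALSE],
       dropped = colnames(design)[drop])
}

#' Maximum-likelihood logistic fit
#'
#' Thin wrapper around \code{stats::glm(family = binomial)} adding the
#' bookkeeping the evaluation layer needs: a degenerate-outcome error,
#' the maximized log-likelihood, the count of estimated non-intercept
#' parameters (aliased columns are excluded), and a heuristic complete-
#' separation flag (any fitted probability within 1e-8 of 0 or 1 together
#' with a huge coefficient).
#'
#' @param design numeric matrix/data.frame of covariates (no intercept
#'   column; one is added).
#' @param outcome logical or 0/1 vector.
#' @return object of class \code{logistic_fit}: list with
#'   \code{coefficients}, \code{se}, \code{loglik}, \code{n_parameters},
#'   \code{converged}, \code{separation}, \code{glm} (the underlying fit),
#'   \code{n}.
#' @export
fit_logistic <- function(design, outcome) {
  y <- as.numeric(outcome)
  stopifnot(all(y %in% c(0, 1)))
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate outcome: needs at least one event and one non-event",
         call. = FALSE)
  }
  design <- as.matrix(design)
  if (ncol(design)) stopifnot(nrow(design) == length(y))
  df <- if (ncol(design)) as.data.frame(design) else
    data.frame(row.names = seq_along(y))
  df$.y <- y
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)))
  cf <- stats::coef(fit)
  est <- !is.na(cf)
  se <- sqrt(diag(stats::vcov(fit, complete = TRUE)))  # NA for aliased
  names(se) <- names(cf)
  fitted <- stats::fitted(fit)
  separation <- (any(fitted < 1e-8 | fitted > 1 - 1e-8) &&
                   any(abs(cf[est]) > 15))
  structure(list(coefficients = cf, se = se,
                 loglik = as.numeric(stats::logLik(fit)),
                 n_parameters = sum(est) - 1L,
                 converged = fit$converged,
                 separation = separation,
                 glm = fit, n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n =", x$n, ", parameters (excl. intercept) =",
      x$n_parameters, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 6),
      if (!x$converged) " (NOT converged)" else "", "\n")
  if (x$separation) cat("  warning: complete separation suspected\n")
  invisible(x)
}

#' Nested-model G-squared statistic
#'
#' Twice the difference in maximized log-likelihood between a full model
#' and a nested baseline, chi-squared distributed under the null with
#' degrees of freedom equal to the difference in number of estimated
#' parameters. Both df conventions are returned: \code{df_diff} (the
#' parameter-count difference, used for the p-value) and \code{df_total}
#' (all non-intercept parameters of the full model, the convention some
#' published tables print).
#'
#' @param full,base \code{logistic_fit} objects on the same rows and
#'   outcome, with base's columns a subset of full's.
#' @return list with \code{g2}, \code{df_diff}, \code{df_total}, \code{p}.
#' @export
g2_statistic <- function(full, base) {
  stopifnot(inherits(full, "logistic_fit"), inherits(base, "logistic_fit"))
  if (full$n != base$n) {
    stop("models were fit on different numbers of rows; not nested",
         call. = FALSE)
  }
  base_cols <- setdiff(names(base$coefficients), "(Intercept)")
  full_cols <- setdiff(names(full$coefficients), "(Intercept)")
  if (!all(base_cols %in% full_cols)) {
    stop("baseline covariates are not a subset of the full model's; ",
         "not nested", call. = FALSE)
  }
  g2 <- 2 * (full$loglik - base$loglik)
  if (g2 < -1e-6) {
    stop("negative G2 (", format(g2), "): models are not nested or a fit ",
         "failed to converge", call. = FALSE)
  }
  g2 <- max(g2, 0)
  df_diff <- full$n_parameters - base$n_parameters
  p <- if (df_diff > 0) stats::pchisq(g2, df_diff, lower.tail = FALSE) else 1
  list(g2 = g2, df_diff = df_diff, df_total = full$n_parameters, p = p)
}

#' Concordance (c) statistic
#'
#' The area under the ROC curve: the probability that a randomly chosen
#' event has a higher score than a randomly chosen non-event, ties counted
#' one half. Computed from mid-ranks (the Mann-Whitney identity), so it is
#' exact under ties and invariant to any strictly increasing transform of
#' the scores. Ranges from 0.5 (chance) to 1.0 (perfect prediction) for a
#' useful score.
#'
#' @param scores numeric predictions (higher = more likely event).
#' @param outcomes logical or 0/1 event indicator.
#' @return the concordance probability (scalar).
#' @export
c_statistic <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  n1 <- as.numeric(sum(y)); n0 <- as.numeric(sum(!y))
  if (n1 == 0 || n0 == 0) {
    stop("c-statistic undefined: outcome has a single class", call. = FALSE)
  }
  r <- rank(scores)  # mid-ranks give the tie = 1/2 convention
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

boot_indices <- function(n, outcome, max_redraw = 1000L) {
  redraws <- 0L
  repeat {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(outcome[idx])) > 1L) {
      return(list(idx = idx, redraws = redraws))
    }
    redraws <- redraws + 1L
    if (redraws > max_redraw) {
      stop("could not draw a two-class bootstrap replicate", call. = FALSE)
    }
  }
}

#' Bootstrap percentile CI for the c-statistic
#'
#' Resamples patients with replacement to the original n, refits the
#' logistic model inside every replicate (so model-selection variability is
#' captured), recomputes the c-statistic, and returns the 2.5th and 97.5th
#' percentiles of the replicate distribution. Replicates whose resampled
#' outcome has a single class are redrawn; if redraws exceed 10% of the
#' requested replications a warning is emitted. Fully seeded.
#'
#' @param design covariate matrix (already reduced of degenerate columns).
#' @param outcome 0/1 outcome vector.
#' @param n_reps number of bootstrap replications (the conventional choice
#'   is 1000).
#' @param seed integer seed.
#' @param refit refit the model per replicate (default); if \code{FALSE},
#'   the full-data model scores each replicate.
#' @return list with \code{c} (full-data point estimate), \code{ci_low},
#'   \code{ci_high}, \code{replicates} (numeric vector), \code{redraws}.
#' @export
bootstrap_c_ci <- function(design, outcome, n_reps = 1000L, seed = 1L,
                           refit = TRUE) {
  design <- as.matrix(design)
  y <- as.numeric(outcome)
  full <- fit_logistic(design, y)
  c_point <- c_statistic(stats::fitted(full$glm), y)
  set.seed(seed)
  reps <- numeric(n_reps)
  total_redraws <- 0L
  n <- length(y)
  for (b in seq_len(n_reps)) {
    bi <- boot_indices(n, y)
    total_redraws <- total_redraws + bi$redraws
    idx <- bi$idx
    if (refit) {
      red <- drop_degenerate_columns(design[idx, , drop = FALSE])
      f <- fit_logistic(red$design, y[idx])
      reps[b] <- c_statistic(stats::fitted(f$glm), y[idx])
    } else {
      eta <- cbind(1, design[idx, , drop = FALSE]) %*%
        ifelse(is.na(full$coefficients), 0, full$coefficients)
      reps[b] <- c_statistic(as.numeric(eta), y[idx])
    }
  }
  if (total_redraws > 0.1 * n_reps) {
    warning(total_redraws, " single-class replicates redrawn (> 10% of ",
            n_reps, " replications)", call. = FALSE)
  }
  qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, type = 7)
  list(c = c_point, ci_low = qs[1], ci_high = qs[2],
       replicates = reps, redraws = total_redraws)
}

#' Paired bootstrap comparison of two models' discrimination
#'
#' In every replicate the same resampled patients are used to refit both
#' models and compute both c-statistics, so their difference is evaluated
#' on common resamples. Returns the fraction of replicates where model A's
#' c strictly exceeds model B's, plus the per-replicate difference vector.
#'
#' @param design_a,design_b covariate matrices on the same rows.
#' @param outcome shared 0/1 outcome.
#' @param n_reps,seed as in [bootstrap_c_ci()].
#' @return list with \code{win_frac_a}, \code{ties}, \code{diff}
#'   (c_A - c_B per replicate).
#' @export
paired_bootstrap_compare <- function(design_a, design_b, outcome,
                                     n_reps = 1000L, seed = 1L) {
  design_a <- as.matrix(design_a); design_b <- as.matrix(design_b)
  y <- as.numeric(outcome)
  stopifnot(nrow(design_a) == length(y), nrow(design_b) == length(y))
  set.seed(seed)
  dif <- numeric(n_reps)
  n <- length(y)
  for (b in seq_len(n_reps)) {
    idx <- boot_indices(n, y)$idx
    yb <- y[idx]
    ra <- drop_degenerate_columns(design_a[idx, , drop = FALSE])
    rb <- drop_degenerate_columns(design_b[idx, , drop = FALSE])
    ca <- c_statistic(stats::fitted(fit_logistic(ra$design, yb)$glm), yb)
    cb <- c_statistic(stats::fitted(fit_logistic(rb$design, yb)$glm), yb)
    dif[b] <- ca - cb
  }
  list(win_frac_a = mean(dif > 0), ties = mean(dif == 0), diff = dif)
}
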