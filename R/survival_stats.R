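#' Kaplan-Meier estimate with an explicit "not reached" median
#'
#' Product-limit estimator of the survival function. The median is the
#' smallest time with `S(t) <= 0.5`; when the curve never falls to 0.5
#' the median is *not reached*, encoded as `median = NA` with
#' `median_reached = FALSE` (never as infinity).
#'
#' @param time Nonnegative follow-up times (months).
#' @param event 0/1 event indicators.
#' @return A list with `time` (event times), `surv` (estimate after each
#'   time, a non-increasing right-continuous step function with
#'   `S(0) = 1`), `n_risk`, `n_event`, `median`, `median_reached`.
#' @export
km_estimate <- function(time, event) {
  stop_if_not(length(time) >= 1L, "need at least one sample")
  stop_if_not(all(time >= 0), "negative follow-up time")
  stop_if_not(all(event %in% c(0, 1)), "event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  surv <- fit$surv
  med_idx <- which(surv <= 0.5)
  reached <- length(med_idx) > 0L
  list(time = fit$time, surv = surv, n_risk = fit$n.risk,
       n_event = fit$n.event,
       median = if (reached) fit$time[min(med_idx)] else NA_real_,
       median_reached = reached)
}

#' Log-rank test across two or more groups
#'
#' Standard observed-minus-expected chi-square comparison of survival
#' curves, with `df = n_groups - 1`.
#'
#' @inheritParams km_estimate
#' @param group Group labels (>= 2 distinct values, >= 1 event overall).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  stop_if_not(nlevels(droplevels(group)) >= 2L, "need at least two groups")
  stop_if_not(sum(event) >= 1, "need at least one event")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  list(statistic = fit$chisq, df = df,
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling and Wald
#' confidence intervals, via `survival::coxph`. Errors on non-convergence
#' and on (numerically detected) complete separation rather than
#' returning runaway estimates.
#'
#' @inheritParams km_estimate
#' @param covariates Data frame of numeric covariates (no constant
#'   column).
#' @param conf_level Wald CI level.
#' @return A `cox_result` data frame: per variable `beta`, `hr`,
#'   `ci_low`, `ci_high`, `p_wald`; attribute `loglik` holds the model
#'   log partial likelihood.
#' @export
cox_fit <- function(time, event, covariates, conf_level = 0.95) {
  stop_if_not(sum(event) >= 1, "need at least one event")
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(x) length(unique(x)) < 2L, TRUE)
  stop_if_not(!any(const), "constant covariate(s): ",
              paste(names(covariates)[const], collapse = ", "))
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, event) ~ .,
                    data = cbind(time = time, event = event, covariates),
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        stop("Cox fit did not converge (possible complete separation): ",
             conditionMessage(w), call. = FALSE)
      }
      suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ .,
                        data = cbind(time = time, event = event, covariates),
                        ties = "efron"))
    })
  s <- summary(fit, conf.int = conf_level)
  out <- data.frame(variable = names(stats::coef(fit)),
                    beta = unname(stats::coef(fit)),
                    hr = unname(exp(stats::coef(fit))),
                    ci_low = unname(s$conf.int[, 3L]),
                    ci_high = unname(s$conf.int[, 4L]),
                    p_wald = unname(s$coefficients[, "Pr(>|z|)"]),
                    stringsAsFactors = FALSE)
  attr(out, "loglik") <- fit$loglik[2L]
  class(out) <- c("cox_result", "data.frame")
  out
}

#' Maximally selected rank-statistic cutpoint
#'
#' Finds the covariate threshold that best separates survival: for every
#' candidate cutpoint (midpoints between consecutive distinct covariate
#' values whose split fraction lies inside `quantile_window`), the
#' standardized two-group log-rank statistic is computed from the
#' log-rank (martingale-residual) scores; the cutoff is the maximizer.
#' Significance of the maximal statistic is assessed by permuting the
#' covariate against the survival outcome, which accounts for the
#' cutpoint search.
#'
#' @inheritParams km_estimate
#' @param x Numeric covariate (>= 3 distinct values inside the window).
#' @param quantile_window Candidate cutpoints are restricted to splits
#'   leaving at least this fraction of samples on each side.
#' @param n_perm Permutations for the p-value.
#' @param seed RNG seed.
#' @return List with `cutoff`, `statistic` (standardized, maximal),
#'   `p_value`, and the per-candidate table `candidates`.
#' @export
maxstat_cutoff <- function(time, event, x,
                           quantile_window = c(0.10, 0.90),
                           n_perm = 1000, seed = 1) {
  stop_if_not(length(unique(x)) >= 2L, "constant covariate")
  a <- logrank_scores(time, event)
  n <- length(a)
  lo <- stats::quantile(x, quantile_window[1L], names = FALSE)
  hi <- stats::quantile(x, quantile_window[2L], names = FALSE)
  vals <- sort(unique(x))
  vals <- vals[vals >= lo & vals <= hi]
  stop_if_not(length(vals) >= 3L,
              "need at least 3 distinct covariate values inside the window")
  cuts <- (vals[-length(vals)] + vals[-1L]) / 2
  stat_for <- function(xv) {
    ord <- order(xv)
    ca <- cumsum(a[ord] - mean(a))
    m <- seq_len(n)
    v <- m * (n - m) / (n * (n - 1)) * sum((a - mean(a))^2)
    # statistic at a cut after position m in sorted order
    s <- abs(ca) / sqrt(pmax(v, .Machine$double.eps))
    list(sorted_x = xv[ord], s = s)
  }
  obs <- stat_for(x)
  cand_stat <- vapply(cuts, function(cc) {
    m <- sum(obs$sorted_x <= cc)
    obs$s[m]
  }, 0)
  best <- which.max(cand_stat)
  max_obs <- cand_stat[best]
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      xp <- x[sample.int(n)]
      sp <- stat_for(xp)
      max(vapply(cuts, function(cc) {
        m <- sum(sp$sorted_x <= cc)
        sp$s[m]
      }, 0))
    }, 0)
  })
  p <- (1 + sum(null_max >= max_obs)) / (1 + n_perm)
  list(cutoff = cuts[best], statistic = max_obs, p_value = p,
       candidates = data.frame(cutoff = cuts, statistic = cand_stat))
}

# Log-rank scores a_i = event_i - Nelson-Aalen cumulative hazard at t_i.
logrank_scores <- function(time, event) {
  stop_if_not(all(time >= 0), "negative follow-up time")
  ut <- sort(unique(time[event == 1]))
  d <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  r <- vapply(ut, function(t) sum(time >= t), 0)
  haz <- cumsum(d / r)
  cumhaz_at <- function(t) {
    i <- findInterval(t, ut)
    ifelse(i == 0, 0, haz[pmax(i, 1)])
  }
  event - cumhaz_at(time)
}

#' Lasso-penalized Cox regression
#'
#' L1-penalized partial-likelihood fit over a log-spaced lambda path via
#' `glmnet`, with lambda chosen by cross-validated partial deviance
#' (`lambda = "cv"`, the default) or supplied as a number. The CV rule
#' defaults to `"1se"` (largest lambda within one standard error of the
#' minimum-deviance lambda), the sparse choice that makes the >90%
#' stability-retention rule discriminate signal from noise; `"min"`
#' (minimum deviance) is available as the alternative. CV folds are
#' stratified on the event indicator so every fold contains events; if
#' that is impossible the fit errors.
#'
#' @inheritParams km_estimate
#' @param covariates Numeric covariate data frame (>= 2 columns; >= 10
#'   events recommended).
#' @param lambda `"cv"` or a nonnegative penalty value.
#' @param n_folds CV folds (when `lambda = "cv"`).
#' @param seed RNG seed for fold assignment.
#' @param nlambda Length of the lambda path.
#' @param cv_rule `"1se"` (default) or `"min"`.
#' @return List with `lambda`, `coef` (named vector, all candidates) and
#'   `selected` (names with nonzero coefficients).
#' @export
lasso_cox <- function(time, event, covariates, lambda = "cv",
                      n_folds = 10, seed = 1, nlambda = 50,
                      cv_rule = c("1se", "min")) {
  cv_rule <- match.arg(cv_rule)
  x <- as.matrix(covariates)
  stop_if_not(ncol(x) >= 2L, "need at least two candidate variables")
  y <- survival::Surv(time, event)
  if (identical(lambda, "cv")) {
    foldid <- stratified_folds(event, n_folds, seed)
    cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                            nlambda = nlambda)
    lam <- if (cv_rule == "1se") cv$lambda.1se else cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    stop_if_not(is.numeric(lambda) && lambda >= 0, "invalid lambda")
    # explicit warm-started path ending at the requested lambda, so the
    # extracted coefficients are at an exact path point
    lam_path <- sort(unique(c(max(lambda, 1e-4) * 2^(7:1), lambda)),
                     decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "cox", lambda = lam_path,
                          thresh = 1e-10)
    lam <- lambda
  }
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = lam))
  names(cf) <- colnames(x)
  list(lambda = lam, coef = cf, selected = names(cf)[cf != 0])
}

# Event-stratified fold assignment: events and censored observations are
# each spread round-robin (in shuffled order) so every fold holds events.
stratified_folds <- function(event, n_folds, seed) {
  stop_if_not(sum(event == 1) >= n_folds,
              "cannot build ", n_folds, " folds that each contain an event")
  foldid <- integer(length(event))
  with_seed(seed, {
    for (lev in unique(event)) {
      idx <- sample(which(event == lev))
      foldid[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  foldid
}

#' Bootstrap stability selection around lasso-Cox
#'
#' The resampling protocol used to guard a multivariable Cox model
#' against optimism and overfitting: draw `n_bootstrap` resamples with
#' replacement (size n), fit [lasso_cox()] on each with a fresh
#' cross-validated lambda (child seeds derived deterministically from
#' `seed`), and keep only variables selected in more than
#' `retain_threshold` of the resamples (defaults: 500 bootstraps,
#' retention > 90%). For each retained variable the hazard ratio is
#' summarized over the bootstrap fits in which it was selected: the mean
#' of `exp(coef)` and a (5th, 95th) percentile interval.
#'
#' Candidate variables are expected to be pre-filtered to univariate
#' p < 0.10 (see [cox_fit()]); the function does not re-filter. An empty
#' retained set is a valid result, not an error.
#'
#' @inheritParams lasso_cox
#' @param n_bootstrap Number of bootstrap resamples.
#' @param retain_threshold Strict selection-frequency threshold.
#' @param hr_quantiles Percentiles for the HR interval.
#' @return A `stability_result` data frame: per variable
#'   `selection_frequency`, `retained`, and for retained variables
#'   `hr_mean`, `hr_ci_low`, `hr_ci_high`; attributes `n_bootstrap`,
#'   `retain_threshold`, `hr_mode = "selected_bootstraps"`.
#' @export
stability_selection <- function(time, event, covariates, n_bootstrap = 500,
                                retain_threshold = 0.90, seed = 1,
                                n_folds = 10, nlambda = 50,
                                cv_rule = c("1se", "min"),
                                hr_quantiles = c(0.05, 0.95)) {
  cv_rule <- match.arg(cv_rule)
  x <- as.data.frame(covariates)
  n <- length(time)
  vars <- names(x)
  coefs <- matrix(NA_real_, nrow = n_bootstrap, ncol = length(vars),
                  dimnames = list(NULL, vars))
  for (b in seq_len(n_bootstrap)) {
    bs <- derive_seed(seed, b)
    idx <- with_seed(bs, sample.int(n, n, replace = TRUE))
    # a usable resample needs events and non-constant covariates
    keep_cols <- vapply(x[idx, , drop = FALSE],
                        function(v) length(unique(v)) > 1L, TRUE)
    if (sum(event[idx]) < n_folds || sum(keep_cols) < 2L) {
      coefs[b, ] <- 0
      next
    }
    fit <- lasso_cox(time[idx], event[idx],
                     x[idx, keep_cols, drop = FALSE],
                     lambda = "cv", n_folds = n_folds,
                     seed = derive_seed(bs, 1), nlambda = nlambda,
                     cv_rule = cv_rule)
    coefs[b, ] <- 0
    coefs[b, names(fit$coef)] <- fit$coef
  }
  freq <- colMeans(coefs != 0)
  retained <- freq > retain_threshold
  out <- data.frame(variable = vars, selection_frequency = unname(freq),
                    retained = unname(retained),
                    hr_mean = NA_real_, hr_ci_low = NA_real_,
                    hr_ci_high = NA_real_, stringsAsFactors = FALSE)
  for (v in vars[retained]) {
    hrs <- exp(coefs[coefs[, v] != 0, v])
    out[out$variable == v, c("hr_mean", "hr_ci_low", "hr_ci_high")] <-
      c(mean(hrs), stats::quantile(hrs, hr_quantiles[1L], names = FALSE),
        stats::quantile(hrs, hr_quantiles[2L], names = FALSE))
  }
  attr(out, "n_bootstrap") <- n_bootstrap
  attr(out, "retain_threshold") <- retain_threshold
  attr(out, "hr_mode") <- "selected_bootstraps"
  class(out) <- c("stability_result", "data.frame")
  out
}
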