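# Downstream survival statistics.  Cox model estimation is delegated to
# survival::coxph (Efron ties); this module owns the counting-process
# expansion, screening rules, generalized-propensity weighting, chained
# imputation and the reporting contracts.

#' Counting-process expansion for absorbing time-varying device covariates
#'
#' Splits each patient's follow-up into (start, stop] episodes at the
#' implant times given in `device_cols`, so the device indicator switches 0
#' to 1 at implantation and stays on (devices are not explanted).  Total
#' follow-up per patient is conserved exactly.
#'
#' @param cohort cohort data.frame with `follow_up_years`, `event`.
#' @param device_cols named character vector: new indicator name ->
#'   implant-time column, e.g. `c(icd = "icd_time_years")`.
#' @return data.frame in counting-process format with `start`, `stop`,
#'   `event` and the device indicator columns, plus all other covariates.
#' @export
expand_episodes <- function(cohort, device_cols) {
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fu <- cohort$follow_up_years[i]
    cuts <- numeric(0)
    for (dc in device_cols) {
      tv <- cohort[[dc]][i]
      if (!is.na(tv) && tv > 0 && tv < fu) cuts <- c(cuts, tv)
    }
    bounds <- sort(unique(c(0, cuts, fu)))
    ep <- data.frame(start = bounds[-length(bounds)], stop = bounds[-1])
    ep$event <- c(rep(0L, nrow(ep) - 1L), cohort$event[i])
    for (nm in names(device_cols)) {
      tv <- cohort[[device_cols[[nm]]]][i]
      ep[[nm]] <- if (is.na(tv)) 0L else as.integer(ep$start >= tv - 1e-12)
    }
    keep <- setdiff(names(cohort), c("follow_up_years", "event",
                                     unname(device_cols)))
    ep <- cbind(ep, cohort[i, keep, drop = FALSE], row.names = NULL)
    rows[[i]] <- ep
  }
  do.call(rbind, rows)
}

cap_separation <- function(coef, se, cap = 15) {
  bad <- is.finite(coef) & abs(coef) > cap
  if (any(bad)) {
    warning("monotone likelihood suspected: coefficient capped for ",
            paste(names(coef)[bad], collapse = ", "))
    coef[bad] <- sign(coef[bad]) * cap
  }
  coef
}

survival_fit_from_coxph <- function(fit, n, n_events) {
  sm <- summary(fit)
  coef <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # robust SE when present (weighted fits)
  if (!is.null(fit$naive.var)) se <- sqrt(diag(fit$var))
  names(se) <- names(coef)
  constant <- is.na(coef)
  coef[constant] <- 0
  se[constant] <- Inf
  coef <- cap_separation(coef, se)
  z <- coef / se
  tab <- data.frame(
    covariate = names(coef),
    coef = unname(coef), se = unname(se),
    hr = exp(unname(coef)),
    ci_lower = exp(unname(coef) - 1.96 * unname(se)),
    ci_upper = exp(unname(coef) + 1.96 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(z))),
    row.names = NULL)
  structure(list(table = tab, loglik = fit$loglik[length(fit$loglik)],
                 ties = "efron", n = n, n_events = n_events),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Cox fit (Efron ties), n=%d, events=%d\n", x$n, x$n_events))
  tab <- x$table
  tab$hr <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$ci_lower, tab$ci_upper)
  print(tab[, c("covariate", "hr", "p")], row.names = FALSE)
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximum partial likelihood (Efron tie correction) for baseline
#' covariates, optionally with absorbing time-varying device covariates
#' expanded to counting-process episodes via [expand_episodes()].  Wald 95\%
#' CIs on the log-HR scale.  Complete separation is flagged and the
#' coefficient capped; a constant covariate reports HR = 1 with infinite
#' standard error.
#'
#' @param cohort cohort data.frame (`follow_up_years`, `event`, covariates).
#' @param covariates character vector of covariate columns.
#' @param time_varying optional named character vector mapping indicator
#'   names to implant-time columns, e.g. `c(icd = "icd_time_years")`.
#' @param weights optional case weights (positive); robust variance is then
#'   used.
#' @return a `survival_fit`.
#' @export
cox_fit <- function(cohort, covariates, time_varying = NULL, weights = NULL) {
  cohort <- validate_cohort(cohort)
  if (sum(cohort$event) < 1) stop("need at least one event")
  if (!is.null(weights) && any(weights <= 0)) stop("weights must be positive")
  n <- nrow(cohort); n_events <- sum(cohort$event)
  if (is.null(time_varying)) {
    dat <- cohort
    fml <- stats::as.formula(paste("survival::Surv(follow_up_years, event) ~",
                                   paste(covariates, collapse = " + ")))
  } else {
    dat <- expand_episodes(cohort, time_varying)
    fml <- stats::as.formula(paste("survival::Surv(start, stop, event) ~",
                                   paste(c(covariates, names(time_varying)),
                                         collapse = " + ")))
  }
  dat$.w <- if (is.null(weights)) rep(1, nrow(dat)) else {
    if (!is.null(time_varying)) stop("weights with time-varying covariates not supported")
    weights
  }
  fit <- suppressWarnings(
    survival::coxph(fml, data = dat, ties = "efron", weights = .w,
                    robust = !is.null(weights)))
  survival_fit_from_coxph(fit, n, n_events)
}

#' Univariate screen for propensity-model covariates
#'
#' Keeps candidate variables that (i) have no missing data and (ii) reach
#' univariate Cox p < `p_threshold`; `force` variables (age and sex by
#' default) are always included regardless.  This is the standard input
#' filter for building the exposure propensity model.
#'
#' @param cohort cohort data.frame.
#' @param candidate_vars candidate covariate columns.
#' @param p_threshold screening threshold in (0, 1) (default 0.25).
#' @param force always-included columns.
#' @return character vector of selected columns.
#' @export
univariate_screen <- function(cohort, candidate_vars, p_threshold = 0.25,
                              force = c("age", "male")) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0,1)")
  cohort <- validate_cohort(cohort)
  selected <- character(0)
  for (v in setdiff(candidate_vars, force)) {
    if (any(is.na(cohort[[v]]))) next
    if (stats::sd(as.numeric(cohort[[v]])) == 0) next
    p <- cox_fit(cohort, v)$table$p[1]
    if (!is.na(p) && p < p_threshold) selected <- c(selected, v)
  }
  unique(c(intersect(force, names(cohort)), selected))
}

#' Generalized propensity score and stabilized IPW weights for a
#' continuous exposure
#'
#' Non-parametric regression of the exposure on the covariates (spline-based
#' generalized additive model) with a Gaussian residual density gives the
#' conditional density `f(e | X)`; the stabilized weight is
#' `w_i = f_marginal(e_i) / f(e_i | X_i)` with a Gaussian marginal.  Weights
#' are truncated at the 1st/99th percentiles.  The balance table reports
#' unweighted and weighted Pearson correlations between exposure and each
#' covariate; weighting should shrink them towards zero.
#'
#' @param exposure continuous exposure (e.g. normalized LVAS).
#' @param covariates complete data.frame of screened covariates.
#' @param truncate_quantiles weight truncation probabilities.
#' @return object of class `propensity_result`: `weights`, `gps`
#'   (conditional density values), `fitted` (conditional mean),
#'   `covariates`, `balance` table.
#' @export
propensity_continuous <- function(exposure, covariates,
                                  truncate_quantiles = c(0.01, 0.99)) {
  e <- as.numeric(exposure)
  cv <- as.data.frame(covariates)
  if (anyNA(cv)) stop("covariates must be complete (screen first)")
  if (nrow(cv) != length(e)) stop("dimension mismatch")
  terms <- vapply(names(cv), function(nm) {
    x <- cv[[nm]]
    nu <- length(unique(x))
    if (is.numeric(x) && nu >= 8) {
      sprintf("s(%s, k = 5)", nm)
    } else nm
  }, character(1))
  dat <- cbind(data.frame(.e = e), cv)
  fit <- mgcv::gam(stats::as.formula(paste(".e ~", paste(terms, collapse = " + "))),
                   data = dat)
  mu <- as.numeric(stats::fitted(fit))
  sigma <- stats::sd(e - mu)
  if (!is.finite(sigma) || sigma < 1e-8 * stats::sd(e)) {
    stop("residual variance ~ 0: exposure fully determined by covariates")
  }
  f_cond <- stats::dnorm(e, mu, sigma)
  f_marg <- stats::dnorm(e, mean(e), stats::sd(e))
  w <- f_marg / f_cond
  qb <- stats::quantile(w, truncate_quantiles)
  w <- pmin(pmax(w, qb[1]), qb[2])
  wcor <- function(x, y, w) {
    w <- w / sum(w)
    mx <- sum(w * x); my <- sum(w * y)
    sum(w * (x - mx) * (y - my)) /
      sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  }
  balance <- data.frame(
    covariate = names(cv),
    r_unweighted = vapply(cv, function(x) stats::cor(e, as.numeric(x)),
                          numeric(1)),
    r_weighted = vapply(cv, function(x) wcor(e, as.numeric(x), w),
                        numeric(1)),
    row.names = NULL)
  structure(list(weights = as.numeric(w), gps = f_cond, fitted = mu,
                 sigma = sigma, covariates = names(cv), balance = balance,
                 truncate_quantiles = truncate_quantiles),
            class = "propensity_result")
}

#' @export
print.propensity_result <- function(x, ...) {
  cat(sprintf("generalized propensity: %d covariates, weights in [%.2f, %.2f]\n",
              length(x$covariates), min(x$weights), max(x$weights)))
  print(x$balance, row.names = FALSE)
  invisible(x)
}

#' Confounding-adjusted association of a score with the endpoint
#'
#' Two complementary adjustments of the score-outcome Cox association:
#' (a) inverse-probability weighting with the stabilized generalized
#' propensity weights (robust variance), and (b) a sensitivity fit entering
#' the propensity score (conditional density value) as a covariate.
#'
#' @param cohort cohort data.frame.
#' @param score_col column holding the (quartile-coded or continuous) score.
#' @param propensity a `propensity_result`, or NULL to supply `weights`.
#' @param weights explicit weights (used when `propensity` is NULL).
#' @return list with `survival_fit`s `ipw` and `covariate_adjusted` (the
#'   latter NULL when no propensity object is given).
#' @export
adjusted_association <- function(cohort, score_col, propensity = NULL,
                                 weights = NULL) {
  if (is.null(weights)) {
    if (is.null(propensity)) stop("supply a propensity result or weights")
    weights <- propensity$weights
  }
  ipw <- cox_fit(cohort, score_col, weights = weights)
  cov_adj <- NULL
  if (!is.null(propensity)) {
    dat <- cohort
    dat$.gps <- propensity$gps
    cov_adj <- cox_fit(dat, c(score_col, ".gps"))
  }
  list(ipw = ipw, covariate_adjusted = cov_adj)
}

# one chained-equations sweep over the incomplete columns
impute_once <- function(df, miss_cols, miss_idx, predictors, n_cycles, pmm_k = 5L) {
  work <- df
  # initial fill: random draws from the observed values
  for (cl in miss_cols) {
    obs <- df[[cl]][!is.na(df[[cl]])]
    work[[cl]][miss_idx[[cl]]] <- sample(obs, length(miss_idx[[cl]]),
                                         replace = TRUE)
  }
  for (cycle in seq_len(n_cycles)) {
    for (cl in miss_cols) {
      rhs <- setdiff(predictors, cl)
      fml <- stats::as.formula(paste(cl, "~", paste(rhs, collapse = " + ")))
      obs_rows <- setdiff(seq_len(nrow(df)), miss_idx[[cl]])
      binary <- all(df[[cl]][obs_rows] %in% c(0, 1))
      if (binary) {
        fit <- suppressWarnings(stats::glm(fml, data = work[obs_rows, ],
                                           family = stats::binomial()))
        p <- stats::predict(fit, newdata = work[miss_idx[[cl]], ],
                            type = "response")
        work[[cl]][miss_idx[[cl]]] <- stats::rbinom(length(p), 1, p)
      } else {
        fit <- stats::lm(fml, data = work[obs_rows, ])
        pred_obs <- stats::predict(fit, newdata = work[obs_rows, ])
        pred_mis <- stats::predict(fit, newdata = work[miss_idx[[cl]], ])
        # predictive mean matching: draw among the pmm_k nearest donors
        for (q in seq_along(pred_mis)) {
          d <- abs(pred_obs - pred_mis[q])
          donors <- obs_rows[order(d)[seq_len(min(pmm_k, length(d)))]]
          work[[cl]][miss_idx[[cl]][q]] <- df[[cl]][sample(donors, 1L)]
        }
      }
    }
  }
  work
}

#' Multiple imputation by chained equations with pooled Cox estimates
#'
#' Chained-equation imputation of the incomplete covariate columns
#' (predictive mean matching for continuous, logistic draws for binary),
#' `n_cycles` sweeps per imputation, `m` imputations.  The outcome (event
#' indicator and log follow-up) is included among the predictors, as is
#' standard for survival imputation.  When `cox_covariates` is given, a Cox
#' model is fitted on every completed cohort and pooled by Rubin's rules
#' (point estimate = mean; total variance = within + (1 + 1/m) between;
#' Barnard-Rubin degrees of freedom).
#'
#' @param cohort cohort data.frame; missingness only in covariate columns.
#' @param m number of imputations (>= 2).
#' @param n_cycles chained-equation sweeps per imputation.
#' @param seed integer seed.
#' @param cox_covariates optional covariates for the pooled Cox fit.
#' @return list with `imputations` (m completed data.frames) and `pooled`
#'   (data.frame of pooled Cox estimates, or NULL).
#' @export
mice_impute <- function(cohort, m = 10L, n_cycles = 10L, seed = 1L,
                        cox_covariates = NULL) {
  if (m < 2) stop("m must be at least 2")
  cohort <- validate_cohort(cohort)
  num_cols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  miss_cols <- num_cols[vapply(num_cols, function(cl) anyNA(cohort[[cl]]),
                               logical(1))]
  for (cl in miss_cols) {
    if (all(is.na(cohort[[cl]]))) stop("column fully missing: ", cl)
  }
  bad <- setdiff(names(cohort)[vapply(cohort, anyNA, logical(1))], miss_cols)
  if (length(bad)) stop("missingness outside numeric covariate columns: ",
                        paste(bad, collapse = ", "))
  miss_idx <- lapply(miss_cols, function(cl) which(is.na(cohort[[cl]])))
  names(miss_idx) <- miss_cols
  work <- cohort
  work$.logfu <- log(cohort$follow_up_years)
  predictors <- c(setdiff(num_cols, c("follow_up_years")), ".logfu")
  set.seed(seed)
  imps <- lapply(seq_len(m), function(i) {
    if (length(miss_cols) == 0) return(cohort)
    out <- impute_once(work, miss_cols, miss_idx, predictors, n_cycles)
    out$.logfu <- NULL
    out
  })
  pooled <- NULL
  if (!is.null(cox_covariates)) {
    fits <- lapply(imps, function(d) cox_fit(d, cox_covariates))
    coefs <- sapply(fits, function(f) f$table$coef)
    ses <- sapply(fits, function(f) f$table$se)
    if (is.null(dim(coefs))) { coefs <- matrix(coefs, nrow = 1); ses <- matrix(ses, nrow = 1) }
    qbar <- rowMeans(coefs)
    wvar <- rowMeans(ses^2)
    bvar <- apply(coefs, 1, stats::var)
    tvar <- wvar + (1 + 1 / m) * bvar
    df_br <- ifelse(bvar > 0,
                    (m - 1) * (1 + wvar / ((1 + 1 / m) * bvar))^2, Inf)
    se <- sqrt(tvar)
    pooled <- data.frame(
      covariate = fits[[1]]$table$covariate,
      coef = qbar, se = se, hr = exp(qbar),
      ci_lower = exp(qbar - 1.96 * se), ci_upper = exp(qbar + 1.96 * se),
      p = 2 * stats::pt(-abs(qbar / se), df = df_br),
      within_var = wvar, between_var = bvar, row.names = NULL)
  }
  list(imputations = imps, pooled = pooled)
}

#' Group comparison table
#'
#' Mann-Whitney (Wilcoxon rank-sum, normal approximation with tie
#' correction) for continuous variables and chi-squared tests for
#' categorical variables (Yates continuity correction on 2x2 tables), using
#' all available data per variable.
#'
#' @param cohort cohort data.frame.
#' @param group_col binary grouping column (e.g. `event`).
#' @param variables columns to compare (default: all numeric except the
#'   group and bookkeeping columns).
#' @return data.frame: variable, type, statistic, p, n.
#' @export
group_compare <- function(cohort, group_col, variables = NULL) {
  g <- cohort[[group_col]]
  lev <- sort(unique(g[!is.na(g)]))
  if (length(lev) != 2) stop("grouping column must have exactly two levels")
  if (min(table(g)) == 0) stop("empty group")
  if (is.null(variables)) {
    variables <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                         c(group_col, "follow_up_years", "event",
                           "icd_time_years", "crt_time_years"))
  }
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    ok <- !is.na(x) & !is.na(g)
    categorical <- length(unique(x[ok])) <= 2 || !is.numeric(x)
    if (categorical) {
      tab <- table(factor(g[ok]), factor(x[ok]))
      ht <- suppressWarnings(stats::chisq.test(tab))
      data.frame(variable = v, type = "categorical",
                 statistic = unname(ht$statistic), p = ht$p.value,
                 n = sum(ok))
    } else {
      ht <- stats::wilcox.test(x[ok][g[ok] == lev[2]],
                               x[ok][g[ok] == lev[1]],
                               exact = FALSE, correct = TRUE)
      data.frame(variable = v, type = "continuous",
                 statistic = unname(ht$statistic), p = ht$p.value,
                 n = sum(ok))
    }
  })
  do.call(rbind, rows)
}
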