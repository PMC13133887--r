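#' IDF metabolic-syndrome label
#'
#' Applies the International Diabetes Federation definition: central-obesity
#' gate (waist circumference at or above the ethnicity-specific sex cutoff,
#' OR BMI > 30 kg/m^2) combined with at least two of four criteria:
#' raised fasting glucose (>= 5.6 mmol/L) or diagnosed diabetes; raised blood
#' pressure (SBP >= 130 or DBP >= 80 mmHg) or antihypertensive treatment;
#' raised triglycerides (>= 1.7 mmol/L) or specific treatment; reduced HDL-C
#' (< 1.03 mmol/L men, < 1.29 mmol/L women) or specific treatment.
#'
#' @param record One-row data.frame or named list with fields `sex`
#'   ("male"/"female"), `waist_cm`, `bmi`, `triglyceride`, `hdl_c`, and
#'   optionally `fasting_glucose`, `sbp`, `dbp` and the treatment/history
#'   flags `diabetes`, `hypertension`, `tg_treatment`, `hdl_treatment`.
#' @param waist_cutoffs Named numeric: waist cutoffs in cm per sex
#'   (defaults `c(male = 90, female = 80)`).
#' @return 0/1 label.
#' @export
label_mets <- function(record, waist_cutoffs = c(male = 90, female = 80)) {
  r <- as.list(record)
  need <- c("sex", "waist_cm", "bmi", "triglyceride", "hdl_c")
  miss <- need[!vapply(need, function(f) !is.null(r[[f]]) && !is.na(r[[f]]),
                       logical(1))]
  if (length(miss)) stop("missing fields for MetS labelling: ",
                         paste(miss, collapse = ", "))
  if (!r$sex %in% c("male", "female")) stop("sex must be 'male' or 'female'")
  gate <- r$waist_cm >= waist_cutoffs[[r$sex]] || r$bmi > 30

  flag <- function(f) !is.null(r[[f]]) && !is.na(r[[f]]) && r[[f]] == 1
  num <- function(f) if (!is.null(r[[f]]) && !is.na(r[[f]])) r[[f]] else NA_real_
  crit <- c(
    glucose = isTRUE(num("fasting_glucose") >= 5.6) || flag("diabetes"),
    bp = isTRUE(num("sbp") >= 130) || isTRUE(num("dbp") >= 80) ||
      flag("hypertension"),
    tg = r$triglyceride >= 1.7 || flag("tg_treatment"),
    hdl = r$hdl_c < (if (r$sex == "male") 1.03 else 1.29) || flag("hdl_treatment")
  )
  as.integer(gate && sum(crit) >= 2)
}

#' Stratified train/test split
#'
#' Randomly partitions a cohort into training and test sets. Within each
#' stratum the training count is `round(train_fraction * stratum size)`
#' (round to nearest), so a 184-subject cohort with outcome strata of 93 and
#' 91 at 0.7 yields 129 training and 55 test subjects. Deterministic for a
#' fixed seed.
#'
#' @param table Data.frame of subjects.
#' @param train_fraction In (0, 1); default 0.7.
#' @param seed Integer RNG seed.
#' @param stratify_by Optional column name to stratify on (e.g. the outcome);
#'   `NULL` for a single stratum.
#' @return List with data.frames `train` and `test`.
#' @export
split_cohort <- function(table, train_fraction = 0.7, seed = 1,
                         stratify_by = "mets_label") {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(as.integer(seed))
  strata <- if (is.null(stratify_by)) rep(1L, nrow(table))
            else table[[stratify_by]]
  if (is.null(strata)) stop("stratification column not found: ", stratify_by)
  train_idx <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    k <- round(train_fraction * length(idx))
    if (k < 1 || k >= length(idx) + 1)
      k <- max(1L, min(length(idx), k))
    if (length(idx) < 2)
      stop("stratum too small for a nonempty split: ", s)
    train_idx <- c(train_idx, sample(idx, k))
  }
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE])
}

is_binary_col <- function(x) all(stats::na.omit(x) %in% c(0, 1))

#' Univariate logistic screen
#'
#' Fits one single-predictor logistic regression per candidate variable.
#' Continuous variables are z-scored using training means/SDs before fitting,
#' so their odds ratios are per standard deviation; binary variables enter
#' as-is. A variable is retained iff its Wald p-value is below `alpha`.
#' Constant predictors are flagged, not fitted.
#'
#' @param train Training data.frame.
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of candidate columns (default: all
#'   numeric columns except the outcome).
#' @param alpha Screening significance level (default 0.1).
#' @return Data.frame (class `candidate_set`) with columns `variable`, `or`,
#'   `ci_lo`, `ci_hi`, `p`, `retained`, `constant`, plus attributes `alpha`
#'   and `standardization` (per-variable mean/sd used, NA for binary).
#' @export
univariate_screen <- function(train, outcome, predictors = NULL, alpha = 0.1) {
  y <- train[[outcome]]
  if (is.null(y) || !is_binary_col(y) || length(unique(y)) < 2)
    stop("outcome must be a binary column with both classes present")
  if (is.null(predictors))
    predictors <- setdiff(names(train)[vapply(train, is.numeric, logical(1))],
                          outcome)
  rows <- list(); std <- list()
  for (v in predictors) {
    x <- train[[v]]
    ok <- stats::complete.cases(x, y)
    xi <- x[ok]; yi <- y[ok]
    if (length(unique(xi)) < 2) {
      rows[[v]] <- data.frame(variable = v, or = NA, ci_lo = NA, ci_hi = NA,
                              p = NA, retained = FALSE, constant = TRUE)
      std[[v]] <- c(mean = NA_real_, sd = NA_real_)
      next
    }
    if (is_binary_col(xi)) {
      std[[v]] <- c(mean = 0, sd = 1)
    } else {
      std[[v]] <- c(mean = mean(xi), sd = stats::sd(xi))
      xi <- (xi - std[[v]][["mean"]]) / std[[v]][["sd"]]
    }
    fit <- stats::glm(yi ~ xi, family = stats::binomial())
    co <- summary(fit)$coefficients
    b <- co["xi", "Estimate"]; se <- co["xi", "Std. Error"]
    p <- co["xi", "Pr(>|z|)"]
    rows[[v]] <- data.frame(variable = v, or = exp(b),
                            ci_lo = exp(b - 1.96 * se),
                            ci_hi = exp(b + 1.96 * se),
                            p = p, retained = p < alpha, constant = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "standardization") <- std
  class(out) <- c("candidate_set", class(out))
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the linear regression
#' of predictor `j` on all the others. Exactly collinear predictors are
#' reported as `Inf`.
#'
#' @param train Data.frame with the predictor columns.
#' @param predictors Character vector (>= 2) of column names, none constant.
#' @return Named numeric vector of VIFs.
#' @export
vif_scores <- function(train, predictors) {
  stopifnot(length(predictors) >= 2)
  X <- as.matrix(train[, predictors, drop = FALSE])
  if (any(apply(X, 2, function(c) length(unique(c)) < 2)))
    stop("constant predictor in VIF computation")
  vifs <- vapply(seq_along(predictors), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vifs) <- predictors
  vifs
}

#' Sequential collinearity pruning
#'
#' Iteratively removes candidates until all VIFs are <= `vif_max` and all
#' pairwise Spearman correlations satisfy `|r| <= r_max`. Each round removes
#' one variable: the highest-VIF offender if any VIF exceeds the cap,
#' otherwise the member of the worst-correlated pair with the larger
#' univariate p-value. With `rule = "and"` a variable must violate both
#' limits to be removed (an exact duplicate pair always violates both).
#'
#' @param candidates A `candidate_set` from [univariate_screen()] (used for
#'   the retained set and the univariate p-values), or a character vector of
#'   variable names.
#' @param train Training data.frame.
#' @param vif_max VIF cap (default 10).
#' @param r_max Spearman |r| cap (default 0.8).
#' @param rule `"or"` (default: either violation is removable) or `"and"`.
#' @return Character vector of surviving predictor names, with attribute
#'   `removed` (named character of removal reasons).
#' @export
prune_collinearity <- function(candidates, train, vif_max = 10, r_max = 0.8,
                               rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (inherits(candidates, "candidate_set")) {
    vars <- candidates$variable[candidates$retained %in% TRUE]
    pvals <- stats::setNames(candidates$p, candidates$variable)
  } else {
    vars <- as.character(candidates)
    pvals <- stats::setNames(rep(NA_real_, length(vars)), vars)
  }
  removed <- character(0)
  for (iter in seq_len(length(vars))) {
    if (length(vars) < 2) break
    vifs <- vif_scores(train, vars)
    rho <- stats::cor(as.matrix(train[, vars, drop = FALSE]),
                      method = "spearman", use = "pairwise.complete.obs")
    diag(rho) <- 0
    max_r <- max(abs(rho))
    vif_bad <- vifs > vif_max
    r_bad <- apply(abs(rho) > r_max, 1, any)
    offenders <- if (rule == "or") vif_bad | r_bad else vif_bad & r_bad
    if (!any(offenders)) break
    if (any(vif_bad[offenders])) {
      drop_v <- names(which.max(ifelse(offenders, vifs, -Inf)))
      reason <- sprintf("VIF %.3g", vifs[drop_v])
    } else {
      pair <- which(abs(rho) == max_r, arr.ind = TRUE)[1, ]
      pv <- pvals[vars[pair]]
      drop_v <- vars[pair][which.max(ifelse(is.na(pv), 1, pv))]
      reason <- sprintf("|Spearman r| %.3g", max_r)
    }
    removed[drop_v] <- reason
    vars <- setdiff(vars, drop_v)
  }
  if (length(vars) < 1) stop("collinearity pruning removed every candidate")
  attr(vars, "removed") <- removed
  vars
}

#' Multivariable logistic regression fit
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`). Continuous
#' predictors are z-scored on training statistics (stored in the fit for
#' prediction); odds ratios and Wald 95% CIs are reported per SD for
#' continuous and per category for binary predictors. Non-convergence or
#' (quasi-)perfect separation raises an error rather than returning a
#' silently unusable fit.
#'
#' @param train Training data.frame.
#' @param predictors Character vector of predictor column names (may be
#'   empty: intercept-only model).
#' @param outcome Name of the binary outcome column.
#' @return An object of class `model_fit`: list with `coefficients`, `se`,
#'   `or`, `ci_lo`, `ci_hi`, `p`, `intercept`, `predictors`,
#'   `standardization`, `converged`, `n`.
#' @export
fit_logistic <- function(train, predictors, outcome) {
  y <- train[[outcome]]
  if (is.null(y) || !is_binary_col(y) || length(unique(stats::na.omit(y))) < 2)
    stop("outcome must be binary with both classes present")
  dat <- train[, c(outcome, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= length(predictors) + 1)
    stop("too few complete cases for the number of predictors")
  std <- list()
  X <- dat[, predictors, drop = FALSE]
  for (v in predictors) {
    if (is_binary_col(X[[v]])) {
      std[[v]] <- c(mean = 0, sd = 1)
    } else {
      std[[v]] <- c(mean = mean(X[[v]]), sd = stats::sd(X[[v]]))
      X[[v]] <- (X[[v]] - std[[v]][["mean"]]) / std[[v]][["sd"]]
    }
  }
  df <- cbind(data.frame(.y = dat[[outcome]]), X)
  fit <- if (length(predictors) == 0) {
    stats::glm(.y ~ 1, data = df, family = stats::binomial())
  } else {
    stats::glm(.y ~ ., data = df, family = stats::binomial())
  }
  if (!fit$converged) stop("logistic fit did not converge")
  co <- summary(fit)$coefficients
  if (any(abs(co[, "Estimate"]) > 15))
    stop("logistic fit unstable (|coefficient| > 15): likely separation")
  est <- co[-1, "Estimate"]; se <- co[-1, "Std. Error"]
  pwald <- co[-1, "Pr(>|z|)"]
  pv <- rownames(co)[-1]
  structure(list(
    predictors = predictors,
    coefficients = stats::setNames(est, pv),
    se = stats::setNames(se, pv),
    or = stats::setNames(exp(est), pv),
    ci_lo = stats::setNames(exp(est - 1.96 * se), pv),
    ci_hi = stats::setNames(exp(est + 1.96 * se), pv),
    p = stats::setNames(pwald, pv),
    intercept = co["(Intercept)", "Estimate"],
    standardization = std,
    converged = fit$converged,
    outcome = outcome,
    n = nrow(dat),
    fitted = as.numeric(stats::fitted(fit))
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> outcome '%s', n = %d\n", x$outcome, x$n))
  if (length(x$predictors) == 0) {
    cat(sprintf("  intercept-only: %.4f\n", x$intercept))
    return(invisible(x))
  }
  tab <- data.frame(OR = round(x$or, 3),
                    CI = sprintf("%.3f-%.3f", x$ci_lo, x$ci_hi),
                    p = signif(x$p, 3))
  print(tab)
  invisible(x)
}

#' Predicted probability from a fitted model
#'
#' Applies the stored training standardization to the record's predictor
#' values and returns `plogis(intercept + sum(coef * z))`.
#'
#' @param fit A [fit_logistic()] result (converged).
#' @param record Data.frame (one or more rows) or named list with the fit's
#'   predictor columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(fit, record) {
  stopifnot(inherits(fit, "model_fit"))
  if (!isTRUE(fit$converged)) stop("model fit did not converge")
  rec <- if (is.data.frame(record)) record
         else as.data.frame(record, check.names = FALSE)
  lp <- rep(fit$intercept, nrow(rec))
  for (v in fit$predictors) {
    if (is.null(rec[[v]]) || anyNA(rec[[v]]))
      stop("missing predictor value: ", v)
    z <- (rec[[v]] - fit$standardization[[v]][["mean"]]) /
      fit$standardization[[v]][["sd"]]
    lp <- lp + fit$coefficients[[v]] * z
  }
  stats::plogis(lp)
}

#' Radiological feature set of the diagnostic model
#'
#' The three IMAT features used by the radiological model: the IMAT-to-muscle
#' ratio and the IMAT fractal dimension and multifractal range.
#' @return Character vector of column names.
#' @export
radiological_features <- function() c("imr", "imat_fd", "imat_mfr")

#' Build the clinical, radiological and combined diagnostic models
#'
#' On one training set: (1) screens all candidate predictors univariately;
#' (2) prunes collinearity among the retained clinical candidates; then fits
#' three logistic models: clinical (pruned clinical candidates),
#' radiological (exactly IMR + IMAT FD + IMAT multifractal range), and
#' combined (union of the two predictor sets).
#'
#' @param train Training data.frame with clinical columns, radiological
#'   feature columns (see [radiological_features()]) and the outcome.
#' @param outcome Binary outcome column name (default `"mets_label"`).
#' @param alpha Univariate screening level (default 0.1).
#' @param vif_max,r_max Collinearity caps (defaults 10 and 0.8).
#' @param clinical_candidates Character vector of clinical columns to screen
#'   (default: all numeric non-outcome columns that are not radiological or
#'   fractal features).
#' @return List of class `model_triplet` with `clinical`, `radiological`,
#'   `combined` ([fit_logistic()] fits), the `screen` table and the pruned
#'   `clinical_predictors`.
#' @export
build_three_models <- function(train, outcome = "mets_label", alpha = 0.1,
                               vif_max = 10, r_max = 0.8,
                               clinical_candidates = NULL) {
  radio <- radiological_features()
  if (!all(radio %in% names(train)))
    stop("training data lacks radiological feature columns: ",
         paste(setdiff(radio, names(train)), collapse = ", "))
  if (is.null(clinical_candidates)) {
    numeric_cols <- names(train)[vapply(train, is.numeric, logical(1))]
    imaging_cols <- grep("_(fd|lacunarity|mfr|cm3)$", numeric_cols,
                         value = TRUE)
    clinical_candidates <- setdiff(numeric_cols,
                                   c(outcome, radio, imaging_cols,
                                     "smi", "sati", "imati", "isr", "msr"))
  }
  screen <- univariate_screen(train, outcome,
                              predictors = clinical_candidates, alpha = alpha)
  kept <- screen$variable[screen$retained %in% TRUE]
  clin_pred <- if (length(kept) >= 2) {
    prune_collinearity(screen, train, vif_max = vif_max, r_max = r_max)
  } else kept
  structure(list(
    clinical = fit_logistic(train, clin_pred, outcome),
    radiological = fit_logistic(train, radio, outcome),
    combined = fit_logistic(train, union(clin_pred, radio), outcome),
    screen = screen,
    clinical_predictors = clin_pred
  ), class = "model_triplet")
}
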