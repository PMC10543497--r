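TTP_CANDIDATES <- c("t_C1D1", "ce_cm3", "fluid_cm3",
                    "edema1_cm3", "edema2_cm3", "high_flair_cm3")

#' Validate and complete a scan-record table
#'
#' A scan record is one patient-timepoint: days on treatment since cycle-1
#' day-1 (`t_C1D1`), per-tissuetype volumes within the abVOI in cm^3, and
#' the observed time-to-progression in days (`ttp_days`, `NA` for
#' non-progressors; a few post-progression timepoints with negative TTP
#' are allowed). `high_flair_cm3` is derived as `edema1_cm3 + edema2_cm3`
#' when absent, and checked when present.
#'
#' @param records Data frame with columns `patient_id`, `t_C1D1`,
#'   `ce_cm3`, `fluid_cm3`, `edema1_cm3`, `edema2_cm3`, optionally
#'   `scan_date`, `high_flair_cm3`, `ttp_days`, `cohort`.
#' @return A validated tibble.
#' @export
scan_records <- function(records) {
  records <- tibble::as_tibble(records)
  req <- c("patient_id", "t_C1D1", "ce_cm3", "fluid_cm3",
           "edema1_cm3", "edema2_cm3")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("scan records missing column(s): ", paste(missing, collapse = ", "))
  if (any(records$t_C1D1 < 0, na.rm = TRUE))
    stop("t_C1D1 must be >= 0 for on-study records")
  vols <- c("ce_cm3", "fluid_cm3", "edema1_cm3", "edema2_cm3")
  if (any(unlist(records[vols]) < 0, na.rm = TRUE))
    stop("tissue volumes must be >= 0")
  hf <- records$edema1_cm3 + records$edema2_cm3
  if (!"high_flair_cm3" %in% names(records)) {
    records$high_flair_cm3 <- hf
  } else if (any(abs(records$high_flair_cm3 - hf) > 1e-8, na.rm = TRUE)) {
    stop("high_flair_cm3 must equal edema1_cm3 + edema2_cm3")
  }
  records
}

#' Pairwise Pearson correlations of longitudinal variables
#'
#' Cross-correlates the per-timepoint abVOI volumes, time on treatment and
#' observed TTP across all records with complete data, with two-sided
#' p-values from [stats::cor.test()]. Zero-variance variables yield
#' undefined correlations and are flagged with `NA` and a warning.
#'
#' @param records A [scan_records()] table (rows with `NA` in the selected
#'   variables are dropped).
#' @param vars Variables to correlate; defaults to the five abVOI volumes,
#'   `t_C1D1` and `ttp_days`.
#' @return Object of class `ttp_cor`: list with matrices `r`, `p` and the
#'   number of records `n`. Use [generics::tidy()] for a long tibble.
#' @export
correlation_matrix <- function(records,
                               vars = c(TTP_CANDIDATES, "ttp_days")) {
  records <- scan_records(records)
  vars <- intersect(vars, names(records))
  if (length(vars) < 2L) stop("need at least two variables")
  x <- records[vars]
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 complete records")
  p <- r <- matrix(NA_real_, length(vars), length(vars),
                   dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (j <= i) next
    xi <- x[[i]]; xj <- x[[j]]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      warning("zero variance in ", vars[if (stats::sd(xi) == 0) i else j],
              ": correlation undefined")
      next
    }
    ct <- stats::cor.test(xi, xj)
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = nrow(x)), class = "ttp_cor")
}

#' @export
print.ttp_cor <- function(x, digits = 2, ...) {
  cat(sprintf("<ttp_cor> Pearson correlations over %d records\n", x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy ttp_cor
#' @export
tidy.ttp_cor <- function(x, ...) {
  vars <- rownames(x$r)
  out <- tidyr::expand_grid(var1 = vars, var2 = vars)
  out <- out[match(out$var1, vars) < match(out$var2, vars), ]
  out$estimate <- x$r[cbind(out$var1, out$var2)]
  out$p.value <- x$p[cbind(out$var1, out$var2)]
  out$n <- x$n
  out
}

#' Construct a time-to-progression linear model directly
#'
#' Builds a `ttp_model` from explicit intercept and coefficients, e.g. a
#' published fit, without refitting. Models produced by [select_model()]
#' carry the underlying [stats::lm] fit as well.
#'
#' @param intercept Intercept in days.
#' @param coefficients Named numeric vector of slopes (days per unit) over
#'   the scan-record columns, e.g. `c(t_C1D1 = -0.6, ce_cm3 = -2.5,
#'   fluid_cm3 = 4.8)`.
#' @param mean_cv_aic,n_records,seed,fit Optional selection metadata.
#' @return Object of class `ttp_model`.
#' @export
ttp_model <- function(intercept, coefficients, mean_cv_aic = NA_real_,
                      n_records = NA_integer_, seed = NA_integer_,
                      fit = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  if (length(coefficients) && is.null(names(coefficients)))
    stop("coefficients must be named by predictor")
  if (any(!is.finite(c(intercept, coefficients))))
    stop("intercept and coefficients must be finite")
  structure(
    list(predictors = names(coefficients),
         intercept = unname(intercept),
         coefficients = coefficients,
         mean_cv_aic = mean_cv_aic, n_records = n_records,
         seed = seed, fit = fit),
    class = "ttp_model"
  )
}

#' @export
print.ttp_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g*%s", x$coefficients, x$predictors),
                 collapse = " ")
  cat(sprintf("<ttp_model> TTP = %.4g %s (days)\n", x$intercept, terms))
  if (is.finite(x$mean_cv_aic))
    cat(sprintf("  mean CV AIC %.2f over %d records (seed %s)\n",
                x$mean_cv_aic, x$n_records, format(x$seed)))
  invisible(x)
}

#' @method tidy ttp_model
#' @export
tidy.ttp_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    s <- summary(x$fit)$coefficients
    return(tibble::tibble(
      term = rownames(s), estimate = s[, 1], std.error = s[, 2],
      statistic = s[, 3], p.value = s[, 4]
    ))
  }
  tibble::tibble(
    term = c("(Intercept)", x$predictors),
    estimate = c(x$intercept, unname(x$coefficients)),
    std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
  )
}

#' @method glance ttp_model
#' @export
glance.ttp_model <- function(x, ...) {
  if (is.null(x$fit))
    return(tibble::tibble(r.squared = NA_real_, adj.r.squared = NA_real_,
                          sigma = NA_real_, statistic = NA_real_,
                          p.value = NA_real_, df = length(x$predictors),
                          mean_cv_aic = x$mean_cv_aic, nobs = x$n_records))
  s <- summary(x$fit)
  fstat <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    p.value = if (is.null(fstat)) NA_real_ else
      stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    df = length(x$predictors),
    mean_cv_aic = x$mean_cv_aic, nobs = x$n_records
  )
}

# Near-equal fold sizes from a seeded permutation; returns fold id per row.
cv_folds <- function(n, k, seed) {
  if (!is.na(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  perm <- sample.int(n)
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  fold
}

# Mean cross-validated AIC of one predictor subset.
# Each fold: OLS on the 9/10 training split, then AIC formed from the
# Gaussian log-likelihood of the held-out segment under the training fit
# (sigma^2 = training MLE, k = p + 2 parameters). aic_on = "train" instead
# scores the standard in-sample AIC of the training fit.
cv_aic_subset <- function(y, X, fold, k_folds, aic_on) {
  p <- ncol(X)
  aics <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f; ho <- !tr
    Xtr <- cbind(1, X[tr, , drop = FALSE])
    qr_tr <- qr(Xtr)
    if (qr_tr$rank < ncol(Xtr)) return(NA_real_)  # singular design
    beta <- qr.coef(qr_tr, y[tr])
    res_tr <- y[tr] - Xtr %*% beta
    sigma2 <- max(sum(res_tr^2) / sum(tr), 1e-12)
    k_par <- p + 2  # coefficients + intercept + sigma
    if (aic_on == "holdout") {
      res_ho <- y[ho] - cbind(1, X[ho, , drop = FALSE]) %*% beta
      ll <- sum(stats::dnorm(res_ho, 0, sqrt(sigma2), log = TRUE))
    } else {
      ll <- sum(stats::dnorm(res_tr, 0, sqrt(sigma2), log = TRUE))
    }
    aics[f] <- -2 * ll + 2 * k_par
  }
  mean(aics)
}

#' Exhaustive-subset linear-model selection by cross-validated AIC
#'
#' Considers every non-empty subset of the candidate predictors (all
#' possible linear combinations, no interactions or transforms). For each
#' subset the records are split into `k_folds` nearly equally sized
#' segments by a seeded random permutation; an ordinary least-squares fit
#' on each training split is scored by an AIC formed from the held-out
#' segment's Gaussian log-likelihood, and the scores are averaged over the
#' folds. The subset with the lowest mean CV AIC wins and is refit on all
#' records. Singular subsets (e.g. containing Edema1, Edema2 and their sum
#' High FLAIR together) are skipped. Ties in mean CV AIC go to the smaller
#' subset, then lexicographic order.
#'
#' Records without an observed `ttp_days` (non-progressors) are excluded
#' from fitting.
#'
#' @param records A [scan_records()] table.
#' @param candidate_vars Candidate predictor columns; default all six
#'   (`t_C1D1`, CE, Fluid, Edema1, Edema2, High FLAIR).
#' @param k_folds Number of CV segments (default 10; `k_folds = n` gives
#'   leave-one-out).
#' @param seed Seed for the fold permutation (required, recorded).
#' @param aic_on `"holdout"` (default) or `"train"`: where the
#'   log-likelihood entering the AIC is evaluated.
#' @return A [ttp_model()] carrying the full-data [stats::lm] refit and a
#'   `cv_table` attribute (tibble of every subset's mean CV AIC).
#' @export
select_model <- function(records, candidate_vars = TTP_CANDIDATES,
                         k_folds = 10, seed,
                         aic_on = c("holdout", "train")) {
  aic_on <- match.arg(aic_on)
  records <- scan_records(records)
  if (!"ttp_days" %in% names(records))
    stop("records must carry ttp_days for model fitting")
  usable <- records[!is.na(records$ttp_days), , drop = FALSE]
  n <- nrow(usable)
  if (n < k_folds) stop("need at least k_folds records with observed TTP")
  missing <- setdiff(candidate_vars, names(usable))
  if (length(missing))
    stop("candidate variable(s) not in records: ",
         paste(missing, collapse = ", "))
  y <- usable$ttp_days
  Xall <- as.matrix(usable[candidate_vars])
  fold <- cv_folds(n, k_folds, seed)

  subsets <- unlist(lapply(seq_along(candidate_vars), function(k)
    utils::combn(candidate_vars, k, simplify = FALSE)), recursive = FALSE)
  aic <- vapply(subsets, function(s)
    cv_aic_subset(y, Xall[, s, drop = FALSE], fold, k_folds, aic_on),
    numeric(1))
  skipped <- is.na(aic)
  if (all(skipped)) stop("all candidate subsets have singular designs")
  cv_table <- tibble::tibble(
    predictors = vapply(subsets, paste, character(1), collapse = "+"),
    n_predictors = lengths(subsets),
    mean_cv_aic = aic
  )
  ord <- order(aic, lengths(subsets), cv_table$predictors)
  best <- subsets[[ord[1L]]]

  fml <- stats::reformulate(best, response = "ttp_days")
  fit <- stats::lm(fml, data = usable)
  co <- stats::coef(fit)
  model <- ttp_model(
    intercept = co[["(Intercept)"]],
    coefficients = co[setdiff(names(co), "(Intercept)")],
    mean_cv_aic = aic[ord[1L]], n_records = n, seed = seed, fit = fit
  )
  attr(model, "cv_table") <- cv_table
  model
}

#' Predict time-to-progression for scan records
#'
#' Evaluates `intercept + sum(coefficient * value)` for each record.
#'
#' @param model A [ttp_model()].
#' @param records A data frame carrying every model predictor (a
#'   [scan_records()] table, or any table with the right columns).
#' @return Numeric vector of predicted TTP in days, one per record row.
#' @export
predict_ttp <- function(model, records) {
  stopifnot(inherits(model, "ttp_model"))
  records <- tibble::as_tibble(records)
  missing <- setdiff(model$predictors, names(records))
  if (length(missing))
    stop("records missing model predictor(s): ",
         paste(missing, collapse = ", "))
  pred <- rep(model$intercept, nrow(records))
  for (v in model$predictors)
    pred <- pred + model$coefficients[[v]] * records[[v]]
  if (any(is.na(pred))) stop("missing predictor values in records")
  as.numeric(pred)
}

#' Accuracy of binary progression-within-horizon prediction
#'
#' Each timepoint is labeled 1 if its TTP (true, respectively predicted)
#' is at most `n` days and 0 otherwise; accuracy is the fraction of
#' timepoints where the two labels agree.
#'
#' @param true_ttp,pred_ttp Equal-length numeric vectors of TTP in days.
#' @param n Horizon in days (e.g. 30, 60, 90).
#' @return Fraction in `[0, 1]`.
#' @export
horizon_accuracy <- function(true_ttp, pred_ttp, n) {
  if (length(true_ttp) == 0L) stop("empty TTP vectors")
  if (length(true_ttp) != length(pred_ttp))
    stop("true and predicted TTP vectors must have equal length")
  mean((true_ttp <= n) == (pred_ttp <= n))
}
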