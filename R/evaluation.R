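# Evaluation machinery: leave-one-bay-out folds, percentage errors, robust
# line fits, and per-stage summary statistics.

#' Leave-one-bay-out cross-validation folds
#'
#' One fold per bay: the bay is held out for testing and the remaining bays
#' form the training set. Folds are ordered by bay label, so the design is
#' deterministic.
#'
#' @param x A `plot_samples` object, or a data frame with a `bay` column.
#' @return A list of folds, each a list with `fold_id`, `test_bay`,
#'   `train_bays`, `train` and `test` (integer indices).
#' @export
make_bay_folds <- function(x) {
  meta <- if (inherits(x, "plot_samples")) x$meta else as.data.frame(x)
  if (is.null(meta$bay)) stop("samples carry no bay labels", call. = FALSE)
  bays <- sort(unique(meta$bay))
  if (length(bays) < 2L)
    stop("bay-wise cross-validation requires at least 2 bays", call. = FALSE)
  lapply(seq_along(bays), function(i) {
    test <- which(meta$bay == bays[i])
    list(fold_id = i, test_bay = bays[i], train_bays = setdiff(bays, bays[i]),
         train = setdiff(seq_len(nrow(meta)), test), test = test)
  })
}

#' Relative percentage estimation error
#'
#' `(observed - estimated) / observed * 100`: an overestimate gives a
#' negative error. Samples with `observed == 0` are undefined; they are
#' returned as `NA` and counted in the `n_undefined` attribute so summaries
#' can exclude them explicitly.
#'
#' @param observed,estimated Numeric vectors of equal length.
#' @return Percentage errors with attribute `n_undefined`.
#' @export
#' @examples
#' percentage_error(0.5, 0.49)  # 2
#' percentage_error(0.4, 0.5)   # -25
percentage_error <- function(observed, estimated) {
  if (length(observed) != length(estimated))
    stop("`observed` and `estimated` must have equal length", call. = FALSE)
  undef <- observed == 0
  err <- ifelse(undef, NA_real_, (observed - estimated) / observed * 100)
  attr(err, "n_undefined") <- sum(undef)
  err
}

#' Robust least-squares line fit
#'
#' Iteratively reweighted least squares with Tukey bisquare weights (tuning
#' constant 4.685, residual scale = MAD/0.6745), iterated until the
#' parameter change is below `tol` or `maxit` iterations. If the residual
#' scale is zero (an exact linear relationship) or no residual exceeds the
#' bisquare threshold, the fit coincides with ordinary least squares.
#' `r2`, `rmse` and the Pearson correlation are computed on all points
#' against the robust line (not refit by OLS).
#'
#' @param x Observed values (the regressor); must not be constant.
#' @param y Estimated values (the response).
#' @param tuning Bisquare tuning constant.
#' @param tol Convergence tolerance on the coefficients.
#' @param maxit Maximum IRLS iterations.
#' @return An object of class `robust_linefit` with `slope`, `intercept`,
#'   `r2`, `rmse`, `pearson_r`, `weights`, `iterations`, `converged`.
#' @export
#' @examples
#' f <- robust_linefit(1:10, 2 * (1:10) + 1)
#' c(f$slope, f$intercept, f$r2)
robust_linefit <- function(x, y, tuning = 4.685, tol = 1e-8, maxit = 50L) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (max(x) == min(x))
    stop("cannot fit a line: x is constant", call. = FALSE)
  X <- cbind(1, x)
  beta <- qr.solve(X, y)          # OLS start
  w <- rep(1, length(x))
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    r <- y - X %*% beta
    s <- median(abs(r - median(r))) / 0.6745
    if (s == 0) { converged <- TRUE; break }   # exact fit: keep OLS line
    u <- as.numeric(r) / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2L) break
    beta_new <- qr.solve(X * sqrt(w), y * sqrt(w))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; converged <- TRUE; break }
    beta <- beta_new
  }
  yhat <- as.numeric(X %*% beta)
  res <- y - yhat
  sst <- sum((y - mean(y))^2)
  structure(list(slope = unname(beta[2]), intercept = unname(beta[1]),
                 r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
                 rmse = sqrt(mean(res^2)),
                 pearson_r = cor(x, y),
                 weights = as.numeric(w), iterations = it,
                 converged = converged),
            class = "robust_linefit")
}

#' @export
print.robust_linefit <- function(x, ...) {
  cat(sprintf("Robust line: y = %.4f x %+.4f  (R2 = %.4f, RMSE = %.4g, r = %.4f)\n",
              x$slope, x$intercept, x$r2, x$rmse, x$pearson_r))
  invisible(x)
}

#' Box-plot statistics of a sample
#'
#' Quartiles by linear interpolation of order statistics (type 7), whiskers
#' at the most extreme points within `[q1 - w*(q3-q1), q3 + w*(q3-q1)]`
#' (default `w = 1.5`), and the values beyond the whiskers as outliers.
#'
#' @param v Numeric vector (NAs dropped).
#' @param whisker Whisker multiplier `w`.
#' @return A list with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
box_stats <- function(v, whisker = 1.5) {
  v <- v[!is.na(v)]
  if (!length(v)) stop("no data for box statistics", call. = FALSE)
  q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - whisker * iqr
  hi <- q[3] + whisker * iqr
  inside <- v >= lo & v <= hi
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(v[inside]), whisker_hi = max(v[inside]),
       outliers = v[!inside])
}

#' Per-stage and pooled evaluation of a VI estimation model
#'
#' Computes, per growth stage, the mean and standard deviation of the
#' percentage errors ([percentage_error()]), the within-stage Pearson
#' correlation of observed and estimated VI, and box statistics of the
#' errors; and, pooled over all stages, the robust line fit
#' ([robust_linefit()]) of estimated on observed VI. Samples with
#' `observed == 0` are excluded from the error moments and counted.
#'
#' @param observed,estimated Numeric vectors of observed and estimated VI.
#' @param stage Stage label per sample.
#' @param model_name Label stored in the report.
#' @param n_train,n_test Optional bookkeeping counts stored in the report.
#' @return An object of class `eval_report`: `model`, `per_stage` (data
#'   frame), `pooled` (`robust_linefit`), `n`, `n_undefined`, `n_train`,
#'   `n_test`. `as.data.frame()` returns the per-stage table.
#' @export
summarize_errors <- function(observed, estimated, stage,
                             model_name = "model",
                             n_train = NA_integer_, n_test = NA_integer_) {
  stopifnot(length(observed) == length(estimated),
            length(observed) == length(stage))
  if (!length(observed)) stop("no samples to evaluate", call. = FALSE)
  err <- percentage_error(observed, estimated)
  per_stage <- do.call(rbind, lapply(sort(unique(stage)), function(s) {
    i <- stage == s
    e <- err[i]
    ok <- !is.na(e)
    if (!any(ok)) {
      return(data.frame(model = model_name, stage = s, n = sum(i),
                        mean_pct = NA_real_, sd_pct = NA_real_,
                        pearson_r = NA_real_, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_, whisker_lo = NA_real_,
                        whisker_hi = NA_real_, n_outliers = NA_integer_))
    }
    bs <- box_stats(e[ok])
    data.frame(model = model_name, stage = s, n = sum(i),
               mean_pct = mean(e[ok]), sd_pct = sd(e[ok]),
               pearson_r = if (sum(i) > 2)
                             suppressWarnings(cor(observed[i], estimated[i]))
                           else NA_real_,
               median = bs$median, q1 = bs$q1, q3 = bs$q3,
               whisker_lo = bs$whisker_lo, whisker_hi = bs$whisker_hi,
               n_outliers = length(bs$outliers))
  }))
  pooled <- if (max(observed) > min(observed))
    robust_linefit(observed, estimated) else NULL
  structure(list(model = model_name, per_stage = per_stage, pooled = pooled,
                 n = length(observed),
                 n_undefined = attr(err, "n_undefined"),
                 n_train = n_train, n_test = n_test),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation of %s (%d samples", x$model, x$n))
  if (x$n_undefined > 0)
    cat(sprintf(", %d excluded: observed VI = 0", x$n_undefined))
  cat(")\n")
  if (!is.null(x$pooled)) { cat("  pooled "); print(x$pooled) }
  df <- x$per_stage
  cat("  per stage (error %):\n")
  for (i in seq_len(nrow(df)))
    cat(sprintf("    stage %s: %6.2f +/- %5.2f  (r = %.3f, n = %d)\n",
                df$stage[i], df$mean_pct[i], df$sd_pct[i], df$pearson_r[i],
                df$n[i]))
  invisible(x)
}

#' @export
as.data.frame.eval_report <- function(x, ...) x$per_stage

#' Write an evaluation report as CSV and JSON
#'
#' The CSV holds one row per stage (mean, sd, r and box statistics of the
#' percentage errors); the JSON additionally holds the pooled robust fit and
#' the bookkeeping counts.
#'
#' @param report An `eval_report` (or a list of them).
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  reports <- if (inherits(report, "eval_report")) list(report) else report
  per_stage <- do.call(rbind, lapply(reports, `[[`, "per_stage"))
  if (!is.null(csv_path))
    write.csv(format(per_stage, digits = 10, trim = TRUE, scientific = FALSE),
              csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    payload <- lapply(reports, function(r) list(
      model = r$model, n = r$n, n_undefined = r$n_undefined,
      n_train = r$n_train, n_test = r$n_test,
      pooled = r$pooled[c("slope", "intercept", "r2", "rmse", "pearson_r")],
      per_stage = r$per_stage))
    names(payload) <- vapply(reports, `[[`, "", "model")
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}
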