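test_that("bay folds hold out each bay exactly once", {
  meta <- data.frame(bay = rep(c("C", "A", "B"), each = 4),
                     stage = rep(1:2, 6))
  folds <- make_bay_folds(meta)
  expect_length(folds, 3)
  expect_equal(vapply(folds, `[[`, "", "test_bay"), c("A", "B", "C"))
  expect_equal(folds[[1]]$train_bays, c("B", "C"))
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(all_test, seq_len(nrow(meta)))  # partition
  for (f in folds) expect_length(intersect(f$train, f$test), 0)
  expect_error(make_bay_folds(data.frame(bay = rep("A", 5))), "at least 2")
})

test_that("percentage error follows the relative-difference convention", {
  expect_equal(as.numeric(percentage_error(0.5, 0.49)), 2)
  expect_equal(as.numeric(percentage_error(0.7, 0.7)), 0)
  expect_equal(as.numeric(percentage_error(0.4, 0.5)), -25)  # overestimate < 0
  e <- percentage_error(c(0.5, 0, 0.2), c(0.4, 0.1, 0.2))
  expect_true(is.na(e[2]))
  expect_equal(attr(e, "n_undefined"), 1)
})

test_that("robust line fit recovers exact linear relationships", {
  x <- seq(0, 1, length.out = 20)
  f <- robust_linefit(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$r2, 1)
  expect_equal(f$rmse, 0, tolerance = 1e-12)
  expect_equal(robust_linefit(x, x)$pearson_r, 1)
  expect_error(robust_linefit(rep(1, 5), 1:5), "constant")
  expect_error(robust_linefit(1:2, 1:2), "at least 3")
})

test_that("robust fit resists a gross outlier better than OLS", {
  set.seed(11)
  x <- seq(0, 1, length.out = 40)
  y <- 2 * x + 0.5 + rnorm(40, 0, 0.01)
  y[7] <- 8  # gross outlier
  rob <- robust_linefit(x, y)
  ols <- unname(coef(lm(y ~ x)))  # closed-form least-squares oracle
  expect_lt(abs(rob$slope - 2), abs(ols[2] - 2))
  expect_lt(abs(rob$intercept - 0.5), abs(ols[1] - 0.5))
  expect_lt(rob$weights[7], 0.01)  # the outlier is effectively discarded
})

test_that("robust fit equals OLS when no residual exceeds the bisquare threshold", {
  set.seed(12)
  x <- seq(0, 1, length.out = 30)
  y <- 1.5 * x + 0.2 + rnorm(30, 0, 0.05)  # homogeneous noise, no outliers
  rob <- robust_linefit(x, y)
  if (all(rob$weights == 1)) {
    ols <- unname(coef(lm(y ~ x)))
    expect_equal(rob$intercept, ols[1], tolerance = 1e-10)
    expect_equal(rob$slope, ols[2], tolerance = 1e-10)
  } else {
    # with mild downweighting the robust slope still tracks OLS closely
    expect_equal(rob$slope, unname(coef(lm(y ~ x))[2]), tolerance = 0.05)
  }
})

test_that("robust fit agrees with an independent M-estimation implementation", {
  skip_if_not_installed("MASS")
  set.seed(13)
  x <- runif(80)
  y <- 0.9 * x + 0.1 + rnorm(80, 0, 0.03)
  y[c(3, 40)] <- y[c(3, 40)] + c(1, -1.5)
  rob <- robust_linefit(x, y)
  mm <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 50)
  expect_equal(rob$slope, unname(coef(mm)[2]), tolerance = 0.02)
  expect_equal(rob$intercept, unname(coef(mm)[1]), tolerance = 0.02)
})

test_that("box statistics agree with a brute-force oracle on small sets", {
  set.seed(14)
  for (n in c(4, 5, 7, 9, 12, 15, 20)) {
    v <- round(rnorm(n, 0, 10), 2)
    got <- box_stats(v)
    ref <- ref_box_stats(v)
    for (fld in c("median", "q1", "q3", "whisker_lo", "whisker_hi"))
      expect_equal(got[[fld]], ref[[fld]], info = sprintf("n=%d %s", n, fld))
    expect_equal(sort(got$outliers), sort(ref$outliers), info = n)
  }
})

test_that("summaries reproduce simple hand-computable groups", {
  r <- summarize_errors(observed = c(1, 1, 1), estimated = c(0.99, 0.98, 0.97),
                        stage = c(1, 1, 1))
  expect_equal(r$per_stage$mean_pct, 2)
  expect_equal(r$per_stage$median, 2)

  # {0,0,0,100} with w = 1.5: 100 is the lone outlier
  obs <- rep(1, 4); est <- c(1, 1, 1, 0)
  r2 <- summarize_errors(c(obs, obs), c(est, est), stage = rep(1:2, each = 4))
  expect_equal(r2$per_stage$n_outliers, c(1L, 1L))
  expect_equal(r2$per_stage$whisker_hi, c(0, 0))
  # identical error sets in both stages give identical rows
  a <- r2$per_stage[1, -2]; b <- r2$per_stage[2, -2]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("zero observed values are excluded from moments with a count", {
  r <- summarize_errors(observed = c(0, 0.5, 0.5), estimated = c(0.1, 0.4, 0.6),
                        stage = rep(1, 3))
  expect_equal(r$n_undefined, 1)
  expect_equal(r$per_stage$mean_pct, 0)  # +20% and -20%
})

test_that("reports can be written as CSV and JSON", {
  set.seed(15)
  obs <- runif(40, 0.2, 0.8)
  est <- obs + rnorm(40, 0, 0.02)
  r <- summarize_errors(obs, est, stage = rep(1:4, 10), model_name = "demo")
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_eval_report(r, csv, js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("model", "stage", "mean_pct", "sd_pct", "pearson_r") %in%
                  names(tab)))
  j <- jsonlite::read_json(js)
  expect_equal(j$demo$n, 40)
  expect_true(is.numeric(j$demo$pooled$r2))
  unlink(c(csv, js))
})
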