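test_that("wilks_lambda matches the determinant-ratio definition", {
  # identical class means -> no separation -> lambda 1
  x <- matrix(c(0, 1, 0, 1), ncol = 1)
  expect_equal(wilks_lambda(x, c(0, 0, 1, 1)), 1)

  # zero within-class variance with distinct means -> lambda 0
  x <- matrix(c(0, 0, 1, 1), ncol = 1)
  expect_equal(wilks_lambda(x, c(0, 0, 1, 1)), 0)

  # fixed 6x2 integer matrix vs brute-force determinant evaluation
  X <- matrix(c(1, 2, 3, 5, 6, 7,
                2, 1, 3, 4, 6, 5), ncol = 2)
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(wilks_lambda(X, y), brute_wilks(X, y), tolerance = 1e-12)
  expect_gt(wilks_lambda(X, y), 0)
  expect_lt(wilks_lambda(X, y), 1)

  # collinear pair -> error naming a variable
  Xc <- cbind(a = c(1, 2, 3, 4, 5, 6), b = 2 * c(1, 2, 3, 4, 5, 6))
  expect_error(wilks_lambda(Xc, y), "collinear")
})

test_that("partial F reduces to the one-way ANOVA F at empty selection", {
  set.seed(8)
  x <- c(0.3, 1.2, -0.5, 0.9, 2.1, 1.7, 0.4, 1.0)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  pf1 <- partial_f(matrix(x, dimnames = list(NULL, "v")), y, "v")
  expect_equal(pf1$F, brute_anova_f(x, y), tolerance = 1e-12)
  expect_equal(pf1$df2, 6L)

  # candidate with equal class means and zero pooled within-group
  # cross-product against the selection -> F = 0
  X <- cbind(s = c(1, 2, 3, 4, 5, 6), c = rep(c(1, -2, 1), 2))
  y2 <- rep(c(0, 1), each = 3)
  expect_equal(partial_f(X, y2, "c", "s")$F, 0, tolerance = 1e-12)

  # entry F equals removal F when the state is otherwise unchanged
  set.seed(9)
  X3 <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y3 <- rep(c(0, 1), each = 10)
  f_in <- partial_f(X3, y3, "c", c("a", "b"))
  f_out <- partial_f(X3, y3, "c", c("a", "b", "c"))
  expect_equal(f_in$F, f_out$F, tolerance = 1e-10)

  expect_error(partial_f(X3[1:4, ], y3[c(1, 2, 11, 12)], "c", c("a", "b")),
               "saturated")
})

test_that("stepwise selection obeys the entry/removal thresholds", {
  set.seed(21)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  X[, 3] <- X[, 3] + 2.5 * y  # one strongly separating variable
  fit <- fit_stepwise_lda(X, y, lda_fit_config(f_enter = 2))

  # the planted separator enters first
  expect_identical(fit$trace$variable[1], "v3")
  # lambda non-increasing along entry steps
  entries <- fit$trace[fit$trace$action == "enter", ]
  expect_true(all(entries$lambda_after <= entries$lambda_before + 1e-12))
  # selected variables keep F-to-remove >= threshold
  expect_true(all(fit$variable_stats$F_to_remove >= fit$config$f_remove - 1e-8))
  # excluded variables would not qualify for entry at termination
  for (v in setdiff(colnames(X), fit$selected)) {
    expect_lte(partial_f(X, y, v, fit$selected)$F, fit$config$f_enter + 1e-8)
  }

  # an unreachable threshold yields a valid empty model
  empty <- fit_stepwise_lda(X, y, lda_fit_config(f_enter = 1e9))
  expect_length(empty$selected, 0)
  pred <- predict(empty, X)
  expect_true(all(pred$class == 0L))
  expect_true(all(pred$p_positive == 0.5))
})

test_that("with a vanishing threshold the fit equals direct LDA", {
  cfg <- lda_fit_config(f_enter = 1e-9, max_steps = 500)
  for (s in 1:10) {
    set.seed(300 + s)
    n <- 40
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
    X[, 1] <- X[, 1] + 0.8 * y
    fit <- fit_stepwise_lda(X, y, cfg)
    expect_setequal(fit$selected, colnames(X))

    Xte <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(NULL, paste0("v", 1:5)))
    got <- predict(fit, Xte)
    want <- brute_lda_predict(X, y, Xte)
    expect_identical(got$class, want$class)
    expect_equal(got$p_positive, want$p_positive, tolerance = 1e-8)
  }
})

test_that("posteriors are symmetric at the midpoint and saturate far out", {
  set.seed(5)
  n <- 100
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  X[, 1] <- X[, 1] + 6 * y   # >= 5 Mahalanobis units apart
  fit <- fit_stepwise_lda(X, y, lda_fit_config(f_enter = 0.5))

  mid <- (fit$means["0", ] + fit$means["1", ]) / 2
  p_mid <- predict(fit, matrix(mid, 1, dimnames = list(NULL, names(mid))))
  expect_equal(p_mid$p_positive, 0.5, tolerance = 1e-10)

  p_far <- predict(fit, matrix(fit$means["1", ], 1,
                               dimnames = list(NULL, colnames(fit$means))))
  expect_gt(p_far$p_positive, 0.99)

  expect_error(predict(fit, matrix(0, 1, 1, dimnames = list(NULL, "a"))),
               "lacks selected")
})

test_that("decisions are invariant to affine rescaling of one variable", {
  set.seed(77)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  X[, 2] <- X[, 2] + 1.2 * y
  fit1 <- fit_stepwise_lda(X, y, lda_fit_config(f_enter = 0.5))
  X2 <- X
  X2[, 2] <- 40 * X2[, 2] + 7
  fit2 <- fit_stepwise_lda(X2, y, lda_fit_config(f_enter = 0.5))
  expect_identical(fit1$selected, fit2$selected)
  expect_identical(predict(fit1, X)$class, predict(fit2, X2)$class)
  expect_equal(predict(fit1, X)$p_positive, predict(fit2, X2)$p_positive,
               tolerance = 1e-8)
})

test_that("equal and empirical priors agree on balanced data", {
  set.seed(13)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("v", 1:3)))
  X[, 1] <- X[, 1] + y
  f_eq <- fit_stepwise_lda(X, y, lda_fit_config(f_enter = 0.5, priors = "equal"))
  f_em <- fit_stepwise_lda(X, y, lda_fit_config(f_enter = 0.5, priors = "empirical"))
  expect_identical(predict(f_eq, X)$class, predict(f_em, X)$class)
})

test_that("stepwise agrees with an independent LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(99)
  n <- 50
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  X[, 2] <- X[, 2] + 1.5 * y
  fit <- fit_stepwise_lda(X, y, lda_fit_config(f_enter = 1e-9))
  m <- MASS::lda(X, grouping = factor(y), prior = c(0.5, 0.5))
  expect_identical(predict(fit, X)$class,
                   as.integer(as.character(predict(m, X)$class)))
})

test_that("models survive a JSON round trip", {
  set.seed(31)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  X[, 1] <- X[, 1] + 1.5 * y
  fit <- fit_stepwise_lda(X, y, lda_fit_config(f_enter = 0.5))
  path <- withr::local_tempfile(fileext = ".json")
  write_stepwise_lda(fit, path)
  back <- read_stepwise_lda(path)
  expect_identical(back$selected, fit$selected)
  expect_identical(predict(back, X)$class, predict(fit, X)$class)
  expect_equal(predict(back, X)$p_positive, predict(fit, X)$p_positive,
               tolerance = 1e-12)
})
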