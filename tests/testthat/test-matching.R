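test_that("the probit propensity model matches closed forms and a Newton oracle", {
  # intercept-only: fitted probability equals the treated share
  d <- tibble::tibble(tr = rep(c(1, 0), c(30, 70)), z = 0)
  pm <- fit_propensity(d, "tr", covariates = character(0))
  expect_equal(unique(round(pm$fitted_probabilities, 10)), 0.3,
               tolerance = 1e-8)

  # tiny dataset: coefficients equal an independent Newton iteration on
  # the probit log-likelihood
  d6 <- tibble::tibble(
    tr = c(0, 1, 0, 1, 0, 1),
    x = c(-1.2, -0.4, 0.3, 0.1, 0.8, 1.5)
  )
  pm6 <- fit_propensity(d6, "tr", covariates = "x")

  newton_probit <- function(y, X, iter = 200) {
    b <- rep(0, ncol(X))
    for (i in seq_len(iter)) {
      eta <- as.vector(X %*% b)
      p <- pnorm(eta)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      lam <- dnorm(eta) * (y - p) / (p * (1 - p))
      W <- dnorm(eta)^2 / (p * (1 - p))
      step <- solve(crossprod(X, W * X), crossprod(X, lam))
      b <- b + as.vector(step)
      if (max(abs(step)) < 1e-12) break
    }
    b
  }
  X <- cbind(1, d6$x)
  expect_equal(unname(pm6$coefs), newton_probit(d6$tr, X), tolerance = 1e-6)

  # missing covariates gain exactly one indicator column each
  set.seed(3)
  dm <- tibble::tibble(tr = rbinom(100, 1, 0.4), a = rnorm(100),
                       b = rnorm(100))
  dm$a[1:20] <- NA
  pm_m <- fit_propensity(dm, "tr", covariates = c("a", "b"))
  expect_identical(pm_m$indicator_columns, "a_missing")
  expect_true("a_missing" %in% names(pm_m$coefs))

  expect_error(fit_propensity(dplyr::mutate(dm, tr = 1), "tr", "a"),
               "Both treated and control")
})

test_that("common support drops treated outside the closed control range", {
  p <- c(0.2, 0.9, 0.1, 0.8)
  tr <- c(1, 1, 0, 0)
  expect_identical(trim_common_support(p, tr), c(TRUE, FALSE, TRUE, TRUE))
  # all treated inside: nothing dropped
  expect_true(all(trim_common_support(c(0.3, 0.5, 0.1, 0.8),
                                      c(1, 1, 0, 0))))
  # boundary: treated equal to the control maximum is retained
  expect_true(all(trim_common_support(c(0.8, 0.1, 0.8),
                                      c(1, 0, 0))))
  expect_error(trim_common_support(c(0.5), c(1)), "No control")
})

test_that("kernel weights reproduce hand-computed Epanechnikov values", {
  # one control in range: weight 1
  mw1 <- kernel_match_weights(c(0.5, 0.52), c(1, 0), bandwidth = 0.06,
                              on_support = c(TRUE, TRUE), keep_pairs = TRUE)
  expect_equal(mw1$pairs$weight, 1)

  # two equidistant controls: weights (1/2, 1/2)
  mw2 <- kernel_match_weights(c(0.5, 0.48, 0.52), c(1, 0, 0),
                              bandwidth = 0.06, keep_pairs = TRUE)
  expect_equal(sort(mw2$pairs$weight), c(0.5, 0.5))

  # controls at (0.50, 0.53, 0.58), b = 0.06:
  # kernel values (0.75, 0.5625, 0) -> weights (0.571428..., 0.428571..., 0)
  mw3 <- kernel_match_weights(c(0.5, 0.5, 0.53, 0.58), c(1, 0, 0, 0),
                              bandwidth = 0.06, keep_pairs = TRUE)
  w3 <- mw3$observations$weight[2:4]
  expect_equal(w3, c(0.75, 0.5625, 0) / (0.75 + 0.5625), tolerance = 1e-12)
  expect_equal(w3[1:2], c(0.5714286, 0.4285714), tolerance = 1e-6)

  # a treated unit with no kernel mass goes off support
  mw4 <- kernel_match_weights(c(0.9, 0.1), c(1, 0), bandwidth = 0.06,
                              on_support = c(TRUE, TRUE))
  expect_false(mw4$observations$on_support[1])

  # a stratum without controls flags its treated off support
  expect_warning(
    mw5 <- kernel_match_weights(c(0.5, 0.5), c(1, 0),
                                strata = c("a", "b"), bandwidth = 0.06,
                                on_support = c(TRUE, TRUE)),
    "no controls")
  expect_false(mw5$observations$on_support[1])

  expect_error(kernel_match_weights(c(0.5, 0.5), c(1, 0), bandwidth = 0),
               "positive")
})

test_that("kernel weights normalize, respect strata, and are shift-equivariant", {
  set.seed(21)
  n <- 600
  p <- runif(n, 0.05, 0.6)
  tr <- rbinom(n, 1, 0.2)
  strata <- sample(c("2000_0", "2000_1", "2002_0"), n, replace = TRUE)
  mw <- kernel_match_weights(p, tr, strata = strata, bandwidth = 0.06,
                             keep_pairs = TRUE)

  # per-treated weights sum to one
  sums <- tapply(mw$pairs$weight, mw$pairs$treated_index, sum)
  expect_true(all(abs(sums - 1) < 1e-10))
  expect_true(all(mw$pairs$weight >= 0))

  # exact matching: no weight crosses a stratum boundary
  expect_true(all(strata[mw$pairs$treated_index] ==
                    strata[mw$pairs$control_index]))

  # aggregated control weights equal the pair sums
  agg <- tapply(mw$pairs$weight, mw$pairs$control_index, sum)
  idx <- as.integer(names(agg))
  expect_equal(unname(mw$observations$weight[idx]), unname(c(agg)),
               tolerance = 1e-12)

  # off-support treated carry no weight
  expect_true(all(mw$observations$weight[
    mw$observations$treated == 1 & !mw$observations$on_support] == 0))

  # shifting every propensity by a constant leaves weights unchanged
  mw_shift <- kernel_match_weights(p + 0.2, tr, strata = strata,
                                   bandwidth = 0.06, keep_pairs = TRUE,
                                   on_support = mw$observations$on_support)
  expect_equal(mw_shift$observations$weight, mw$observations$weight,
               tolerance = 1e-12)
})

test_that("standardized bias matches hand calculations", {
  # equal means
  x <- c(1, 2, 3, 1, 2, 3)
  expect_equal(standardized_bias(x, c(1, 1, 1, 0, 0, 0)), 0)

  # mean difference 1 with both variances 2: 100 / sqrt(2)
  set.seed(4)
  xt <- rnorm(50000, 1, sqrt(2))
  xc <- rnorm(50000, 0, sqrt(2))
  sb <- standardized_bias(c(xt, xc), rep(c(1, 0), each = 50000))
  expect_equal(sb, 100 / sqrt(2), tolerance = 1)

  # binary covariate at 0.54 vs 0.56 with Bernoulli variances:
  # 100 * (-0.02) / sqrt((0.54*0.46 + 0.56*0.44) / 2) = -4.02
  x_bin <- c(rep(1, 54), rep(0, 46), rep(1, 56), rep(0, 44))
  tr_bin <- rep(c(1, 0), each = 100)
  hand <- 100 * (0.54 - 0.56) /
    sqrt((0.54 * 0.46 * 100 / 99 + 0.56 * 0.44 * 100 / 99) / 2)
  expect_equal(standardized_bias(x_bin, tr_bin), hand, tolerance = 1e-10)
  expect_equal(standardized_bias(x_bin, tr_bin), -4.0, tolerance = 0.05)

  # zero pooled variance is undefined
  expect_true(is.na(standardized_bias(rep(1, 6), c(1, 1, 1, 0, 0, 0))))
})

test_that("the balance table collapses to the unmatched rows under flat weights", {
  set.seed(5)
  n <- 400
  d <- tibble::tibble(tr = rbinom(n, 1, 0.3), x = rnorm(n),
                      b = rbinom(n, 1, 0.4))
  bal <- balance_table(d, "tr", c("x", "b"), weights = rep(1, n))
  for (v in c("x", "b")) {
    u <- bal[bal$covariate == v & bal$sample == "unmatched", ]
    m <- bal[bal$covariate == v & bal$sample == "matched", ]
    expect_equal(m$mean_control, u$mean_control, tolerance = 1e-10)
    expect_equal(m$std_bias, u$std_bias, tolerance = 1e-10)
  }
  # binary covariates carry no variance ratio
  expect_true(all(is.na(bal$variance_ratio[bal$covariate == "b"])))
  expect_error(balance_table(d, "tr", "nope"), "not found")
})
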