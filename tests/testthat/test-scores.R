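test_that("polygenic scores are allele-aligned weighted dosage sums", {
  g <- make_genotypes(matrix(c(1, 2), nrow = 1),
                      effect_allele = c("A", "A"),
                      other_allele = c("G", "G"))
  # all-zero weights
  w0 <- tibble::tibble(variant_id = c("v001", "v002"),
                       effect_allele = c("A", "A"), weight = c(0, 0))
  expect_equal(compute_pgs(g, w0)$raw_score, 0)

  # one aligned variant, weight 1, dosage 2
  w1 <- tibble::tibble(variant_id = "v002", effect_allele = "A", weight = 1)
  expect_equal(compute_pgs(g, w1)$raw_score, 2)

  # flip rule: second variant weighted on the non-effect allele
  # 0.5 * 1 + (-1.0) * (2 - 2) = 0.5
  w2 <- tibble::tibble(variant_id = c("v001", "v002"),
                       effect_allele = c("A", "G"),
                       weight = c(0.5, -1.0))
  expect_equal(compute_pgs(g, w2)$raw_score, 0.5)

  # irreconcilable alleles are skipped with a warning and counted
  w3 <- tibble::tibble(variant_id = c("v001", "v002"),
                       effect_allele = c("A", "T"),
                       weight = c(0.5, -1.0))
  expect_warning(s3 <- compute_pgs(g, w3), "neither")
  expect_equal(s3$raw_score, 0.5)
  expect_equal(attr(s3, "scoring_report")$n_skipped_allele, 1L)

  # zero shared variants is an error
  w4 <- tibble::tibble(variant_id = "nope", effect_allele = "A", weight = 1)
  expect_error(compute_pgs(g, w4), "shared")

  # unmatched weight-table variants are counted
  w5 <- tibble::tibble(variant_id = c("v001", "zzz"),
                       effect_allele = c("A", "A"), weight = c(1, 1))
  s5 <- compute_pgs(g, w5)
  expect_equal(attr(s5, "scoring_report")$n_skipped_unmatched, 1L)
})

test_that("scoring is invariant to variant order and allele representation", {
  set.seed(42)
  n <- 50; m <- 10
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  g <- make_genotypes(dos, effect_allele = rep("A", m),
                      other_allele = rep("C", m))
  w <- tibble::tibble(variant_id = sprintf("v%03d", 1:m),
                      effect_allele = rep("A", m),
                      weight = rnorm(m))
  base <- compute_pgs(g, w)$raw_score

  # permuted weight rows
  perm <- sample(m)
  expect_equal(compute_pgs(g, w[perm, ])$raw_score, base, tolerance = 1e-12)

  # flip every variant to the other allele representation:
  # dosage x -> 2 - x, effect/other swapped; scores must be identical
  g_flip <- make_genotypes(2 - dos, effect_allele = rep("C", m),
                           other_allele = rep("A", m))
  expect_equal(compute_pgs(g_flip, w)$raw_score, base, tolerance = 1e-12)
})

test_that("standardization is an exact z-transform and idempotent", {
  expect_equal(standardize_score(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize_score(rep(2, 5)), "zero")
  set.seed(7)
  x <- rnorm(100, 5, 3)
  z <- standardize_score(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 1e-10)
  expect_equal(standardize_score(z), z, tolerance = 1e-12)
})

test_that("greedy clumping keeps the most significant variant per LD block", {
  w <- tibble::tibble(
    variant_id = c("a", "b"),
    effect_allele = c("A", "A"),
    weight = c(0.1, 0.2),
    p_value = c(1e-8, 1e-4),
    chr = c(1, 1),
    pos = c(100000, 200000)
  )
  r2_hi <- tibble::tibble(id_a = "a", id_b = "b", r2 = 0.5)
  r2_lo <- tibble::tibble(id_a = "a", id_b = "b", r2 = 0.05)

  # correlated within window: only the smaller p survives
  kept <- greedy_clump(w, r2_hi, r2_threshold = 0.1, window_kb = 1000)
  expect_equal(kept$variant_id, "a")
  # below the r2 threshold: both kept
  expect_equal(nrow(greedy_clump(w, r2_lo, 0.1, 1000)), 2)
  # outside the window: both kept
  w_far <- dplyr::mutate(w, pos = c(100000, 2100000))
  expect_equal(nrow(greedy_clump(w_far, r2_hi, 0.1, 1000)), 2)
  # missing p/position is an error
  expect_error(greedy_clump(dplyr::select(w, -p_value), r2_hi), "p_value")
})

test_that("clumping output does not depend on input row order", {
  set.seed(11)
  m <- 20
  w <- tibble::tibble(
    variant_id = sprintf("s%02d", 1:m),
    effect_allele = "A",
    weight = rnorm(m),
    p_value = runif(m),
    chr = sample(1:2, m, replace = TRUE),
    pos = sample(1e5:2e6, m)
  )
  pairs <- t(utils::combn(m, 2))
  r2 <- tibble::tibble(id_a = w$variant_id[pairs[, 1]],
                       id_b = w$variant_id[pairs[, 2]],
                       r2 = runif(nrow(pairs)))
  base <- greedy_clump(w, r2, 0.2, 500)
  for (k in 1:5) {
    shuf <- greedy_clump(w[sample(m), ], r2, 0.2, 500)
    expect_identical(shuf$variant_id, base$variant_id)
  }
})

test_that("growth-curve validation recovers a planned incremental R-squared", {
  build_panel <- function(n, slope, noise_sd, e_sd, seed) {
    set.seed(seed)
    mpgs <- rnorm(n)
    sex <- rbinom(n, 1, 0.5)
    intercept <- slope * mpgs + rnorm(n, 0, noise_sd)
    waves <- 5
    panel <- tidyr::expand_grid(i = seq_len(n), wave = seq_len(waves))
    panel$person_id <- sprintf("p%05d", panel$i)
    panel$age <- 55 + 2 * (panel$wave - 1) + runif(nrow(panel), -0.5, 0.5)
    age_c <- panel$age - mean(panel$age)
    panel$bmi <- intercept[panel$i] + 0.1 * age_c - 0.01 * age_c^2 +
      rnorm(nrow(panel), 0, e_sd)
    panel$sex <- sex[panel$i]
    scores <- tibble::tibble(person_id = sprintf("p%05d", seq_len(n)),
                             mpgs = mpgs)
    list(panel = panel, scores = scores)
  }

  # planned R^2 = var(0.3 mpgs) / total = 0.09 / (0.09/0.07) -> noise var
  noise_sd <- sqrt(0.09 / 0.07 - 0.09)
  d <- build_panel(5000, 0.3, noise_sd, e_sd = 0.1, seed = 3)
  val <- validate_mpgs_growth_curve(d$panel, d$scores, covariates = "sex")
  expect_lt(abs(val$incremental_r2 - 0.07), 0.015)
  expect_equal(val$n_excluded, 0)

  # score unrelated to BMI: negligible incremental R^2
  d0 <- build_panel(5000, 0, 1, e_sd = 0.1, seed = 4)
  val0 <- validate_mpgs_growth_curve(d0$panel, d0$scores, covariates = "sex")
  expect_lt(val0$incremental_r2, 0.01)

  # no residual noise at all: R^2 -> 1
  d1 <- build_panel(500, 0.3, 0, e_sd = 0, seed = 5)
  val1 <- suppressWarnings(validate_mpgs_growth_curve(d1$panel, d1$scores))
  expect_gt(val1$r2_full, 0.999)

  # persons with < 3 waves are excluded and counted
  short <- d$panel[d$panel$wave <= 2 | d$panel$i > 10, ]
  val2 <- validate_mpgs_growth_curve(short, d$scores, covariates = "sex")
  expect_equal(val2$n_excluded, 10)
})
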