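test_that("genotype dosages follow Binomial(2, maf) and Hardy-Weinberg", {
  cfg <- sim_config(n_individuals = 4, n_variants = 2, n_mean_causal = 0,
                    n_var_causal = 0, maf_range = c(0.5, 0.5), seed = 3)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosages %in% 0:2))
  expect_equal(dim(g$dosages), c(4, 2))
  expect_false(anyDuplicated(g$variant_ids) > 0)

  cfg <- sim_config(n_individuals = 20000, n_variants = 1, n_mean_causal = 0,
                    n_var_causal = 0, maf_range = c(0.3, 0.3), seed = 11)
  g <- simulate_genotypes(cfg)
  freq <- mean(g$dosages) / 2
  se <- sqrt(0.3 * 0.7 / (2 * 20000))
  expect_lt(abs(freq - 0.3), 3 * se)

  # genotype class counts vs the HWE expectation (0.49, 0.42, 0.09)
  counts <- tabulate(g$dosages[, 1] + 1, nbins = 3)
  hwe <- c((1 - 0.3)^2, 2 * 0.3 * 0.7, 0.3^2)
  chi <- suppressWarnings(stats::chisq.test(counts, p = hwe))
  expect_gt(chi$p.value, 0.001)

  # reproducible under a fixed seed
  g2 <- simulate_genotypes(cfg)
  expect_identical(g$dosages, g2$dosages)

  expect_error(sim_config(n_individuals = 0), "positive")
  expect_error(sim_config(n_waves = 1), "at least 2")
  expect_error(sim_config(maf_range = c(0, 0.5)), "inside")
})

test_that("phenotype has the planted mean and log-linear variance structure", {
  n <- 20000
  cfg <- sim_config(n_individuals = n, n_variants = 1, n_mean_causal = 0,
                    n_var_causal = 0, seed = 5)

  # null architecture: standard normal residuals
  set.seed(1)
  dos <- matrix(rbinom(n, 2, 0.5), ncol = 1)
  g <- make_genotypes(dos)
  tr <- make_truth(mean_betas = 0, var_alphas = 0)
  y <- simulate_phenotype(g, tr, cfg)$phenotype
  expect_lt(abs(var(y) - 1), 3 * sqrt(2 / n))

  # single variance variant, alpha = 0.5: var ratio dosage-2 vs dosage-0
  # has closed form exp(2 * 0.5) = e
  tr <- make_truth(mean_betas = 0, var_alphas = 0.5)
  y <- simulate_phenotype(g, tr, cfg)$phenotype
  v2 <- var(y[dos == 2]); n2 <- sum(dos == 2)
  v0 <- var(y[dos == 0]); n0 <- sum(dos == 0)
  log_se <- sqrt(2 / n2 + 2 / n0)
  expect_lt(abs(log(v2 / v0) - 1), 3 * log_se)

  # single mean variant, beta = 1: OLS recovers the slope
  tr <- make_truth(mean_betas = 1, var_alphas = 0)
  y <- simulate_phenotype(g, tr, cfg)$phenotype
  fit <- lm(y ~ dos)
  expect_lt(abs(coef(fit)[2] - 1), 3 * summary(fit)$coefficients[2, 2])

  # exp overflow guard
  tr <- make_truth(mean_betas = 0, var_alphas = 60)
  expect_error(simulate_phenotype(g, tr, cfg), "overflow")
})

test_that("treatment assignment is confounded by covariates but never by genotype", {
  cfg0 <- sim_config(n_individuals = 20000, n_variants = 40,
                     confounding_strength = 0, seed = 21)
  g <- simulate_genotypes(cfg0)
  tr <- draw_truth(g, cfg0)
  panel <- simulate_panel(g, tr, cfg0)
  persons <- dplyr::filter(panel, wave == 1)
  expect_true(all(panel$treated[panel$person_id %in%
                                  persons$person_id[persons$treated == 0]] == 0))

  # randomized: every covariate balanced
  for (v in c("log_income", "tenure", "smoker", "sex", "age")) {
    x <- persons[[v]]
    ok <- !is.na(x)
    expect_lt(abs(standardized_bias(x[ok], persons$treated[ok])), 5)
  }
  # realized fraction near target
  expect_lt(abs(mean(persons$treated) - cfg0$treatment_fraction), 0.02)

  # confounded: strong imbalance before matching
  cfg1 <- sim_config(n_individuals = 20000, n_variants = 40, seed = 21)
  panel1 <- simulate_panel(g, tr, cfg1)
  persons1 <- dplyr::filter(panel1, wave == 1)
  sb <- vapply(c("log_income", "tenure", "smoker", "firm_size"), function(v) {
    x <- persons1[[v]]
    ok <- !is.na(x)
    abs(standardized_bias(x[ok], persons1$treated[ok]))
  }, numeric(1))
  expect_gt(max(sb), 10)

  # no gene-environment correlation: scores balanced by construction
  sc <- attr(panel1, "person_scores")
  expect_lt(abs(standardized_bias(sc$mpgs, persons1$treated)), 5)
  expect_lt(abs(standardized_bias(sc$vpgs, persons1$treated)), 5)
})

test_that("panel treatment effects match difference-in-means oracles under randomization", {
  # lambda = 0.5, no interactions: naive DiD on randomized arms
  cfg <- sim_config(n_individuals = 20000, n_variants = 40,
                    confounding_strength = 0, att_mean = 0.5,
                    att_by_mpgs = 0, att_by_vpgs = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  tr <- draw_truth(g, cfg)
  panel <- simulate_panel(g, tr, cfg)
  fr <- build_did_frame(panel)
  d <- fr$bmi - fr$bmi_lag
  tt <- t.test(d[fr$treated == 1], d[fr$treated == 0])
  naive <- unname(diff(rev(tt$estimate)))
  se <- tt$stderr
  expect_lt(abs(naive - 0.5), 3 * se)

  # delta = 0.25: interaction OLS oracle on randomized arms
  cfg <- sim_config(n_individuals = 20000, n_variants = 40,
                    confounding_strength = 0, att_mean = 0,
                    att_by_mpgs = 0, att_by_vpgs = 0.25, seed = 32)
  g <- simulate_genotypes(cfg)
  tr <- draw_truth(g, cfg)
  panel <- simulate_panel(g, tr, cfg)
  fr <- dplyr::left_join(build_did_frame(panel),
                         attr(panel, "person_scores"), by = "person_id")
  fit <- lm(I(bmi - bmi_lag) ~ treated * vpgs, data = fr)
  est <- coef(fit)["treated:vpgs"]
  se <- summary(fit)$coefficients["treated:vpgs", 2]
  expect_lt(abs(est - 0.25), 3 * se)

  # null effects: equal mean change across arms
  cfg <- sim_config(n_individuals = 20000, n_variants = 40,
                    confounding_strength = 0, att_mean = 0,
                    att_by_mpgs = 0, att_by_vpgs = 0, seed = 33)
  panel <- simulate_panel(g, draw_truth(g, cfg), cfg)
  fr <- build_did_frame(panel)
  d <- fr$bmi - fr$bmi_lag
  tt <- t.test(d[fr$treated == 1], d[fr$treated == 0])
  expect_lt(abs(unname(diff(rev(tt$estimate)))), 3 * tt$stderr)
})

test_that("planted variance QTLs are detectable by an independent Levene-type test", {
  n <- 20000
  set.seed(9)
  dos <- matrix(rbinom(n, 2, 0.4), ncol = 1)
  g <- make_genotypes(dos)
  tr <- make_truth(mean_betas = 0, var_alphas = 0.3)
  cfg <- sim_config(n_individuals = n, n_variants = 1, n_mean_causal = 0,
                    n_var_causal = 0, seed = 9)
  y <- simulate_phenotype(g, tr, cfg)$phenotype
  lev <- car::leveneTest(y, factor(dos))
  expect_lt(lev[1, "Pr(>F)"], 0.001)
})

test_that("train/test splits are disjoint, exhaustive and reproducible", {
  ids <- letters[1:10]
  sp <- split_train_test(ids, 0.8, seed = 4)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_train_test(ids, 0.8, seed = 4))
  expect_warning(split_train_test(ids, 1), "empty test set")
  expect_error(split_train_test(ids, 0), "fraction")
})

test_that("every drawn truth parameter is stored exactly as drawn", {
  cfg <- sim_config(n_individuals = 50, n_variants = 12, n_mean_causal = 4,
                    n_var_causal = 4, seed = 17)
  g <- simulate_genotypes(cfg)
  tr <- draw_truth(g, cfg)
  expect_length(tr$mean_betas, 12)
  expect_equal(sum(tr$mean_betas != 0), 4)
  expect_equal(sum(tr$var_alphas != 0), 4)
  # disjoint causal sets by default
  expect_equal(sum(tr$mean_betas != 0 & tr$var_alphas != 0), 0)
  expect_identical(tr, draw_truth(g, cfg))
  expect_equal(unname(tr$true_att_params),
               c(cfg$att_mean, cfg$att_by_mpgs, cfg$att_by_vpgs))
})
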