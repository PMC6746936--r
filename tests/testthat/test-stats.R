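test_that("VIF equals 1/(1-R^2) and is 1 for orthogonal predictors", {
  # orthogonal design: centered sinusoid basis
  n <- 24
  x <- data.frame(a = cos(2 * pi * (1:n) / n), b = sin(2 * pi * (1:n) / n),
                  c = cos(4 * pi * (1:n) / n))
  vf <- vif_filter(x)
  expect_equal(unname(vf$vif), rep(1, 3), tolerance = 1e-10)
  expect_length(vf$removed, 0)

  # constructed pair with sample correlation exactly 0.8
  set.seed(41)
  z1 <- scale(stats::rnorm(40, 0, 1))[, 1]
  z2 <- scale(stats::resid(stats::lm(stats::rnorm(40) ~ z1)))[, 1]
  z1 <- z1 / sqrt(sum(z1^2)); z2 <- z2 / sqrt(sum(z2^2))
  pair <- data.frame(u = z1, v = 0.8 * z1 + sqrt(1 - 0.64) * z2)
  vf2 <- vif_filter(pair, threshold = 10)
  expect_equal(unname(vf2$vif), rep(1 / (1 - 0.64), 2), tolerance = 1e-8)
})

test_that("VIF filtering removes exact duplicates first and is order-invariant", {
  set.seed(2)
  x <- data.frame(a = stats::rnorm(30), b = stats::rnorm(30))
  x$dup <- x$a
  expect_warning(vf <- vif_filter(x), "perfectly collinear")
  expect_true("a" %in% vf$removed || "dup" %in% vf$removed)
  expect_true(all(is.finite(vf$vif)))
  set.seed(3)
  y <- as.data.frame(matrix(stats::rnorm(30 * 6), 30, 6))
  y$V7 <- y$V1 * 0.95 + stats::rnorm(30, 0, 0.05)
  r1 <- suppressWarnings(vif_filter(y))
  r2 <- suppressWarnings(vif_filter(y[, sample(names(y))]))
  expect_setequal(r1$retained, r2$retained)
})

test_that("VIF matches an independent lm-based computation", {
  set.seed(14)
  x <- as.data.frame(matrix(stats::rnorm(40 * 5), 40, 5))
  x$V6 <- 0.6 * x$V1 - 0.5 * x$V2 + stats::rnorm(40, 0, 0.7)
  got <- vif_filter(x, threshold = Inf)$vif
  expect_equal(unname(got), unname(brute_vif(x)), tolerance = 1e-8)
})

test_that("exhaustive AIC ranking matches a brute-force enumeration", {
  set.seed(8)
  for (p in c(3, 5)) {
    x <- as.data.frame(matrix(stats::rnorm(25 * p), 25, p))
    y <- x$V1 + stats::rnorm(25, 0, 0.8)
    rk <- aic_rank(x, y)
    expect_equal(nrow(rk$models), 2^p - 1)
    expect_equal(sum(rk$models$weight), 1, tolerance = 1e-12)
    ref <- brute_aic_rank(x, y)
    got <- stats::setNames(rk$variables$cum_weight, rk$variables$variable)
    expect_equal(got[names(ref)], ref, tolerance = 1e-8)
    # weights follow exp(-delta/2) normalisation exactly
    m <- rk$models
    expect_equal(m$weight[1] / m$weight[2],
                 exp(-(m$aic[1] - m$aic[2]) / 2), tolerance = 1e-12)
  }
  # single-predictor enumeration is the one trivial model
  x1 <- data.frame(only = stats::rnorm(20))
  rk1 <- aic_rank(x1, stats::rnorm(20))
  expect_equal(rk1$models$weight, 1)
  expect_equal(rk1$variables$cum_weight, 1)
  expect_error(aic_rank(as.data.frame(matrix(stats::rnorm(20 * 16), 20)),
                        stats::rnorm(20)), "p > 15")
})

test_that("Spearman correlation handles hand cases and matches cor.test", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  set.seed(4)
  x <- stats::rnorm(25); y <- 0.5 * x + stats::rnorm(25)
  got <- spearman_rho(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  t_ref <- got$rho * sqrt(23 / (1 - got$rho^2))
  expect_equal(got$p, 2 * stats::pt(-abs(t_ref), 23), tolerance = 1e-12)
  perm <- spearman_rho(x[1:8], y[1:8], p_method = "permutation", n_perm = 500)
  expect_true(perm$p > 0 && perm$p <= 1)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("rank_hsa pipelines VIF filtering into the ranking", {
  co <- generate_cohort(24, seed = 77, spacing_mm = 1.0, write_images = FALSE,
                        effect_spec = list(coefficients = c(NSA = 1.2)))
  dat <- cbind(rf_hat = co$truth$rf_hat_true, co$hsa)
  dat$patient_id <- NULL
  rk <- suppressWarnings(rank_hsa(rf_hat ~ ., dat))
  expect_s3_class(rk, "hsa_ranking")
  expect_lte(length(rk$vif$retained), 15)
  expect_true(all(rk$ranking$variables$cum_weight >= 0 &
                    rk$ranking$variables$cum_weight <= 1))
  expect_equal(sum(rk$ranking$models$weight), 1, tolerance = 1e-12)
})
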