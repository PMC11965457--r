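# Hand-built Gaussian dataset helpers (single ROI, explicit truth).
gauss_dataset <- function(n, b0 = 2.8, b1 = -0.005, sigma = 0.15,
                          sites = "siteA", offsets = 0, seed = 1,
                          age_range = c(10, 80), modality = "thickness") {
  set.seed(seed)
  age <- runif(n, age_range[1], age_range[2])
  site <- sample(sites, n, replace = TRUE)
  y <- b0 + b1 * age + offsets[match(site, sites)] + rnorm(n, 0, sigma)
  cov <- data.frame(subject_id = sprintf("g%05d", seq_len(n)), age = age,
                    sex = "M", site = site, group = "REF",
                    stringsAsFactors = FALSE)
  roi_dataset(matrix(y, ncol = 1, dimnames = list(cov$subject_id, "roi1")),
              cov, modality)
}

# Held-out log-likelihood of a fitted model (measurement space).
heldout_loglik <- function(model, data) {
  pr <- normdev:::predict_warped(model, data$covariates,
                                 warn_extrapolation = FALSE)
  y <- data$values[, model$roi]
  z <- warp(y, model$warp)
  sum(stats::dnorm(z, pr$mu, pr$sd, log = TRUE) + warp_log_deriv(y, model$warp))
}

test_that("identity-warp fit equals the closed-form Bayesian ridge solution", {
  for (seed in 1:4) {
    d <- gauss_dataset(150, seed = seed, sites = c("siteA", "siteB"),
                       offsets = c(0, 0.2))
    m <- fit_normative_model(d, "roi1", warp = "identity")
    X <- normdev:::build_design(m$basis, d$covariates, FALSE)
    y <- d$values[, 1]
    # independent closed-form oracle: (X'X + (alpha/beta) I)^-1 X'y
    w_ridge <- solve(crossprod(X) + (m$alpha / m$beta) * diag(ncol(X)),
                     crossprod(X, y))
    expect_lt(max(abs(m$w - drop(w_ridge))), 1e-6)
  }
})

test_that("noiseless linear data is interpolated exactly", {
  set.seed(2)
  age <- runif(200, 10, 80)
  y <- 2 + 0.5 * age
  cov <- data.frame(subject_id = sprintf("s%03d", 1:200), age = age,
                    sex = "M", site = "siteA", group = "REF",
                    stringsAsFactors = FALSE)
  d <- roi_dataset(matrix(y, ncol = 1, dimnames = list(cov$subject_id, "r")),
                   cov, "thickness")
  m <- fit_normative_model(d, "r", warp = "identity")
  pr <- normdev:::predict_warped(m, cov, FALSE)
  expect_lt(max(abs(pr$mu - y)), 1e-6)
})

test_that("the fitted warp beats the identity warp on skewed data", {
  # flat-trajectory construction: the response is location + SHASH noise,
  # the regime in which the warped likelihood is correctly specified
  shash_dataset <- function(n, eps, delta, seed) {
    set.seed(seed)
    age <- runif(n, 10, 80)
    y <- 2.6 - 0.002 * age + 0.15 * sinh((asinh(rnorm(n)) + eps) / delta)
    cov <- data.frame(subject_id = sprintf("w%05d", seq_len(n)), age = age,
                      sex = "M", site = "siteA", group = "REF",
                      stringsAsFactors = FALSE)
    roi_dataset(matrix(y, ncol = 1,
                       dimnames = list(cov$subject_id, "roi1")),
                cov, "thickness")
  }
  wins <- 0L
  n_rep <- 20L
  for (rep in seq_len(n_rep)) {
    tr <- shash_dataset(2000, 0.5, 1.3, seed = 1000 + rep)
    ho <- shash_dataset(400, 0.5, 1.3, seed = 5000 + rep)
    m_warp <- fit_normative_model(tr, "roi1", warp = "shash")
    m_id <- fit_normative_model(tr, "roi1", warp = "identity")
    if (heldout_loglik(m_warp, ho) > heldout_loglik(m_id, ho))
      wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_rep))
})

test_that("Z-scores are calibrated on held-out training-distribution data", {
  spec <- cohort_spec(group_sizes = c("REF" = 1000, "HC" = 5000),
                      dictionary = small_dictionary(5, 0, 0),
                      sites = data.frame(site = c("s1", "s2"),
                                         offset_sd = c(0, 0.25),
                                         scale = c(1, 1.1),
                                         role = "train",
                                         stringsAsFactors = FALSE),
                      seed = 314)
  sim <- simulate_reference_cohort(spec, groups = c("REF", "HC"))
  # both pools share the training sites here
  dat <- sim$data$thickness
  dat$covariates$group[dat$covariates$group == "HC"] <- "HC"
  tr <- subset_group(dat, "REF")
  ho <- subset_group(dat, "HC")
  z <- compute_zscores(fit_normative_models(tr), NULL, ho)$z
  expect_gt(mean(z), -0.05)
  expect_lt(mean(z), 0.05)
  expect_gt(stats::sd(z), 0.95)
  expect_lt(stats::sd(z), 1.05)
})

test_that("site adaptation recovers an injected measurement offset", {
  sigma <- 0.15
  d <- gauss_dataset(800, sigma = sigma, seed = 31)
  m <- fit_normative_model(d, "roi1", warp = "identity")
  calib <- gauss_dataset(200, sigma = sigma, sites = "siteNew",
                         offsets = 0.3, seed = 32)
  ad <- adapt_to_site(m, calib)
  sd_pred <- mean(normdev:::predict_warped(m, calib$covariates, FALSE)$sd)
  # CLT error of the mean residual at n = 200 is about 1/sqrt(200)
  expect_lt(abs(ad$mu - 0.3 / sd_pred), 3 / sqrt(200))
  expect_lt(abs(ad$rho - 1), 0.2)
  expect_equal(ad$n, 200)
})

test_that("null adaptation leaves residual moments near (0, 1)", {
  d <- gauss_dataset(600, seed = 41)
  m <- fit_normative_model(d, "roi1", warp = "identity")
  calib <- gauss_dataset(400, sites = "siteB", offsets = 0, seed = 42)
  ad <- adapt_to_site(m, calib)
  expect_lt(abs(ad$mu), 3 / sqrt(400))
  expect_lt(abs(ad$rho - 1), 0.15)
})

test_that("Z-scores are definitional for constructed observations", {
  d <- gauss_dataset(500, seed = 51)
  m <- fit_normative_model(d, "roi1", warp = "identity")
  cov <- d$covariates[1:20, ]
  pr <- normdev:::predict_warped(m, cov, FALSE)
  vals <- matrix(pr$mu + 2 * pr$sd, ncol = 1,
                 dimnames = list(cov$subject_id, "roi1"))
  ds <- roi_dataset(vals, cov, "thickness")
  z <- compute_zscores(m, NULL, ds)$z
  expect_equal(unname(z[, 1]), rep(2, 20), tolerance = 1e-10)
})

test_that("scoring an uncalibrated site directs the user to adapt_to_site", {
  d <- gauss_dataset(300, seed = 61)
  m <- fit_normative_model(d, "roi1", warp = "identity")
  new <- gauss_dataset(30, sites = "siteX", seed = 62)
  expect_error(compute_zscores(m, NULL, new), "adapt_to_site")
})

test_that("ages outside the training range extrapolate with a warning", {
  d <- gauss_dataset(300, age_range = c(20, 60), seed = 63)
  m <- fit_normative_model(d, "roi1", warp = "identity")
  old <- gauss_dataset(10, age_range = c(70, 80), seed = 64)
  expect_warning(compute_zscores(m, NULL, old), "extrapolating")
})

test_that("centiles are monotone, symmetric at the median, and calibrated", {
  spec <- cohort_spec(group_sizes = c("REF" = 2000, "HC" = 5000),
                      dictionary = small_dictionary(1, 0, 0),
                      sites = one_site(),
                      noise = list(epsilon = 0, delta = 1), seed = 71)
  sim <- simulate_reference_cohort(spec, groups = c("REF", "HC"))
  tr <- subset_group(sim$data$thickness, "REF")
  ho <- subset_group(sim$data$thickness, "HC")
  m <- fit_normative_model(tr, tr$roi_names[1], warp = "identity")

  ages <- seq(10, 85, by = 5)
  cent <- predict_centiles(m, NULL, ages, probs = c(0.025, 0.5, 0.975))
  pr <- normdev:::predict_warped(m, data.frame(age = ages, site = "siteA"),
                                 FALSE)
  expect_equal(cent$value[cent$prob == 0.5], pr$mu, tolerance = 1e-10)
  lo <- cent$value[cent$prob == 0.025]
  hi <- cent$value[cent$prob == 0.975]
  expect_true(all(hi - lo > 0))

  band <- predict_centiles(m, NULL, ho$covariates$age,
                           probs = c(0.025, 0.975))
  lo <- band$value[band$prob == 0.025][seq_len(nrow(ho$values))]
  hi <- band$value[band$prob == 0.975][seq_len(nrow(ho$values))]
  y <- ho$values[, 1]
  coverage <- mean(y > lo & y < hi)
  expect_gt(coverage, 0.94)
  expect_lt(coverage, 0.96)

  expect_error(predict_centiles(m, NULL, ages, probs = numeric(0)), "probs")
})

test_that("model store round-trips bit-identically through JSON", {
  spec <- small_spec(group_sizes = c("REF" = 300, "CALIB" = 60, "HC" = 40),
                     seed = 81)
  sim <- simulate_reference_cohort(spec, groups = c("REF", "CALIB", "HC"))
  d <- sim$data$area
  tr <- subset_group(d, "REF")
  cal <- subset_group(d, "CALIB")
  ho <- subset_group(d, "HC")
  ms <- fit_normative_models(tr)
  ad <- adapt_to_site(ms, cal)
  z1 <- compute_zscores(ms, ad, ho)

  dir <- withr::local_tempdir()
  save_models(ms, dir, adaptation = ad)
  loaded <- load_models(dir)
  z2 <- compute_zscores(loaded$models, loaded$adaptation, ho)
  expect_identical(z1$z, z2$z)
})

test_that("degenerate bases and inputs raise informative errors", {
  d <- gauss_dataset(100, seed = 91)
  expect_error(fit_normative_model(d, "roi1", basis_spec(linear = TRUE)),
               "collinear")
  expect_error(fit_normative_model(d, "nope"), "not in dataset")
  tiny <- gauss_dataset(15, seed = 92)
  expect_error(fit_normative_model(tiny, "roi1"), "training subjects")
  calib_small <- gauss_dataset(5, sites = "siteC", seed = 93)
  m <- fit_normative_model(d, "roi1", warp = "identity")
  expect_error(adapt_to_site(m, calib_small), "at least 10")
})
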