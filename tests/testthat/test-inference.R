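# Small clinical-style covariate tables built in code.
toy_people <- function(n, age, site = "s1", group = "G",
                       prefix = "p") {
  data.frame(subject_id = sprintf("%s%03d", prefix, seq_len(n)),
             age = age, site = site, group = group,
             stringsAsFactors = FALSE)
}

test_that("matching is 1:1 without reuse and follows propensity order", {
  cases <- toy_people(3, c(50, 40, 30), prefix = "c")
  controls <- toy_people(5, c(49, 41, 31, 10, 5), prefix = "k")
  mr <- propensity_match(cases, controls)
  expect_equal(nrow(mr$pairs), 3)
  expect_equal(anyDuplicated(mr$pairs$control_id), 0L)
  # hand-worked greedy solution on the age-monotone propensity
  expect_equal(mr$pairs$control_id[match(c("c001", "c002", "c003"),
                                         mr$pairs$case_id)],
               c("k001", "k002", "k003"))
})

test_that("identical covariates give zero matching distance", {
  cases <- toy_people(4, c(30, 35, 40, 45), prefix = "c")
  controls <- toy_people(6, c(30, 35, 40, 45, 30, 35), prefix = "k")
  mr <- propensity_match(cases, controls)
  expect_lt(max(mr$pairs$distance), 1e-8)
})

test_that("matching repairs a strong age imbalance", {
  set.seed(6)
  cases <- toy_people(40, rnorm(40, 52, 5), prefix = "c")
  controls <- toy_people(200, c(rnorm(100, 52, 5), rnorm(100, 30, 5)),
                         prefix = "k")
  mr <- propensity_match(cases, controls)
  pre <- abs(mr$balance$smd_pre[mr$balance$covariate == "age"])
  post <- abs(mr$balance$smd_post[mr$balance$covariate == "age"])
  expect_gt(pre, 0.5)
  expect_lt(post, 0.1)
})

test_that("complete separation falls back with a warning", {
  cases <- toy_people(10, seq(70, 79), prefix = "c")
  controls <- toy_people(20, seq(20, 39), prefix = "k")
  expect_warning(mr <- propensity_match(cases, controls), "separat")
  expect_equal(nrow(mr$pairs), 10)
})

test_that("matching preconditions are enforced", {
  cases <- toy_people(5, 30:34, prefix = "c")
  expect_error(propensity_match(cases, toy_people(3, 30:32, prefix = "k")),
               "at least as many controls")
  off_site <- toy_people(6, 30:35, site = "elsewhere", prefix = "k")
  expect_error(propensity_match(cases, off_site), "site overlap")
})

test_that("exact permutation p equals the brute-force enumeration", {
  set.seed(11)
  y <- c(1.2, 0.4, -0.3, 2.1, 0.9, -1.5)
  g <- c(1, 1, 1, 0, 0, 0)
  X <- cbind(group = g - mean(g))
  res <- permutation_glm(y, X, "group", exact = TRUE)
  expect_equal(res$n_perm, 720L)

  # independent oracle: all 2^6 label vectors with three 1s, statistic =
  # absolute difference in group means (monotone in |t| at fixed sizes)
  md_obs <- abs(mean(y[g == 1]) - mean(y[g == 0]))
  hits <- 0L; total <- 0L
  for (bits in 0:63) {
    lab <- as.integer(intToBits(bits))[1:6]
    if (sum(lab) != 3) next
    total <- total + 1L
    md <- abs(mean(y[lab == 1]) - mean(y[lab == 0]))
    if (md >= md_obs - 1e-12) hits <- hits + 1L
  }
  expect_equal(res$p, hits / total)

  # and the t statistic matches the classic equal-variance two-sample t
  tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)$statistic
  expect_equal(res$t, unname(tt), tolerance = 1e-10)
  expect_equal(res$df, 4)
})

test_that("constant outcomes give t = 0 and p = 1", {
  y <- rep(3.2, 8)
  X <- cbind(group = rep(c(0.5, -0.5), each = 4))
  res <- permutation_glm(y, X, "group", exact = TRUE)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})

test_that("permutation p is reproducible and respects Freedman-Lane nuisance", {
  set.seed(21)
  n <- 40
  age <- runif(n, 20, 60)
  y <- 0.05 * age + rnorm(n)
  g <- rep(c(1, 0), each = n / 2)
  X <- cbind(group = g - mean(g), age = age - mean(age))
  r1 <- permutation_glm(y, X, "group", n_perm = 500, seed = 7)
  r2 <- permutation_glm(y, X, "group", n_perm = 500, seed = 7)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$t, r2$t)
  # t equals lm's t for the group coefficient with intercept
  fit <- summary(lm(y ~ g + age))
  expect_equal(r1$t, fit$coefficients["g", "t value"], tolerance = 1e-10)

  dup <- cbind(X, again = X[, "group"])
  expect_error(permutation_glm(y, dup, "group"), "collinear")
  expect_error(permutation_glm(y, X, "group", n_perm = 50), "n_perm")
})

test_that("cohens_d follows the committed convention", {
  expect_equal(cohens_d(0, 10, 12), 0)
  expect_equal(cohens_d(2, 50, 50), 0.4)
  # classic two-sample check: d = (m1 - m2) / pooled sd
  set.seed(31)
  a <- rnorm(30, 0.5); b <- rnorm(25)
  X <- cbind(group = c(rep(1, 30), rep(0, 25)))
  X[, 1] <- X[, 1] - mean(X[, 1])
  res <- permutation_glm(c(a, b), X, "group", n_perm = 100, seed = 1)
  sp <- sqrt(((30 - 1) * var(a) + (25 - 1) * var(b)) / (30 + 25 - 2))
  expect_equal(cohens_d(res$t, 30, 25), (mean(a) - mean(b)) / sp,
               tolerance = 1e-10)
})

test_that("BH correction matches the step-up procedure by hand", {
  expect_equal(correct_multiplicity(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(correct_multiplicity(0.037), 0.037)
  expect_error(correct_multiplicity(numeric(0)), "empty")
  expect_error(correct_multiplicity(c(0.1, 0.2), method = "westfall_young"),
               "t_obs")
})

test_that("burden permutation test is exact on the 4v4 enumeration", {
  counts <- c(9, 7, 6, 8, 2, 3, 1, 4)
  groups <- rep(c("P", "H"), each = 4)
  res <- burden_permutation_test(counts, groups, "P", "H",
                                 direction = "greater", exact = TRUE)
  expect_equal(res$n_perm, 70)
  stat_obs <- mean(counts[1:4]) - mean(counts[5:8])
  hits <- 0L; total <- 0L
  for (bits in 0:255) {
    lab <- as.integer(intToBits(bits))[1:8]
    if (sum(lab) != 4) next
    total <- total + 1L
    if (mean(counts[lab == 1]) - mean(counts[lab == 0]) >= stat_obs - 1e-12)
      hits <- hits + 1L
  }
  expect_equal(total, 70L)
  expect_equal(res$p, hits / total)
})

test_that("degenerate and reproducible burden tests behave as documented", {
  expect_warning(
    res <- burden_permutation_test(rep(2, 10), rep(c("A", "B"), 5),
                                   "A", "B"),
    "equal")
  expect_equal(res$p, 1)
  set.seed(41)
  counts <- rpois(30, 3)
  groups <- rep(c("A", "B"), 15)
  r1 <- burden_permutation_test(counts, groups, "A", "B", n_perm = 300,
                                seed = 5)
  r2 <- burden_permutation_test(counts, groups, "A", "B", n_perm = 300,
                                seed = 5)
  expect_identical(r1$p, r2$p)
})

test_that("group GLM returns the full schema with monotone correction tiers", {
  set.seed(51)
  n <- 60
  cov <- toy_people(n, runif(n, 20, 60), group = rep(c("SSD-V", "HC"),
                                                     each = n / 2))
  cov$icv_mm3 <- rnorm(n, 1.5e6, 1e5)
  z <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(cov$subject_id, c("r1", "r2", "r3")))
  z[cov$group == "SSD-V", "r2"] <- z[cov$group == "SSD-V", "r2"] - 1.5
  devs <- list(thickness = deviation_matrix(z, "thickness"),
               area = deviation_matrix(z + rnorm(n * 3, 0, 0.1), "area"))
  contrasts <- data.frame(group_a = "SSD-V", group_b = "HC",
                          alternative = "two.sided")
  res <- run_group_glm(devs, cov, contrasts, n_perm = 200, seed = 3)
  expect_setequal(names(res),
                  c("modality", "roi", "contrast", "n_a", "n_b", "t",
                    "cohens_d", "p_unc", "p_fwe_roi", "p_fwe_roi_contrast",
                    "p_fwe_roi_contrast_modality", "n_perm", "seed"))
  expect_equal(nrow(res), 6)
  expect_true(all(res$p_unc > 0 & res$p_unc <= 1))
  expect_true(all(res$p_fwe_roi >= res$p_unc))
  expect_true(all(res$p_fwe_roi_contrast >= res$p_fwe_roi))
  expect_true(all(res$p_fwe_roi_contrast_modality >= res$p_fwe_roi_contrast))
  hit <- res[res$modality == "thickness" & res$roi == "r2", ]
  expect_lt(hit$p_unc, 0.05)
  expect_lt(hit$t, 0)
  expect_equal(hit$cohens_d, cohens_d(hit$t, 30, 30))

  res2 <- run_group_glm(devs, cov, contrasts, n_perm = 200, seed = 3)
  expect_identical(res, res2)

  wy <- run_group_glm(devs, cov, contrasts, n_perm = 200, seed = 3,
                      correction = "westfall_young")
  expect_true(all(wy$p_fwe_roi >= wy$p_unc))
  expect_lt(wy[wy$modality == "thickness" & wy$roi == "r2", "p_fwe_roi"],
            0.05)
})

test_that("matched contrasts restrict to the matched pairs", {
  set.seed(61)
  n_case <- 15; n_hc <- 60
  cov <- rbind(toy_people(n_case, runif(n_case, 40, 60), group = "SSD-V",
                          prefix = "c"),
               toy_people(n_hc, runif(n_hc, 20, 60), group = "HC",
                          prefix = "k"))
  z <- matrix(rnorm(nrow(cov) * 2), nrow(cov), 2,
              dimnames = list(cov$subject_id, c("r1", "r2")))
  devs <- list(thickness = deviation_matrix(z, "thickness"))
  mr <- propensity_match(cov[cov$group == "SSD-V", ],
                         cov[cov$group == "HC", ])
  res <- run_group_glm(devs, cov,
                       data.frame(group_a = "SSD-V", group_b = "HC",
                                  alternative = "two.sided"),
                       matching = list("SSD-V_vs_HC" = mr),
                       n_perm = 150, seed = 1)
  expect_equal(unique(res$n_a), n_case)
  expect_equal(unique(res$n_b), n_case)
})

test_that("trait association is null-uniform under a shuffled trait", {
  set.seed(71)
  n <- 58; R <- 100
  cov <- toy_people(n, runif(n, 20, 60),
                    group = rep(c("SSD-V", "nonSSD-V"), c(38, 20)))
  cov$pclr_total <- sample(pmin(40, pmax(0, rnorm(n, 20, 8))))
  cov$icv_mm3 <- rnorm(n, 1.5e6, 1e5)
  z <- matrix(rnorm(n * R), n, R,
              dimnames = list(cov$subject_id, sprintf("r%03d", 1:R)))
  devs <- list(thickness = deviation_matrix(z, "thickness"))
  res <- trait_association(devs, cov, n_perm = 500, seed = 9)
  expect_equal(nrow(res), R)
  # permutation p-values are discrete (granularity 1/(n_perm+1)), hence
  # the suppressed KS ties warning
  expect_gt(suppressWarnings(stats::ks.test(res$p_unc, "punif"))$p.value,
            0.01)
})

test_that("trait association includes ICV only for head-size modalities", {
  set.seed(81)
  n <- 40
  cov <- toy_people(n, runif(n, 20, 60), group = "SSD-V")
  cov$pclr_total <- rnorm(n, 20, 8)
  cov$icv_mm3 <- NA_real_
  z <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(cov$subject_id, c("r1", "r2")))
  # thickness ignores ICV entirely, so missing ICV is no obstacle ...
  res <- trait_association(list(thickness = deviation_matrix(z, "thickness")),
                           cov, n_perm = 150, seed = 2)
  expect_equal(nrow(res), 2)
  # ... while area requires it and refuses when nobody has it
  expect_error(trait_association(list(area = deviation_matrix(z, "area")),
                                 cov, n_perm = 150, seed = 2),
               "at least 10")
})
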