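#' Propensity-score matching of cases to controls
#'
#' Matches each case to one control (1:1, without replacement) on
#' logistic-regression distance: case membership is modelled on age and
#' site indicators, cases are processed in descending propensity order,
#' and each takes the nearest unused control on the linear predictor.
#' Under complete separation of the logistic fit the distance falls back
#' to standardized covariates, with a warning. A balance report
#' (standardized mean differences before/after matching) is attached.
#'
#' @param cases,controls data frames with columns \code{subject_id},
#'   \code{age}, \code{site}.
#' @param covariates covariate names used for the propensity model.
#' @return object of class \code{match_result}: \code{pairs} (case id,
#'   control id, distance), \code{propensity} per subject, and
#'   \code{balance} (covariate, smd_pre, smd_post).
#' @export
propensity_match <- function(cases, controls, covariates = c("age", "site")) {
  if (nrow(controls) < nrow(cases))
    stop("need at least as many controls as cases", call. = FALSE)
  if (!length(intersect(cases$site, controls$site)))
    stop("no site overlap between cases and controls", call. = FALSE)
  df <- rbind(
    data.frame(subject_id = cases$subject_id, age = cases$age,
               site = cases$site, case = 1, stringsAsFactors = FALSE),
    data.frame(subject_id = controls$subject_id, age = controls$age,
               site = controls$site, case = 0, stringsAsFactors = FALSE))
  form <- if ("site" %in% covariates && length(unique(df$site)) > 1)
    case ~ age + factor(site) else case ~ age
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged) {
    warning("logistic propensity model separated; falling back to standardized-covariate distance",
            call. = FALSE)
    lp <- (df$age - mean(df$age)) / stats::sd(df$age)
  } else {
    lp <- stats::predict(fit, type = "link")
  }
  is_case <- df$case == 1
  case_idx <- which(is_case)[order(lp[is_case], decreasing = TRUE)]
  avail <- which(!is_case)
  pairs <- vector("list", length(case_idx))
  for (k in seq_along(case_idx)) {
    i <- case_idx[k]
    j <- avail[which.min(abs(lp[avail] - lp[i]))]
    pairs[[k]] <- data.frame(case_id = df$subject_id[i],
                             control_id = df$subject_id[j],
                             distance = abs(lp[j] - lp[i]),
                             stringsAsFactors = FALSE)
    avail <- setdiff(avail, j)
  }
  pairs <- do.call(rbind, pairs)
  post_controls <- controls[match(pairs$control_id, controls$subject_id), ]
  bal <- data.frame(
    covariate = "age",
    smd_pre = smd(cases$age, controls$age),
    smd_post = smd(cases$age, post_controls$age),
    stringsAsFactors = FALSE)
  if ("site" %in% covariates) {
    for (s in sort(unique(df$site))) {
      bal <- rbind(bal, data.frame(
        covariate = paste0("site:", s),
        smd_pre = smd(as.numeric(cases$site == s),
                      as.numeric(controls$site == s)),
        smd_post = smd(as.numeric(cases$site == s),
                       as.numeric(post_controls$site == s))))
    }
  }
  structure(list(pairs = pairs,
                 propensity = data.frame(subject_id = df$subject_id,
                                         lp = lp, case = df$case,
                                         stringsAsFactors = FALSE),
                 balance = bal),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("1:1 propensity match: %d pairs\n", nrow(x$pairs)))
  print(x$balance, row.names = FALSE)
  invisible(x)
}

# All permutations of 1..n (n! columns); used for exact enumeration.
all_permutations <- function(n) {
  if (n > 8) stop("exact enumeration limited to n <= 8", call. = FALSE)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(ncol(sub))) {
      col <- col + 1L
      out[, col] <- c(k, rest[sub[, j]])
    }
  }
  out
}

# Permutation index matrix (n rows, one column per permutation).
perm_index_matrix <- function(n, n_perm, seed = NULL, exact = FALSE) {
  if (exact) return(all_permutations(n))
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
}

# Demean columns and check the design contract (tolerance relative to
# column magnitude so large-unit covariates pass the floating-point check).
check_design <- function(X, y) {
  scl <- pmax(1, apply(abs(X), 2, max))
  if (any(abs(colMeans(X)) > 1e-10 * scl))
    stop("design columns must be demeaned", call. = FALSE)
  if (abs(mean(y)) > 1e-10 * max(1, stats::sd(y)))
    stop("outcome must be demeaned", call. = FALSE)
  check_full_rank(X)
}

#' Permutation inference for one GLM contrast (Freedman-Lane)
#'
#' Ordinary-least-squares t statistic for a contrast of the (demeaned)
#' design, with a permutation null built by the Freedman-Lane scheme: the
#' outcome is regressed on the nuisance columns (those with zero contrast
#' weight), the nuisance residuals are permuted, the full model is refit,
#' and the contrast t recomputed. The Monte-Carlo p-value is
#' \eqn{(1 + \#\{|t^*| \ge |t|\})/(1 + n_{perm})} (two-sided by default);
#' with \code{exact = TRUE} every permutation is enumerated and the
#' p-value is the exact proportion (the identity permutation included).
#'
#' @param y outcome vector (demeaned internally).
#' @param X design matrix with named, demeaned columns.
#' @param contrast numeric contrast vector over the columns of \code{X},
#'   or a single column name.
#' @param n_perm number of Monte-Carlo permutations (>= 100).
#' @param seed RNG seed for the permutation draws.
#' @param alternative \code{"two.sided"}, \code{"greater"} or
#'   \code{"less"}.
#' @param exact enumerate all \code{n!} permutations (n <= 8).
#' @param perms optional precomputed permutation index matrix (rows =
#'   subjects, columns = permutations), overriding \code{n_perm}/seed.
#' @param return_null keep the permutation t vector (needed for
#'   max-statistic familywise correction).
#' @return list with \code{t}, \code{df}, \code{p}, \code{n_perm},
#'   \code{seed}, \code{alternative} and optionally \code{t_perm}.
#' @export
permutation_glm <- function(y, X, contrast, n_perm = 10000L, seed = 1L,
                            alternative = c("two.sided", "greater", "less"),
                            exact = FALSE, perms = NULL,
                            return_null = FALSE) {
  alternative <- match.arg(alternative)
  if (!exact && is.null(perms) && n_perm < 100)
    stop_field("n_perm", "must be >= 100")
  if (is.character(contrast)) {
    cv <- as.numeric(colnames(X) == contrast)
    if (!any(cv != 0)) stop(sprintf("no column '%s' in design", contrast),
                            call. = FALSE)
    contrast <- cv
  }
  y <- y - mean(y)
  check_design(X, y)
  n <- length(y); M <- ncol(X)
  XtXi <- solve(crossprod(X))
  H <- XtXi %*% t(X)
  cXc <- drop(t(contrast) %*% XtXi %*% contrast)
  tstat_of <- function(Y) {
    # Y: n x P matrix of (possibly permuted) outcomes
    B <- H %*% Y
    cb <- drop(t(contrast) %*% B)
    rss <- colSums(Y^2) - colSums(B * crossprod(X, Y))
    rss <- pmax(rss, 0)
    # demeaning projected out the intercept, so it costs one df
    s2 <- rss / (n - M - 1)
    se <- sqrt(s2 * cXc)
    ifelse(se > 0, cb / se, 0)
  }
  t_obs <- tstat_of(matrix(y, ncol = 1))
  nuis <- which(contrast == 0)
  if (length(nuis)) {
    Z <- X[, nuis, drop = FALSE]
    gz <- drop(Z %*% solve(crossprod(Z), crossprod(Z, y)))
  } else {
    gz <- rep(0, n)
  }
  e <- y - gz
  if (is.null(perms))
    perms <- perm_index_matrix(n, n_perm, seed = seed, exact = exact)
  Ystar <- gz + matrix(e[perms], n, ncol(perms))
  t_perm <- tstat_of(Ystar)
  tol <- 1e-12 + 1e-8 * abs(t_obs)
  hits <- switch(alternative,
                 two.sided = sum(abs(t_perm) >= abs(t_obs) - tol),
                 greater = sum(t_perm >= t_obs - tol),
                 less = sum(t_perm <= t_obs + tol))
  p <- if (exact) hits / ncol(perms) else (1 + hits) / (1 + ncol(perms))
  out <- list(t = unname(t_obs), df = n - M - 1, p = p, n_perm = ncol(perms),
              seed = if (exact) NA_integer_ else seed,
              alternative = alternative)
  if (return_null) out$t_perm <- t_perm
  out
}

#' Cohen's d from a contrast t statistic
#'
#' Uses the convention \eqn{d = t\sqrt{1/n_1 + 1/n_2}}; for an
#' equal-variance two-group comparison without covariates this equals the
#' classic mean difference over pooled standard deviation.
#'
#' @param t contrast t statistic.
#' @param n1,n2 group sizes.
#' @return Cohen's d.
#' @export
cohens_d <- function(t, n1, n2) {
  stopifnot(n1 > 0, n2 > 0)
  t * sqrt(1 / n1 + 1 / n2)
}

#' Multiplicity correction over a pooled test family
#'
#' Benjamini-Hochberg FDR adjustment (default) over the pooled family of
#' uncorrected p-values for a correction tier (ROIs; ROIs x contrasts;
#' ROIs x contrasts x modalities). The max-statistic Westfall-Young
#' familywise alternative is available via \code{method =
#' "westfall_young"}, which requires the aligned permutation-null t
#' matrix.
#'
#' @param p numeric vector of uncorrected p-values (the pooled family).
#' @param method \code{"bh"} or \code{"westfall_young"}.
#' @param t_obs observed t statistics (Westfall-Young only).
#' @param t_null permutations x tests matrix of null t statistics with
#'   aligned permutation indices (Westfall-Young only).
#' @return vector of corrected p-values, same order as \code{p}.
#' @export
correct_multiplicity <- function(p, method = c("bh", "westfall_young"),
                                 t_obs = NULL, t_null = NULL) {
  method <- match.arg(method)
  if (!length(p)) stop("empty test family", call. = FALSE)
  if (method == "bh") return(stats::p.adjust(p, method = "BH"))
  if (is.null(t_obs) || is.null(t_null))
    stop("westfall_young needs t_obs and t_null", call. = FALSE)
  maxnull <- apply(abs(t_null), 1, max)
  vapply(abs(t_obs), function(tt)
    (1 + sum(maxnull >= tt - 1e-12)) / (1 + length(maxnull)), numeric(1))
}

#' Group-difference permutation GLM across ROIs, contrasts and modalities
#'
#' For each modality, ROI and contrast row, runs a Freedman-Lane
#' permutation GLM of the deviation scores on a demeaned group indicator,
#' controlling for demeaned age (and demeaned ICV for area and volume),
#' then applies nested multiplicity correction at three tiers: over ROIs
#' within (modality, contrast); over ROIs x contrasts within modality;
#' and over ROIs x contrasts x modalities.
#'
#' @param devs named list of [deviation_matrix()] objects, one per
#'   modality.
#' @param covariates participants data frame covering all scored subjects.
#' @param contrasts data frame with columns \code{group_a},
#'   \code{group_b} and optionally \code{alternative}; see
#'   [default_contrasts()].
#' @param matching optional named list of [propensity_match()] results,
#'   keyed by \code{"<group_a>_vs_<group_b>"}: any contrast over that
#'   pairing (either direction) is restricted to the matched case and
#'   control subjects.
#' @param n_perm permutations per test.
#' @param seed master seed; each (modality, contrast) derives its own
#'   permutation stream, shared across ROIs so max-statistic correction
#'   is aligned.
#' @param correction \code{"bh"} (default) or \code{"westfall_young"}.
#' @param icv_modalities modalities whose tests include the ICV
#'   covariate; subjects missing ICV are dropped from these tests with a
#'   message.
#' @return data frame with columns \code{modality}, \code{roi},
#'   \code{contrast}, \code{n_a}, \code{n_b}, \code{t}, \code{cohens_d},
#'   \code{p_unc}, \code{p_fwe_roi}, \code{p_fwe_roi_contrast},
#'   \code{p_fwe_roi_contrast_modality}, \code{n_perm}, \code{seed}.
#' @export
run_group_glm <- function(devs, covariates, contrasts = default_contrasts(),
                          matching = NULL, n_perm = 1000L, seed = 1L,
                          correction = c("bh", "westfall_young"),
                          icv_modalities = c("area", "volume")) {
  correction <- match.arg(correction)
  if (!"alternative" %in% names(contrasts))
    contrasts$alternative <- "two.sided"
  rows <- list()
  nulls <- list()
  for (mod in names(devs)) {
    dev <- devs[[mod]]
    stopifnot(inherits(dev, "deviation_matrix"))
    use_icv <- mod %in% icv_modalities
    for (k in seq_len(nrow(contrasts))) {
      ga <- contrasts$group_a[k]; gb <- contrasts$group_b[k]
      clab <- sprintf("%s>%s", ga, gb)
      cov <- covariates[match(rownames(dev$z), covariates$subject_id), ,
                        drop = FALSE]
      keep <- cov$group %in% c(ga, gb)
      mkey <- intersect(c(sprintf("%s_vs_%s", ga, gb),
                          sprintf("%s_vs_%s", gb, ga)), names(matching))
      if (length(mkey)) {
        mr <- matching[[mkey[1]]]
        keep <- keep & cov$subject_id %in%
          c(mr$pairs$case_id, mr$pairs$control_id)
      }
      if (use_icv) {
        drop_icv <- keep & is.na(cov$icv_mm3)
        if (any(drop_icv))
          message(sprintf("run_group_glm: dropping %d subject(s) without ICV for %s/%s",
                          sum(drop_icv), mod, clab))
        keep <- keep & !is.na(cov$icv_mm3)
      }
      idx <- which(keep)
      grp <- as.numeric(cov$group[idx] == ga)
      n_a <- sum(grp == 1); n_b <- sum(grp == 0)
      # nuisance columns standardized as well: the contrast t is
      # invariant to column scale and conditioning improves
      Xc <- cbind(group = grp - mean(grp),
                  age = scale(cov$age[idx])[, 1])
      if (use_icv) Xc <- cbind(Xc, icv = scale(cov$icv_mm3[idx])[, 1])
      cseed <- sub_seed(seed, paste("glm", mod, clab))
      perms <- perm_index_matrix(length(idx), n_perm, seed = cseed)
      for (r in colnames(dev$z)) {
        res <- permutation_glm(dev$z[idx, r], Xc, "group",
                               alternative = contrasts$alternative[k],
                               perms = perms, return_null = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          modality = mod, roi = r, contrast = clab, n_a = n_a, n_b = n_b,
          t = res$t, cohens_d = cohens_d(res$t, n_a, n_b), p_unc = res$p,
          n_perm = res$n_perm, seed = seed, stringsAsFactors = FALSE)
        nulls[[length(nulls) + 1L]] <- res$t_perm
      }
    }
  }
  out <- do.call(rbind, rows)
  t_null <- do.call(cbind, nulls)
  apply_tiers(out, t_null, correction)
}

# Nested correction tiers shared by group and trait runs.
apply_tiers <- function(out, t_null, correction) {
  adj <- function(sel) {
    if (correction == "bh") correct_multiplicity(out$p_unc[sel])
    else correct_multiplicity(out$p_unc[sel], method = "westfall_young",
                              t_obs = out$t[sel],
                              t_null = t_null[, sel, drop = FALSE])
  }
  out$p_fwe_roi <- NA_real_
  out$p_fwe_roi_contrast <- NA_real_
  out$p_fwe_roi_contrast_modality <- NA_real_
  for (mod in unique(out$modality)) {
    for (cl in unique(out$contrast[out$modality == mod])) {
      sel <- out$modality == mod & out$contrast == cl
      out$p_fwe_roi[sel] <- adj(sel)
    }
    sel <- out$modality == mod
    out$p_fwe_roi_contrast[sel] <- adj(sel)
  }
  out$p_fwe_roi_contrast_modality <- adj(rep(TRUE, nrow(out)))
  # nested families are supersets, so each tier can only be less favorable
  out$p_fwe_roi <- pmax(out$p_fwe_roi, out$p_unc)
  out$p_fwe_roi_contrast <- pmax(out$p_fwe_roi_contrast, out$p_fwe_roi)
  out$p_fwe_roi_contrast_modality <- pmax(out$p_fwe_roi_contrast_modality,
                                          out$p_fwe_roi_contrast)
  cols <- c("modality", "roi", "contrast", "n_a", "n_b", "t", "cohens_d",
            "p_unc", "p_fwe_roi", "p_fwe_roi_contrast",
            "p_fwe_roi_contrast_modality", "n_perm", "seed")
  out[, intersect(cols, names(out)), drop = FALSE]
}

#' Default group contrast table (8 contrasts)
#'
#' Four clinically motivated pairings, each in both directions: every
#' diagnostic group versus healthy controls, plus violent versus
#' non-violent schizophrenia-spectrum patients. With 332 regions this
#' yields the 332 x 8 = 2656-test family; with the default 327-region
#' dictionary, 2616 tests.
#'
#' @return data frame with columns \code{group_a}, \code{group_b},
#'   \code{alternative}.
#' @export
default_contrasts <- function() {
  pairs <- rbind(c("SSD-V", "HC"), c("SSD-NV", "HC"), c("nonSSD-V", "HC"),
                 c("SSD-V", "SSD-NV"))
  out <- rbind(
    data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
               alternative = "greater", stringsAsFactors = FALSE),
    data.frame(group_a = pairs[, 1], group_b = pairs[, 2],
               alternative = "less", stringsAsFactors = FALSE))
  out[order(out$group_a, out$group_b, out$alternative), ]
}

#' One-sided permutation test on per-subject deviation burden
#'
#' Tests whether one group's mean per-subject count of extreme deviations
#' (aggregated across modalities) exceeds ("greater") or falls below
#' ("less") another group's, by permuting group labels. With
#' \code{exact = TRUE} all assignments of subjects to groups are
#' enumerated and the p-value is exact.
#'
#' @param counts per-subject burden counts.
#' @param groups group label per subject.
#' @param group_a,group_b the two groups compared (statistic: mean(a) -
#'   mean(b)).
#' @param direction \code{"greater"} or \code{"less"}.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param exact enumerate all assignments (choose(n, n_a) <= 200000).
#' @return list with \code{statistic} (mean difference), \code{p},
#'   \code{n_perm}, \code{seed}, \code{direction}.
#' @export
burden_permutation_test <- function(counts, groups, group_a, group_b,
                                    direction = c("greater", "less"),
                                    n_perm = 10000L, seed = 1L,
                                    exact = FALSE) {
  direction <- match.arg(direction)
  sel <- groups %in% c(group_a, group_b)
  x <- counts[sel]; g <- groups[sel]
  na <- sum(g == group_a); nb <- sum(g == group_b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty", call. = FALSE)
  stat <- mean(x[g == group_a]) - mean(x[g == group_b])
  if (stats::var(x) == 0) {
    warning("all burden counts equal; p = 1", call. = FALSE)
    return(list(statistic = stat, p = 1, n_perm = 0L, seed = seed,
                direction = direction))
  }
  n <- length(x)
  if (exact) {
    nc <- choose(n, na)
    if (nc > 2e5) stop("exact enumeration too large", call. = FALSE)
    idx <- utils::combn(n, na)
    stats_null <- apply(idx, 2, function(i) mean(x[i]) - mean(x[-i]))
    hits <- if (direction == "greater")
      sum(stats_null >= stat - 1e-12) else sum(stats_null <= stat + 1e-12)
    return(list(statistic = stat, p = hits / nc, n_perm = nc,
                seed = NA_integer_, direction = direction))
  }
  set.seed(seed)
  stats_null <- vapply(seq_len(n_perm), function(i) {
    a <- sample.int(n, na)
    mean(x[a]) - mean(x[-a])
  }, numeric(1))
  hits <- if (direction == "greater")
    sum(stats_null >= stat - 1e-12) else sum(stats_null <= stat + 1e-12)
  list(statistic = stat, p = (1 + hits) / (1 + n_perm), n_perm = n_perm,
       seed = seed, direction = direction)
}

#' Trait-association permutation GLM (PCL-R)
#'
#' Per-ROI Freedman-Lane permutation GLM of deviation scores on a
#' clinician-rated trait (default the PCL-R total), restricted to
#' subjects with the trait present, controlling for age, psychosis
#' status, and ICV for area/volume modalities. The same nested
#' multiplicity tiers as the group tests are applied (here contrasts =
#' the single trait regressor).
#'
#' @param devs named list of [deviation_matrix()] per modality.
#' @param covariates participants data frame.
#' @param trait covariate column holding the trait score.
#' @param psychosis_groups group labels counted as psychotic for the
#'   psychosis-status covariate.
#' @param n_perm permutations (default 10000).
#' @param seed master seed.
#' @param correction \code{"bh"} or \code{"westfall_young"}.
#' @param icv_modalities modalities whose design includes ICV.
#' @param min_n minimum subjects with the trait (default 10).
#' @return data frame as in [run_group_glm()] with contrast label
#'   \code{trait:<name>}.
#' @export
trait_association <- function(devs, covariates, trait = "pclr_total",
                              psychosis_groups = c("SSD-V", "SSD-NV"),
                              n_perm = 10000L, seed = 1L,
                              correction = c("bh", "westfall_young"),
                              icv_modalities = c("area", "volume"),
                              min_n = 10L) {
  correction <- match.arg(correction)
  rows <- list(); nulls <- list()
  for (mod in names(devs)) {
    dev <- devs[[mod]]
    cov <- covariates[match(rownames(dev$z), covariates$subject_id), ,
                      drop = FALSE]
    keep <- !is.na(cov[[trait]])
    if (mod %in% icv_modalities) keep <- keep & !is.na(cov$icv_mm3)
    idx <- which(keep)
    if (length(idx) < min_n)
      stop(sprintf("only %d subject(s) with %s; need at least %d",
                   length(idx), trait, min_n), call. = FALSE)
    tr <- cov[[trait]][idx]
    Xc <- cbind(trait = tr - mean(tr),
                age = scale(cov$age[idx])[, 1])
    psy <- as.numeric(cov$group[idx] %in% psychosis_groups)
    if (stats::var(psy) > 0) Xc <- cbind(Xc, psychosis = psy - mean(psy))
    if (mod %in% icv_modalities) Xc <- cbind(Xc, icv = scale(cov$icv_mm3[idx])[, 1])
    cseed <- sub_seed(seed, paste("trait", mod, trait))
    perms <- perm_index_matrix(length(idx), n_perm, seed = cseed)
    for (r in colnames(dev$z)) {
      res <- permutation_glm(dev$z[idx, r], Xc, "trait", perms = perms,
                             return_null = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        modality = mod, roi = r, contrast = paste0("trait:", trait),
        n_a = length(idx), n_b = NA_integer_, t = res$t,
        cohens_d = NA_real_, p_unc = res$p, n_perm = res$n_perm,
        seed = seed, stringsAsFactors = FALSE)
      nulls[[length(nulls) + 1L]] <- res$t_perm
    }
  }
  out <- do.call(rbind, rows)
  apply_tiers(out, do.call(cbind, nulls), correction)
}
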