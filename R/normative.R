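#' Basis specification for normative regression
#'
#' The normative mean is a linear model in a design built from age and
#' site: an intercept, a cubic B-spline in age with interior knots placed
#' at quantiles of the training ages, optionally a raw linear age column
#' (off by default: the spline span already contains it), and one-hot
#' fixed effects for the training sites (first site as reference level, so
#' a site unseen at training maps to the reference column pattern and is
#' handled entirely by [adapt_to_site()]).
#'
#' @param degree spline degree (default cubic).
#' @param n_knots number of interior knots (default 5).
#' @param intercept include an intercept column.
#' @param linear include a raw linear age column in addition to the
#'   spline (collinear with the spline span unless \code{n_knots = 0} and
#'   \code{degree = 0}; kept for degenerate bases).
#' @param site_effects include one-hot training-site fixed effects.
#' @return object of class \code{basis_spec}.
#' @export
basis_spec <- function(degree = 3L, n_knots = 5L, intercept = TRUE,
                       linear = FALSE, site_effects = TRUE) {
  if (degree < 1) stop_field("degree", "must be >= 1")
  if (n_knots < 0) stop_field("n_knots", "must be >= 0")
  structure(list(degree = as.integer(degree), n_knots = as.integer(n_knots),
                 intercept = intercept, linear = linear,
                 site_effects = site_effects),
            class = "basis_spec")
}

# Resolve data-dependent basis quantities (knots, boundary, site levels)
# on the training covariates.
resolve_basis <- function(spec, covariates) {
  age <- covariates$age
  knots <- if (spec$n_knots > 0)
    unname(stats::quantile(age, probs = seq_len(spec$n_knots) /
                             (spec$n_knots + 1))) else numeric(0)
  list(spec = spec, knots = knots,
       boundary = range(age),
       site_levels = sort(unique(covariates$site)))
}

# Design matrix for arbitrary covariates under a resolved basis. Sites
# outside the training levels fall back to the reference pattern
# (all-zero dummies); age outside the training range extrapolates the
# spline with a warning.
build_design <- function(resolved, covariates, warn_extrapolation = TRUE) {
  spec <- resolved$spec
  age <- covariates$age
  out_of_range <- age < resolved$boundary[1] | age > resolved$boundary[2]
  if (warn_extrapolation && any(out_of_range))
    warning(sprintf("%d subject(s) outside the training age range [%.1f, %.1f]; extrapolating",
                    sum(out_of_range), resolved$boundary[1],
                    resolved$boundary[2]), call. = FALSE)
  bs_mat <- suppressWarnings(
    splines::bs(age, knots = resolved$knots, degree = spec$degree,
                Boundary.knots = resolved$boundary, intercept = FALSE))
  cols <- list()
  if (spec$intercept) cols[["(Intercept)"]] <- rep(1, length(age))
  if (spec$linear) cols[["age"]] <- age
  for (j in seq_len(ncol(bs_mat))) cols[[sprintf("bs_age%d", j)]] <- bs_mat[, j]
  if (spec$site_effects && length(resolved$site_levels) > 1) {
    for (s in resolved$site_levels[-1])
      cols[[paste0("site_", s)]] <- as.numeric(covariates$site == s)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

check_full_rank <- function(X) {
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient basis: collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(qd$rank)
}

# Negative warped-Gaussian log-evidence for one ROI. `prep` carries the
# eigendecomposition of X'X so each evaluation is O(nM + M^2).
neg_log_evidence <- function(theta, y, X, prep, warp_kind, c0, d0) {
  if (warp_kind == "shash") {
    wp <- warp_params(epsilon = theta[1], delta = exp(theta[2]), c = c0, d = d0)
    la <- theta[3]; lb <- theta[4]
  } else {
    wp <- warp_params()
    la <- theta[1]; lb <- theta[2]
  }
  z <- warp(y, wp)
  jac <- if (warp_kind == "shash") sum(warp_log_deriv(y, wp)) else 0
  a <- exp(la); b <- exp(lb)
  n <- length(y); M <- ncol(X)
  Xtz <- crossprod(X, z)
  dvec <- a + b * prep$lambda
  w <- b * (prep$Q %*% (crossprod(prep$Q, Xtz) / dvec))
  rss <- sum(z^2) - 2 * sum(w * Xtz) + sum(w * (prep$XtX %*% w))
  rss <- max(rss, 0)
  logev <- 0.5 * (n * lb + M * la - sum(log(dvec)) - b * rss -
                    a * sum(w^2) - n * log(2 * pi)) + jac
  if (!is.finite(logev)) return(1e10)
  -logev
}

#' Fit a warped Bayesian linear regression normative model for one ROI
#'
#' Maximizes the warped-Gaussian marginal likelihood
#' \deqn{\sum_i \log N(\phi(y_i) \mid w^\top\psi(x_i),\ \beta^{-1}) +
#'       \sum_i \log \phi'(y_i)}
#' over the weight posterior (closed form given the warp), the precisions
#' \eqn{\alpha, \beta} and the sinh-arcsinh warp parameters
#' \eqn{(\epsilon, \log\delta)}, by bounded quasi-Newton (L-BFGS-B) with
#' seeded multi-start. The warp's affine location/scale are fixed at the
#' training median and standard deviation of \eqn{y}. With
#' \code{warp = "identity"} the model reduces exactly to textbook
#' Bayesian ridge regression on \eqn{y}.
#'
#' @param train a [roi_dataset()] of reference (training) subjects.
#' @param roi ROI column name to fit.
#' @param basis a [basis_spec()].
#' @param warp \code{"shash"} (default) or \code{"identity"}.
#' @param opts list: \code{seed} (multi-start RNG), \code{restarts}
#'   (default 3), \code{maxit}.
#' @return object of class \code{normative_model}: posterior weight mean
#'   \code{w} and covariance \code{Sigma_w}, precisions \code{alpha},
#'   \code{beta}, fitted [warp_params()], the resolved basis, training age
#'   range and site list, and the attained log-evidence.
#' @export
fit_normative_model <- function(train, roi, basis = basis_spec(),
                                warp = c("shash", "identity"),
                                opts = list()) {
  stopifnot(inherits(train, "roi_dataset"))
  warp <- match.arg(warp)
  resolved <- resolve_basis(basis, train$covariates)
  X <- build_design(resolved, train$covariates, warn_extrapolation = FALSE)
  fit_normative_model_impl(train, roi, resolved, X, warp, opts)
}

fit_normative_model_impl <- function(train, roi, resolved, X, warp, opts) {
  opts <- utils::modifyList(list(seed = 11L, restarts = 3L, maxit = 500L), opts)
  if (!roi %in% colnames(train$values))
    stop(sprintf("ROI '%s' not in dataset", roi), call. = FALSE)
  y <- train$values[, roi]
  if (length(y) < ncol(X) + 10)
    stop(sprintf("need at least basis dimension + 10 = %d training subjects, have %d",
                 ncol(X) + 10, length(y)), call. = FALSE)
  check_full_rank(X)
  eg <- eigen(crossprod(X), symmetric = TRUE)
  prep <- list(Q = eg$vectors, lambda = pmax(eg$values, 0), XtX = crossprod(X))

  c0 <- if (warp == "shash") stats::median(y) else 0
  d0 <- if (warp == "shash") max(stats::sd(y), 1e-12) else 1
  z0 <- if (warp == "shash") warp(y, warp_params(c = c0, d = d0)) else y
  lb0 <- -log(max(stats::var(z0), 1e-12))
  start0 <- if (warp == "shash") c(0, 0, lb0 - 4, lb0) else c(lb0 - 4, lb0)
  lower <- if (warp == "shash") c(-3, -2.3, -20, -30) else c(-20, -30)
  upper <- if (warp == "shash") c(3, 2.3, 20, 40) else c(20, 40)

  starts <- with_stream(opts$seed, paste0("fit-starts:", roi), {
    s <- list(start0)
    for (r in seq_len(opts$restarts - 1L))
      s[[r + 1L]] <- pmin(pmax(start0 + stats::rnorm(length(start0), 0, 0.5),
                               lower), upper)
    s
  })
  best <- NULL
  trace <- character(0)
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, neg_log_evidence, y = y, X = X, prep = prep,
                   warp_kind = warp, c0 = c0, d0 = d0,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = opts$maxit, factr = 1e7)),
      error = function(e) e)
    if (inherits(res, "error")) { trace <- c(trace, conditionMessage(res)); next }
    trace <- c(trace, sprintf("start(%s): value %.6g, convergence %d",
                              paste(sprintf("%.2f", st), collapse = ","),
                              res$value, res$convergence))
    if (res$convergence %in% c(0L, 1L) &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop(paste0("normative optimizer failed to converge for ROI '", roi,
                "'; trace:\n", paste(trace, collapse = "\n")), call. = FALSE)

  th <- best$par
  if (warp == "shash") {
    wp <- warp_params(epsilon = th[1], delta = exp(th[2]), c = c0, d = d0)
    alpha <- exp(th[3]); beta <- exp(th[4])
  } else {
    wp <- warp_params()
    alpha <- exp(th[1]); beta <- exp(th[2])
  }
  z <- warp(y, wp)
  dvec <- alpha + beta * prep$lambda
  Sigma_w <- prep$Q %*% (t(prep$Q) / dvec)
  w <- beta * (Sigma_w %*% crossprod(X, z))
  structure(list(roi = roi, modality = train$modality,
                 w = drop(w), Sigma_w = Sigma_w,
                 alpha = alpha, beta = beta, warp = wp,
                 basis = resolved, colnames = colnames(X),
                 age_range = range(train$covariates$age),
                 sites = resolved$site_levels,
                 log_evidence = -best$value, n_train = length(y),
                 schema_version = "1"),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative model [%s] %s: n=%d, %d basis columns, %d site(s)\n",
              x$modality, x$roi, x$n_train, length(x$w), length(x$sites)))
  cat(sprintf("  alpha=%.4g beta=%.4g epsilon=%.3g delta=%.3g logev=%.2f\n",
              x$alpha, x$beta, x$warp$epsilon, x$warp$delta, x$log_evidence))
  invisible(x)
}

#' Fit normative models for every ROI of a dataset
#'
#' Convenience wrapper over [fit_normative_model()] sharing the design
#' matrix across ROIs.
#'
#' @inheritParams fit_normative_model
#' @param rois ROI names to fit (default: all columns).
#' @return named list of \code{normative_model}, class
#'   \code{normative_model_set}.
#' @export
fit_normative_models <- function(train, rois = NULL, basis = basis_spec(),
                                 warp = c("shash", "identity"),
                                 opts = list()) {
  stopifnot(inherits(train, "roi_dataset"))
  warp <- match.arg(warp)
  rois <- rois %||% train$roi_names
  resolved <- resolve_basis(basis, train$covariates)
  X <- build_design(resolved, train$covariates, warn_extrapolation = FALSE)
  models <- lapply(rois, function(r)
    fit_normative_model_impl(train, r, resolved, X, warp, opts))
  names(models) <- rois
  structure(models, class = "normative_model_set",
            modality = train$modality)
}

# Predicted mean and predictive sd in warped space for one model.
# sigma_pred^2 = 1/beta + psi' Sigma_w psi (aleatoric + weight-posterior
# uncertainty, so deviations far from the training bulk shrink toward 0).
predict_warped <- function(model, covariates, warn_extrapolation = TRUE) {
  X <- build_design(model$basis, covariates, warn_extrapolation)
  mu <- drop(X %*% model$w)
  s2 <- 1 / model$beta + rowSums((X %*% model$Sigma_w) * X)
  list(mu = mu, sd = sqrt(s2), X = X)
}

#' Calibrate a fitted model to unseen sites
#'
#' Estimates, per site present in the calibration dataset, the offset
#' \eqn{\mu_s} and scale \eqn{\rho_s} of the standardized warped-space
#' residuals \eqn{(\phi(y) - w^\top\psi(x)) / \sigma_{pred}} of reference
#' controls scanned at that site. Downstream Z-scores at an adapted site
#' are \eqn{(r - \mu_s)/\rho_s}.
#'
#' @param model a \code{normative_model} or \code{normative_model_set}.
#' @param calib a [roi_dataset()] of healthy calibration controls.
#' @param sites site labels to calibrate (default: all sites in
#'   \code{calib}).
#' @param min_n minimum calibration subjects per site (default 10;
#'   fewer is an error).
#' @return data frame of class \code{site_adaptation} with columns
#'   \code{roi}, \code{site}, \code{mu}, \code{rho}, \code{n}.
#' @export
adapt_to_site <- function(model, calib, sites = NULL, min_n = 10L) {
  stopifnot(inherits(calib, "roi_dataset"))
  models <- as_model_set(model)
  sites <- sites %||% sort(unique(calib$covariates$site))
  rows <- list()
  for (s in sites) {
    idx <- which(calib$covariates$site == s)
    if (length(idx) < min_n)
      stop(sprintf("site '%s' has %d calibration subjects; need at least %d",
                   s, length(idx), min_n), call. = FALSE)
    cov_s <- calib$covariates[idx, , drop = FALSE]
    for (m in models) {
      pr <- predict_warped(m, cov_s, warn_extrapolation = FALSE)
      r <- (warp(calib$values[idx, m$roi], m$warp) - pr$mu) / pr$sd
      rows[[length(rows) + 1L]] <- data.frame(
        roi = m$roi, site = s, mu = mean(r), rho = stats::sd(r),
        n = length(idx), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$rho <= 0))
    stop("degenerate calibration residuals (zero spread)", call. = FALSE)
  class(out) <- c("site_adaptation", "data.frame")
  out
}

as_model_set <- function(model) {
  if (inherits(model, "normative_model_set")) return(model)
  if (inherits(model, "normative_model")) {
    out <- list(model); names(out) <- model$roi
    return(structure(out, class = "normative_model_set",
                     modality = model$modality))
  }
  stop("expected a normative_model or normative_model_set", call. = FALSE)
}

#' Deviation Z-score matrix
#'
#' @param z numeric subjects-by-ROIs matrix.
#' @param modality modality tag.
#' @param model_id,adaptation_id provenance strings.
#' @return object of class \code{deviation_matrix}.
#' @export
deviation_matrix <- function(z, modality, model_id = NA_character_,
                             adaptation_id = NA_character_) {
  stopifnot(is.matrix(z), is.numeric(z))
  structure(list(z = z, modality = modality, model_id = model_id,
                 adaptation_id = adaptation_id),
            class = "deviation_matrix")
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat(sprintf("Deviation matrix [%s]: %d subjects x %d ROIs (model %s)\n",
              x$modality, nrow(x$z), ncol(x$z), x$model_id))
  invisible(x)
}

#' Score per-subject deviation Z-scores
#'
#' Computes \deqn{Z = \frac{\phi(y) - w^\top\psi(x) - \mu_s\,\sigma_{pred}}
#' {\rho_s\,\sigma_{pred}}} with
#' \eqn{\sigma_{pred}^2 = \beta^{-1} + \psi(x)^\top \Sigma_w \psi(x)}.
#' Subjects at training sites use the null adaptation
#' (\eqn{\mu_s = 0, \rho_s = 1}); subjects at any other site require an
#' [adapt_to_site()] entry for that site. Ages outside the training range
#' are scored with a warning (spline extrapolation).
#'
#' @param model a \code{normative_model} or \code{normative_model_set}.
#' @param adaptation a \code{site_adaptation} from [adapt_to_site()], or
#'   \code{NULL} when all subjects are at training sites.
#' @param data [roi_dataset()] to score.
#' @return a [deviation_matrix()].
#' @export
compute_zscores <- function(model, adaptation = NULL, data) {
  stopifnot(inherits(data, "roi_dataset"))
  models <- as_model_set(model)
  cov <- data$covariates
  site <- cov$site
  first <- models[[1]]
  adapted_sites <- if (is.null(adaptation)) character(0) else
    unique(adaptation$site)
  unknown <- setdiff(unique(site), c(first$sites, adapted_sites))
  if (length(unknown))
    stop(sprintf("site(s) %s unseen at training and not calibrated; run adapt_to_site() on reference controls first",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  z <- matrix(NA_real_, nrow(cov), length(models),
              dimnames = list(cov$subject_id, names(models)))
  warned <- FALSE
  for (m in models) {
    pr <- predict_warped(m, cov, warn_extrapolation = !warned)
    warned <- TRUE
    mu_s <- rep(0, nrow(cov)); rho_s <- rep(1, nrow(cov))
    if (!is.null(adaptation)) {
      ad <- adaptation[adaptation$roi == m$roi, , drop = FALSE]
      hit <- match(site, ad$site)
      use <- !is.na(hit)
      mu_s[use] <- ad$mu[hit[use]]
      rho_s[use] <- ad$rho[hit[use]]
    }
    r <- (warp(data$values[, m$roi], m$warp) - pr$mu) / pr$sd
    z[, m$roi] <- (r - mu_s) / rho_s
  }
  deviation_matrix(z, modality = data$modality,
                   model_id = paste0("fit-", first$modality),
                   adaptation_id = if (is.null(adaptation)) "none" else
                     paste(adapted_sites, collapse = "+"))
}

#' Predict normative centile curves
#'
#' Returns the measurement-space centile
#' \eqn{q_p(age) = \phi^{-1}\!\big(w^\top\psi + \sigma_{pred}(\mu_s +
#' \rho_s\,\Phi^{-1}(p))\big)} on a grid of ages, monotone in \eqn{p} at
#' every age because the warp is strictly increasing.
#'
#' @param model a single \code{normative_model}.
#' @param adaptation optional \code{site_adaptation}.
#' @param ages numeric vector of ages (years).
#' @param probs centile probabilities in (0, 1); must be non-empty.
#' @param site site at which to predict (default: the training reference
#'   pattern with null adaptation).
#' @return data frame with columns \code{age}, \code{prob}, \code{value}.
#' @export
predict_centiles <- function(model, adaptation = NULL, ages,
                             probs = c(0.025, 0.5, 0.975), site = NULL) {
  stopifnot(inherits(model, "normative_model"))
  if (!length(probs) || any(probs <= 0 | probs >= 1))
    stop_field("probs", "must be a non-empty subset of (0, 1)")
  site <- site %||% model$sites[1]
  cov <- data.frame(age = ages, site = site, stringsAsFactors = FALSE)
  pr <- predict_warped(model, cov, warn_extrapolation = FALSE)
  mu_s <- 0; rho_s <- 1
  if (!is.null(adaptation)) {
    ad <- adaptation[adaptation$roi == model$roi & adaptation$site == site, ]
    if (nrow(ad) == 1) { mu_s <- ad$mu; rho_s <- ad$rho }
  }
  grid <- expand.grid(age = ages, prob = probs)
  idx <- match(grid$age, ages)
  zq <- pr$mu[idx] + pr$sd[idx] * (mu_s + rho_s * stats::qnorm(grid$prob))
  grid$value <- warp_inverse(zq, model$warp)
  grid
}

#' Save / load normative models as JSON
#'
#' One JSON file per (modality, ROI) with a versioned schema, holding the
#' model parameters and any site-adaptation entries. Numeric values are
#' written at full double precision, so reloaded models reproduce
#' Z-scores bit-identically.
#'
#' @param models a \code{normative_model_set} (or single model).
#' @param dir model store directory.
#' @param adaptation optional \code{site_adaptation} to store alongside.
#' @return \code{save_models}: written paths, invisibly;
#'   \code{load_models}: list with \code{models} and \code{adaptation}.
#' @export
save_models <- function(models, dir, adaptation = NULL) {
  models <- as_model_set(models)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # doubles are written as 17-significant-digit strings: that many digits
  # uniquely determine an IEEE double, giving bit-exact reload
  num <- function(x) sprintf("%.17g", x)
  paths <- character(0)
  for (m in models) {
    obj <- list(schema_version = "1", roi = m$roi, modality = m$modality,
                w = num(m$w), Sigma_w = num(as.vector(m$Sigma_w)),
                alpha = num(m$alpha), beta = num(m$beta),
                warp = lapply(unclass(m$warp), num),
                basis = list(spec = unclass(m$basis$spec),
                             knots = num(m$basis$knots),
                             boundary = num(m$basis$boundary),
                             site_levels = m$basis$site_levels),
                colnames = m$colnames, age_range = num(m$age_range),
                sites = m$sites, log_evidence = m$log_evidence,
                n_train = m$n_train)
    if (!is.null(adaptation)) {
      ad <- adaptation[adaptation$roi == m$roi, , drop = FALSE]
      obj$adaptation <- lapply(seq_len(nrow(ad)), function(i)
        list(site = ad$site[i], mu = num(ad$mu[i]), rho = num(ad$rho[i]),
             n = ad$n[i]))
    }
    p <- file.path(dir, sprintf("model_%s_%s.json", m$modality,
                                gsub("[^A-Za-z0-9_.-]", "_", m$roi)))
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname save_models
#' @export
load_models <- function(dir) {
  files <- sort(list.files(dir, pattern = "^model_.*\\.json$",
                           full.names = TRUE))
  if (!length(files)) stop(sprintf("no model files in '%s'", dir), call. = FALSE)
  models <- list()
  ad_rows <- list()
  for (f in files) {
    o <- jsonlite::read_json(f, simplifyVector = TRUE)
    wvec <- as.numeric(o$w)
    m <- structure(list(
      roi = o$roi, modality = o$modality, w = wvec,
      Sigma_w = matrix(as.numeric(o$Sigma_w), length(wvec), length(wvec)),
      alpha = as.numeric(o$alpha), beta = as.numeric(o$beta),
      warp = warp_params(as.numeric(o$warp$epsilon),
                         as.numeric(o$warp$delta),
                         as.numeric(o$warp$c), as.numeric(o$warp$d)),
      basis = list(spec = structure(as.list(o$basis$spec)[
                     c("degree", "n_knots", "intercept", "linear",
                       "site_effects")], class = "basis_spec"),
                   knots = as.numeric(o$basis$knots),
                   boundary = as.numeric(o$basis$boundary),
                   site_levels = as.character(o$basis$site_levels)),
      colnames = as.character(o$colnames),
      age_range = as.numeric(o$age_range), sites = as.character(o$sites),
      log_evidence = o$log_evidence, n_train = o$n_train,
      schema_version = o$schema_version), class = "normative_model")
    models[[m$roi]] <- m
    if (!is.null(o$adaptation) && length(o$adaptation)) {
      ad <- if (is.data.frame(o$adaptation)) o$adaptation else
        do.call(rbind, lapply(o$adaptation, as.data.frame))
      ad$roi <- m$roi
      ad$mu <- as.numeric(ad$mu)
      ad$rho <- as.numeric(ad$rho)
      ad$n <- as.integer(ad$n)
      ad_rows[[length(ad_rows) + 1L]] <- ad[, c("roi", "site", "mu", "rho", "n")]
    }
  }
  adaptation <- NULL
  if (length(ad_rows)) {
    adaptation <- do.call(rbind, ad_rows)
    class(adaptation) <- c("site_adaptation", "data.frame")
  }
  list(models = structure(models, class = "normative_model_set",
                          modality = models[[1]]$modality),
       adaptation = adaptation)
}
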