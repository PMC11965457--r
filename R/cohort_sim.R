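#' Default multi-site layout for synthetic cohorts
#'
#' Four training sites (seen by the reference pool) and two transfer sites
#' (where the calibration pool and all study groups are scanned, unseen at
#' training time). Per-site mean offsets are expressed in units of each
#' ROI's residual sigma so that one number applies coherently across
#' modalities with different units; \code{scale} multiplies the residual
#' spread.
#'
#' @return data frame with columns \code{site}, \code{offset_sd},
#'   \code{scale}, \code{role} (\code{"train"} or \code{"transfer"}).
#' @export
default_sites <- function() {
  data.frame(
    site = sprintf("site%02d", 1:6),
    offset_sd = c(0, 0.3, -0.2, 0.15, 0.4, -0.3),
    scale = c(1, 1.1, 0.9, 1.05, 1.15, 0.95),
    role = c(rep("train", 4), rep("transfer", 2)),
    stringsAsFactors = FALSE)
}

#' Specify a synthetic morphometry cohort
#'
#' Defines the generative model for a multi-site cohort: group sizes (the
#' study groups SSD-V/SSD-NV/nonSSD-V/HC plus a reference training pool
#' REF and a site-calibration pool CALIB), per-group age ranges, a site
#' layout with offset/scale effects, smooth cubic age trajectories per
#' ROI, skewed heteroskedastic sinh-arcsinh residual noise, and an
#' intracranial-volume (ICV) coupling for area and volume measures. Each
#' subject's measurement is
#' \deqn{y = f_{roi}(age) + o_{site}\sigma_{roi} + s_{site}\,\sigma_{roi}\,
#'   S^{-1}(\eta;\epsilon,\delta) + b_{roi}\,\tilde{icv}}
#' with \eqn{\eta \sim N(0,1)} and \eqn{S^{-1}} the inverse sinh-arcsinh
#' map, so the normative warp family is correctly specified by
#' construction.
#'
#' @param group_sizes named integer vector of subjects per group. Defaults
#'   to the study design: SSD-V 38, SSD-NV 138, nonSSD-V 20, HC 196, plus
#'   REF 1000 and CALIB 998.
#' @param age_range named list of \code{c(min, max)} ages in years per
#'   group; entry \code{".default"} covers unlisted groups.
#' @param sites site layout data frame, see [default_sites()].
#' @param dictionary ROI dictionary, see [default_roi_dictionary()].
#' @param trajectory optional data frame (\code{modality, roi, b0, b1, b2,
#'   b3, sigma}) of cubic age-trajectory coefficients in the scaled age
#'   \code{t = (age - 40)/40} and residual sigma (measurement units). When
#'   \code{NULL}, coefficients are drawn once per ROI from
#'   modality-appropriate ranges, deterministically from \code{seed}.
#' @param noise list: \code{epsilon} (skew), \code{delta} (tailweight > 0)
#'   of the residual law, \code{sigma_scale} (global multiplier on all
#'   residual sigmas; 0 gives noiseless data), \code{contamination}
#'   (fraction of cells with inflated Gaussian noise, for
#'   misspecification experiments; default 0).
#' @param icv_model list: \code{mean}, \code{sd} of ICV (mm^3) and
#'   \code{loading}, the target correlation between ICV and area/volume
#'   measures (thickness is never coupled).
#' @param pclr_model list: \code{mean}, \code{sd} of the simulated PCL-R
#'   total (0-40 scale), emitted for violence groups only.
#' @param violence_groups group labels that receive PCL-R scores.
#' @param female_fraction fraction of female subjects; the default 0
#'   mirrors an all-male study sample.
#' @param seed integer master seed; every random draw derives from it via
#'   per-purpose streams, so toggling effect injection does not perturb
#'   noise realizations.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(group_sizes = c("SSD-V" = 38L, "SSD-NV" = 138L,
                                        "nonSSD-V" = 20L, "HC" = 196L,
                                        "REF" = 1000L, "CALIB" = 998L),
                        age_range = list("SSD-V" = c(19, 54),
                                         "SSD-NV" = c(15, 58),
                                         "nonSSD-V" = c(9, 71),
                                         "HC" = c(16, 71),
                                         "CALIB" = c(16, 71),
                                         "REF" = c(8, 90),
                                         ".default" = c(8, 90)),
                        sites = default_sites(),
                        dictionary = default_roi_dictionary(),
                        trajectory = NULL,
                        noise = list(),
                        icv_model = list(),
                        pclr_model = list(),
                        violence_groups = c("SSD-V", "nonSSD-V"),
                        female_fraction = 0,
                        seed = 1L) {
  noise <- utils::modifyList(
    list(epsilon = 0.10, delta = 1.05, sigma_scale = 1, contamination = 0), noise)
  icv_model <- utils::modifyList(
    list(mean = 1.5e6, sd = 1.5e5, loading = 0.4), icv_model)
  pclr_model <- utils::modifyList(list(mean = 20, sd = 8), pclr_model)

  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop_field("group_sizes", "must be a named vector")
  if (any(group_sizes < 0)) stop_field("group_sizes", "counts must be >= 0")
  if (!is.data.frame(sites) || nrow(sites) == 0)
    stop_field("sites", "site list must be a non-empty data frame")
  if (!all(c("site", "offset_sd", "scale", "role") %in% names(sites)))
    stop_field("sites", "needs columns site, offset_sd, scale, role")
  if (any(sites$scale <= 0)) stop_field("sites", "scale factors must be > 0")
  if (noise$delta <= 0) stop_field("noise$delta", "must be > 0")
  if (noise$sigma_scale < 0) stop_field("noise$sigma_scale", "must be >= 0")
  if (noise$contamination < 0 || noise$contamination > 1)
    stop_field("noise$contamination", "must be in [0, 1]")
  if (female_fraction < 0 || female_fraction > 1)
    stop_field("female_fraction", "must be in [0, 1]")
  for (g in names(group_sizes)) {
    ar <- age_range[[g]] %||% age_range[[".default"]]
    if (is.null(ar)) stop_field("age_range", paste("no range for group", g))
    if (length(ar) != 2L || ar[1] >= ar[2])
      stop_field("age_range", paste("min must be < max for group", g))
  }
  validate_roi_dictionary(dictionary)
  if (!is.null(trajectory)) {
    need <- c("modality", "roi", "b0", "b1", "b2", "b3", "sigma")
    miss <- setdiff(need, names(trajectory))
    if (length(miss))
      stop_field("trajectory", paste("missing columns:", paste(miss, collapse = ", ")))
    if (any(trajectory$sigma < 0)) stop_field("trajectory", "sigma must be >= 0")
  }
  structure(list(group_sizes = group_sizes, age_range = age_range,
                 sites = sites, dictionary = dictionary,
                 trajectory = trajectory, noise = noise,
                 icv_model = icv_model, pclr_model = pclr_model,
                 violence_groups = violence_groups,
                 female_fraction = female_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                          collapse = ", "), "\n", sep = "")
  cat(sprintf("  sites: %d (%d train, %d transfer)\n", nrow(x$sites),
              sum(x$sites$role == "train"), sum(x$sites$role == "transfer")))
  cat(sprintf("  ROIs: %d; residual skew epsilon=%.3g, delta=%.3g; seed=%d\n",
              nrow(x$dictionary), x$noise$epsilon, x$noise$delta, x$seed))
  invisible(x)
}

#' Specify injected group-specific deviation effects
#'
#' A table of sparse, group-specific effects: for each (group, modality,
#' ROI) a signed \code{shift} in units of that ROI's residual sigma is
#' added for a Bernoulli(\code{prevalence}) subset of the group
#' ("carriers"), encoding the premise that only a fraction of patients
#' carries any given anatomical deviation. \code{trait_link} optionally
#' couples the ROI to the simulated PCL-R total (Z-units per PCL-R point,
#' applied mean-centred to subjects with a PCL-R score).
#'
#' @param effects data frame with columns \code{group}, \code{modality},
#'   \code{roi}, \code{shift}, \code{prevalence} and optionally
#'   \code{trait_link}.
#' @return object of class \code{deviation_effects}.
#' @export
deviation_effects <- function(effects) {
  need <- c("group", "modality", "roi", "shift", "prevalence")
  miss <- setdiff(need, names(effects))
  if (length(miss))
    stop_field("effects", paste("missing columns:", paste(miss, collapse = ", ")))
  if (!"trait_link" %in% names(effects)) effects$trait_link <- 0
  if (any(effects$prevalence < 0 | effects$prevalence > 1))
    stop_field("effects$prevalence", "must be in [0, 1]")
  structure(effects, class = c("deviation_effects", "data.frame"))
}

# Per-ROI generative parameters (trajectory coefficients, sigma), drawn
# once and deterministically from the spec seed unless supplied.
roi_parameters <- function(spec) {
  if (!is.null(spec$trajectory)) {
    tr <- spec$trajectory
  } else {
    dict <- spec$dictionary
    tr <- with_stream(spec$seed, "trajectory", {
      out <- lapply(seq_len(nrow(dict)), function(i) {
        mod <- dict$modality[i]
        if (mod == "thickness") {
          b0 <- stats::runif(1, 2.2, 3.0)
          data.frame(modality = mod, roi = dict$roi[i], b0 = b0,
                     b1 = stats::runif(1, -0.35, -0.15),
                     b2 = stats::runif(1, -0.10, 0.05),
                     b3 = stats::runif(1, -0.05, 0.05),
                     sigma = stats::runif(1, 0.09, 0.16))
        } else {
          base <- if (mod == "area") stats::runif(1, 600, 2500)
                  else stats::runif(1, 1500, 15000)
          data.frame(modality = mod, roi = dict$roi[i], b0 = base,
                     b1 = base * stats::runif(1, -0.12, -0.03),
                     b2 = base * stats::runif(1, -0.05, 0.02),
                     b3 = base * stats::runif(1, -0.02, 0.02),
                     sigma = base * stats::runif(1, 0.06, 0.11))
        }
      })
      do.call(rbind, out)
    })
  }
  tr$sigma <- tr$sigma * spec$noise$sigma_scale
  tr$icv_b <- icv_coupling_coef(tr, spec)
  tr
}

# Deterministic ICV coupling coefficient per ROI (area/volume only): set
# from the model-implied pre-coupling spread so that the value-ICV
# correlation equals the requested loading in a cohort spanning the
# default age range. Being a fixed generative parameter (not a per-table
# empirical fit), the same law applies to reference and clinical tables.
icv_coupling_coef <- function(tr, spec) {
  lam <- spec$icv_model$loading
  b <- rep(0, nrow(tr))
  couple <- tr$modality %in% c("area", "volume")
  if (lam == 0 || !any(couple)) return(b)
  ages <- unlist(spec$age_range)
  tgrid <- (seq(min(ages), max(ages), length.out = 2001) - 40) / 40
  # variance of the inverse-SHASH residual law, by quantile quadrature
  eta <- stats::qnorm((seq_len(4000) - 0.5) / 4000)
  s_inv <- sinh((asinh(eta) + spec$noise$epsilon) / spec$noise$delta)
  v_shash <- stats::var(s_inv)
  msc <- mean(spec$sites$scale^2)
  voff <- stats::var(spec$sites$offset_sd) * (nrow(spec$sites) - 1) /
    nrow(spec$sites)
  if (!is.finite(voff)) voff <- 0
  for (j in which(couple)) {
    traj <- tr$b0[j] + tr$b1[j] * tgrid + tr$b2[j] * tgrid^2 +
      tr$b3[j] * tgrid^3
    v_base <- stats::var(traj) + tr$sigma[j]^2 * (msc * v_shash + voff)
    b[j] <- lam * sqrt(v_base) / sqrt(1 - lam^2)
  }
  b
}

trajectory_value <- function(age, b0, b1, b2, b3) {
  t <- (age - 40) / 40
  b0 + b1 * t + b2 * t^2 + b3 * t^3
}

# Build the per-subject covariate table for the requested groups.
simulate_subjects <- function(spec, groups) {
  sizes <- spec$group_sizes[groups]
  n <- sum(sizes)
  group <- rep(names(sizes), times = sizes)
  id <- sprintf("sub-%s-%04d", gsub("[^A-Za-z0-9]", "", group),
                unlist(lapply(sizes, seq_len)))
  with_stream(spec$seed, "subjects", {
    age <- numeric(n)
    for (g in names(sizes)) {
      ar <- spec$age_range[[g]] %||% spec$age_range[[".default"]]
      idx <- which(group == g)
      age[idx] <- stats::runif(length(idx), ar[1], ar[2])
    }
    sex <- ifelse(stats::runif(n) < spec$female_fraction, "F", "M")
    # REF lives on training sites; every other pool on transfer sites
    # (falling back to all sites when the layout has no transfer sites).
    train_sites <- spec$sites$site[spec$sites$role == "train"]
    transfer_sites <- spec$sites$site[spec$sites$role == "transfer"]
    if (!length(transfer_sites)) transfer_sites <- spec$sites$site
    if (!length(train_sites)) train_sites <- spec$sites$site
    site <- ifelse(group == "REF",
                   sample(train_sites, n, replace = TRUE),
                   sample(transfer_sites, n, replace = TRUE))
    icv <- stats::rnorm(n, spec$icv_model$mean, spec$icv_model$sd)
    pclr <- rep(NA_real_, n)
    vg <- group %in% spec$violence_groups
    pclr[vg] <- pmin(40, pmax(0, stats::rnorm(sum(vg), spec$pclr_model$mean,
                                              spec$pclr_model$sd)))
    data.frame(subject_id = id, age = age, sex = sex, site = site,
               group = group, icv_mm3 = icv, pclr_total = pclr,
               stringsAsFactors = FALSE)
  })
}

# Core generator shared by the reference and clinical entry points.
simulate_cohort_core <- function(spec, groups, effects = NULL) {
  missing_groups <- setdiff(groups, names(spec$group_sizes))
  if (length(missing_groups))
    stop(sprintf("unknown group label(s): %s",
                 paste(missing_groups, collapse = ", ")), call. = FALSE)
  subjects <- simulate_subjects(spec, groups)
  rp <- roi_parameters(spec)
  site_tab <- spec$sites
  site_offset <- stats::setNames(site_tab$offset_sd, site_tab$site)
  site_scale <- stats::setNames(site_tab$scale, site_tab$site)
  wp <- warp_params(epsilon = spec$noise$epsilon, delta = spec$noise$delta)
  n <- nrow(subjects)

  carriers <- list()
  datasets <- list()
  for (mod in c("thickness", "area", "volume")) {
    rpm <- rp[rp$modality == mod, , drop = FALSE]
    if (!nrow(rpm)) next
    R <- nrow(rpm)
    base <- matrix(0, n, R, dimnames = list(subjects$subject_id, rpm$roi))
    for (j in seq_len(R))
      base[, j] <- trajectory_value(subjects$age, rpm$b0[j], rpm$b1[j],
                                    rpm$b2[j], rpm$b3[j])
    off <- outer(unname(site_offset[subjects$site]), rpm$sigma)
    eta <- with_stream(spec$seed, paste0("noise:", mod),
                       matrix(rshash(n * R, wp), n, R))
    if (spec$noise$contamination > 0) {
      with_stream(spec$seed, paste0("contam:", mod), {
        hit <- matrix(stats::runif(n * R) < spec$noise$contamination, n, R)
        eta[hit] <- stats::rnorm(sum(hit), 0, 5)
      })
    }
    resid <- eta * rep(rpm$sigma, each = n) *
      unname(site_scale[subjects$site])
    values <- base + off + resid

    # ICV coupling for head-size-dependent modalities (fixed generative
    # coefficient; see icv_coupling_coef)
    if (mod %in% c("area", "volume") && spec$icv_model$loading != 0 &&
        spec$noise$sigma_scale > 0) {
      icv_std <- (subjects$icv_mm3 - spec$icv_model$mean) / spec$icv_model$sd
      values <- values + outer(icv_std, rpm$icv_b)
    }

    if (!is.null(effects)) {
      em <- effects[effects$modality == mod, , drop = FALSE]
      for (k in seq_len(nrow(em))) {
        if (!em$group[k] %in% names(spec$group_sizes))
          stop(sprintf("unknown group label(s): %s", em$group[k]), call. = FALSE)
        if (!em$roi[k] %in% rpm$roi)
          stop(sprintf("effect references unknown ROI '%s' (%s)",
                       em$roi[k], mod), call. = FALSE)
        idx <- which(subjects$group == em$group[k])
        if (!length(idx)) next
        sig <- rpm$sigma[match(em$roi[k], rpm$roi)]
        carry <- with_stream(spec$seed,
                             paste("effects", em$group[k], mod, em$roi[k]),
                             stats::runif(length(idx)) < em$prevalence[k])
        values[idx[carry], em$roi[k]] <-
          values[idx[carry], em$roi[k]] + em$shift[k] * sig
        if (em$trait_link[k] != 0) {
          has_pclr <- idx[!is.na(subjects$pclr_total[idx])]
          if (length(has_pclr)) {
            dev <- subjects$pclr_total[has_pclr] - spec$pclr_model$mean
            values[has_pclr, em$roi[k]] <- values[has_pclr, em$roi[k]] +
              em$trait_link[k] * sig * dev
          }
        }
        if (any(carry))
          carriers[[length(carriers) + 1L]] <- data.frame(
            subject_id = subjects$subject_id[idx[carry]],
            group = em$group[k], modality = mod, roi = em$roi[k],
            shift = em$shift[k], stringsAsFactors = FALSE)
      }
    }
    datasets[[mod]] <- roi_dataset(values, subjects, modality = mod)
  }

  truth <- structure(list(
    subjects = subjects,
    roi_params = rp,
    sites = site_tab,
    carriers = if (length(carriers)) do.call(rbind, carriers) else
      data.frame(subject_id = character(), group = character(),
                 modality = character(), roi = character(),
                 shift = numeric(), stringsAsFactors = FALSE),
    noise = spec$noise, icv_model = spec$icv_model, seed = spec$seed),
    class = "truth_table")
  list(data = datasets, truth = truth)
}

#' Simulate the reference and calibration pools
#'
#' Generates the normative training pool (group \code{REF}, scanned at the
#' training sites) and the site-calibration pool (group \code{CALIB},
#' healthy controls scanned at the transfer sites), one ROI dataset per
#' modality, with a ground-truth table of all generative parameters.
#'
#' @param spec a [cohort_spec()].
#' @param groups which pools to simulate; default \code{c("REF", "CALIB")}.
#' @return list with elements \code{data} (named list of
#'   \code{roi_dataset}, one per modality) and \code{truth}
#'   (\code{truth_table}).
#' @export
simulate_reference_cohort <- function(spec, groups = c("REF", "CALIB")) {
  stopifnot(inherits(spec, "cohort_spec"))
  simulate_cohort_core(spec, groups)
}

#' Simulate the clinical study groups
#'
#' Generates the study groups (default SSD-V, SSD-NV, nonSSD-V, HC) under
#' the same generative law as the reference pools, plus injected sparse
#' group-specific deviation effects: each carrier subject (drawn
#' Bernoulli(prevalence) per effect row) receives the stated shift in
#' residual-sigma units. PCL-R totals are emitted for violence groups
#' only, clipped to the 0-40 scale.
#'
#' @param spec a [cohort_spec()].
#' @param effects a [deviation_effects()] table, or \code{NULL} for no
#'   injected effects.
#' @param groups group labels to simulate.
#' @return list with elements \code{data} and \code{truth} as in
#'   [simulate_reference_cohort()]; \code{truth$carriers} flags every
#'   subject carrying each injected effect.
#' @export
simulate_clinical_groups <- function(spec, effects = NULL,
                                     groups = c("SSD-V", "SSD-NV",
                                                "nonSSD-V", "HC")) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(effects)) stopifnot(inherits(effects, "deviation_effects"))
  simulate_cohort_core(spec, groups, effects)
}

#' Write a simulated cohort to disk
#'
#' Emits a BIDS-participants-style \code{participants.tsv}, one wide
#' \code{roi_<modality>.tsv} per modality (first column
#' \code{subject_id}), and \code{truth.json} holding the generative
#' parameters and carrier flags. All files round-trip losslessly through
#' the package readers.
#'
#' @param data named list of \code{roi_dataset} objects (one per modality).
#' @param truth the matching \code{truth_table} (or \code{NULL} to skip).
#' @param out_dir output directory, created if needed.
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(data, truth, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  cov <- data[[1]]$covariates
  paths <- c(participants = file.path(out_dir, "participants.tsv"))
  write_tsv(cov, paths[["participants"]])
  for (mod in names(data)) {
    p <- file.path(out_dir, sprintf("roi_%s.tsv", mod))
    tab <- data.frame(subject_id = rownames(data[[mod]]$values),
                      data[[mod]]$values, check.names = FALSE,
                      stringsAsFactors = FALSE)
    write_tsv(tab, p)
    paths[[paste0("roi_", mod)]] <- p
  }
  if (!is.null(truth)) {
    p <- file.path(out_dir, "truth.json")
    jsonlite::write_json(unclass(truth), p, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    paths[["truth"]] <- p
  }
  invisible(paths)
}
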