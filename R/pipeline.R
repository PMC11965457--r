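#' Validate a pipeline run configuration
#'
#' Reads a YAML run configuration and validates it in full, reporting
#' every problem at once. Unknown keys are an error (nothing is silently
#' ignored); the seed must be explicit (no wall-clock seeding).
#'
#' Recognized keys: \code{seed}, \code{out_dir}, \code{modalities},
#' \code{n_roi} (ROIs per modality, or \code{"all"}), \code{group_sizes},
#' \code{threshold}, \code{n_perm}, \code{matching} (\code{"1to1"} or
#' \code{"full"}), \code{correction} (\code{"bh"} or
#' \code{"westfall_young"}), \code{warp} (\code{"shash"} or
#' \code{"identity"}), \code{basis} (\code{degree}, \code{n_knots}),
#' \code{noise} (\code{epsilon}, \code{delta}, \code{sigma_scale},
#' \code{contamination}), \code{effects} (list of \code{group},
#' \code{modality}, \code{roi} or \code{roi_index}, \code{shift},
#' \code{prevalence}, \code{trait_link}).
#'
#' @param path YAML file path, or a named list with the same structure.
#' @return object of class \code{run_config}.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path),
                                 call. = FALSE)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else
    stop("config must be a file path or a list", call. = FALSE)

  known <- c("seed", "out_dir", "modalities", "n_roi", "group_sizes",
             "threshold", "n_perm", "matching", "correction", "warp",
             "basis", "noise", "effects")
  errs <- character(0)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    errs <- c(errs, sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(cfg$seed))
    errs <- c(errs, "missing required field 'seed' (explicit seeding only)")
  else if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    errs <- c(errs, "'seed' must be a single integer")
  if (is.null(cfg$out_dir)) errs <- c(errs, "missing required field 'out_dir'")
  defaults <- list(modalities = c("thickness", "area", "volume"),
                   n_roi = 10L,
                   group_sizes = list("SSD-V" = 38L, "SSD-NV" = 138L,
                                      "nonSSD-V" = 20L, "HC" = 196L,
                                      "REF" = 1000L, "CALIB" = 998L),
                   threshold = 2, n_perm = 1000L, matching = "1to1",
                   correction = "bh", warp = "shash",
                   basis = list(degree = 3L, n_knots = 5L),
                   noise = list(), effects = list())
  # fill defaults key-by-key: modifyList would recurse into (and drop)
  # unnamed list values such as the effects entries
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("basis", "noise"))
    if (is.list(cfg[[k]])) cfg[[k]] <- utils::modifyList(defaults[[k]], cfg[[k]])
  bad_mod <- setdiff(cfg$modalities, c("thickness", "area", "volume"))
  if (length(bad_mod))
    errs <- c(errs, sprintf("unknown modality(ies): %s",
                            paste(bad_mod, collapse = ", ")))
  if (!is.numeric(cfg$threshold) || cfg$threshold <= 0)
    errs <- c(errs, "'threshold' must satisfy threshold > 0")
  if (!is.numeric(cfg$n_perm) || cfg$n_perm < 100)
    errs <- c(errs, "'n_perm' must be >= 100")
  if (!cfg$matching %in% c("1to1", "full"))
    errs <- c(errs, "'matching' must be \"1to1\" or \"full\"")
  if (!cfg$correction %in% c("bh", "westfall_young"))
    errs <- c(errs, "'correction' must be \"bh\" or \"westfall_young\"")
  if (!cfg$warp %in% c("shash", "identity"))
    errs <- c(errs, "'warp' must be \"shash\" or \"identity\"")
  if (!identical(cfg$n_roi, "all") &&
      (!is.numeric(cfg$n_roi) || cfg$n_roi < 1))
    errs <- c(errs, "'n_roi' must be a positive count or \"all\"")
  for (i in seq_along(cfg$effects)) {
    e <- cfg$effects[[i]]
    need <- c("group", "modality", "shift", "prevalence")
    miss <- setdiff(need, names(e))
    if (length(miss))
      errs <- c(errs, sprintf("effects[%d]: missing %s", i,
                              paste(miss, collapse = ", ")))
    if (is.null(e[["roi"]]) && is.null(e[["roi_index"]]))
      errs <- c(errs, sprintf("effects[%d]: needs 'roi' or 'roi_index'", i))
    if (!is.null(e$prevalence) && (e$prevalence < 0 || e$prevalence > 1))
      errs <- c(errs, sprintf("effects[%d]: prevalence must be in [0, 1]", i))
  }
  if (length(errs))
    stop(paste0("invalid configuration:\n  - ",
                paste(errs, collapse = "\n  - ")), call. = FALSE)
  structure(cfg, class = "run_config")
}

config_to_spec <- function(cfg) {
  dict <- default_roi_dictionary()
  if (!identical(cfg$n_roi, "all")) {
    dict <- do.call(rbind, lapply(cfg$modalities, function(m) {
      d <- dict[dict$modality == m, , drop = FALSE]
      utils::head(d, cfg$n_roi)
    }))
  } else {
    dict <- dict[dict$modality %in% cfg$modalities, , drop = FALSE]
  }
  gs <- unlist(cfg$group_sizes)
  cohort_spec(group_sizes = gs, dictionary = dict,
              noise = cfg$noise, seed = cfg$seed)
}

config_effects <- function(cfg, dict) {
  if (!length(cfg$effects)) return(NULL)
  rows <- lapply(cfg$effects, function(e) {
    roi <- e[["roi"]] # [[ avoids partial matching against roi_index
    if (is.null(roi)) {
      d <- dict[dict$modality == e$modality, , drop = FALSE]
      roi <- d$roi[e[["roi_index"]]]
    }
    data.frame(group = e$group, modality = e$modality, roi = roi,
               shift = e$shift, prevalence = e$prevalence,
               trait_link = e$trait_link %||% 0, stringsAsFactors = FALSE)
  })
  deviation_effects(do.call(rbind, rows))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage in order — simulate, fit, adapt, score, map,
#' test, associate — under a validated configuration, writing all result
#' tables, a manifest (config, package version, per-file MD5 checksums,
#' collected warnings) and a human-readable summary to the run directory.
#' Reruns with an identical configuration produce byte-identical result
#' tables.
#'
#' @param config a \code{run_config} from [validate_config()], a config
#'   file path, or a config list.
#' @return the run directory path, invisibly.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  run <- function(name, expr) {
    stage <<- name
    message(sprintf("[run_all] stage: %s", name))
    withCallingHandlers(expr, warning = function(w) {
      note("[%s] %s", name, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  tryCatch({
    spec <- config_to_spec(cfg)
    effects <- config_effects(cfg, spec$dictionary)

    ref <- run("simulate", {
      r <- simulate_reference_cohort(spec)
      write_cohort(r$data, r$truth, file.path(out, "data", "reference"))
      r
    })
    clin <- run("simulate", {
      cl <- simulate_clinical_groups(spec, effects)
      write_cohort(cl$data, cl$truth, file.path(out, "data", "clinical"))
      cl
    })

    ref_only <- lapply(ref$data, subset_dataset, group = "REF")
    calib <- lapply(ref$data, subset_dataset, group = "CALIB")

    models <- run("fit", lapply(ref_only, function(d)
      fit_normative_models(d, warp = cfg$warp,
                           basis = basis_spec(degree = cfg$basis$degree,
                                              n_knots = cfg$basis$n_knots),
                           opts = list(seed = sub_seed(cfg$seed, "fit")))))
    adaptations <- run("adapt", lapply(cfg$modalities, function(m)
      adapt_to_site(models[[m]], calib[[m]])))
    names(adaptations) <- cfg$modalities
    run("adapt", for (m in cfg$modalities)
      save_models(models[[m]], file.path(out, "models"), adaptations[[m]]))

    devs <- run("score", {
      d <- lapply(cfg$modalities, function(m)
        compute_zscores(models[[m]], adaptations[[m]], clin$data[[m]]))
      names(d) <- cfg$modalities
      for (m in cfg$modalities)
        write_deviations(d[[m]], file.path(out, sprintf("deviations_%s.tsv", m)))
      d
    })

    cov <- clin$data[[1]]$covariates
    masks <- run("map", {
      mk <- lapply(devs, threshold_extremes, threshold = cfg$threshold)
      freq <- do.call(rbind, lapply(mk, roi_extreme_frequency,
                                    groups = cov$group))
      write_results(freq, file.path(out, "extreme_summary_roi.tsv"))
      rates <- do.call(rbind, lapply(mk, group_mean_extreme_rate,
                                     groups = cov$group))
      write_results(rates, file.path(out, "extreme_summary_group.tsv"))
      burden <- subject_extreme_burden(unname(mk))
      burden$group <- cov$group
      write_results(burden, file.path(out, "subject_burden.tsv"))
      tier_map <- freq[!is.na(freq$tier), ]
      write_results(tier_map, file.path(out, "tier_map.tsv"))
      list(masks = mk, freq = freq, rates = rates, burden = burden)
    })

    results <- run("test", {
      contrasts <- default_contrasts()
      matching <- NULL
      if (cfg$matching == "1to1") {
        matching <- list()
        for (g in intersect(c("SSD-V", "SSD-NV", "nonSSD-V"),
                            unique(cov$group))) {
          mr <- propensity_match(cov[cov$group == g, ],
                                 cov[cov$group == "HC", ])
          matching[[sprintf("%s_vs_HC", g)]] <- mr
        }
      }
      glm_res <- run_group_glm(devs, cov, contrasts, matching = matching,
                               n_perm = cfg$n_perm, seed = cfg$seed,
                               correction = cfg$correction)
      write_results(glm_res, file.path(out, "results_group.tsv"))

      burden <- masks$burden
      brows <- list()
      for (g in intersect(c("SSD-V", "SSD-NV", "nonSSD-V"),
                          unique(cov$group))) {
        for (sgn in c("negative", "positive")) {
          cnt <- if (sgn == "negative") burden$n_negative else burden$n_positive
          dirn <- if (sgn == "negative") "greater" else "less"
          bt <- burden_permutation_test(cnt, burden$group, g, "HC",
                                        direction = dirn,
                                        n_perm = cfg$n_perm,
                                        seed = sub_seed(cfg$seed,
                                                        paste("burden", g, sgn)))
          brows[[length(brows) + 1L]] <- data.frame(
            group_a = g, group_b = "HC", sign = sgn, direction = dirn,
            statistic = bt$statistic, p = bt$p, n_perm = bt$n_perm,
            stringsAsFactors = FALSE)
        }
      }
      burden_res <- do.call(rbind, brows)
      write_results(burden_res, file.path(out, "results_burden.tsv"))
      list(glm = glm_res, burden = burden_res, matching = matching)
    })

    assoc <- run("associate", {
      a <- trait_association(devs, cov, n_perm = cfg$n_perm,
                             seed = cfg$seed, correction = cfg$correction)
      write_results(a, file.path(out, "results_pclr.tsv"))
      a
    })

    run("report", {
      write_manifest(cfg, out, warnings_log)
      write_summary(cfg, out, masks, results, assoc)
    })
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial outputs kept in '%s')",
                 stage, conditionMessage(e), out), call. = FALSE)
  })
  invisible(out)
}

# Restrict a roi_dataset to one group.
subset_dataset <- function(data, group) {
  keep <- data$covariates$group %in% group
  roi_dataset(data$values[keep, , drop = FALSE],
              data$covariates[keep, , drop = FALSE], data$modality)
}

write_manifest <- function(cfg, out, warnings_log) {
  files <- sort(list.files(out, recursive = TRUE, full.names = TRUE,
                           pattern = "\\.(tsv|json)$"))
  files <- files[basename(files) != "manifest.json"]
  sums <- tools::md5sum(files)
  manifest <- list(
    package = "normdev",
    version = as.character(utils::packageVersion("normdev")),
    config = unclass(cfg),
    checksums = as.list(stats::setNames(unname(sums),
                                        sub(paste0(out, "/?"), "", files))),
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_summary <- function(cfg, out, masks, results, assoc) {
  con <- file(file.path(out, "summary.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("normdev run summary")
  w("===================")
  w("seed: %d; threshold |Z| > %g; %d permutations; matching: %s; correction: %s",
    cfg$seed, cfg$threshold, cfg$n_perm, cfg$matching, cfg$correction)
  w("")
  w("Group mean extreme-deviation rates (%% of regions per subject):")
  r <- masks$rates
  for (i in seq_len(nrow(r)))
    w("  %-9s %-9s %-8s %5.2f%%", r$group[i], r$modality[i], r$sign[i],
      r$mean_pct[i])
  w("")
  w("Top negative-frequency regions per group:")
  for (g in unique(masks$freq$group)) {
    tp <- top_regions(masks$freq, g, "negative", k = 3)
    for (i in seq_len(nrow(tp)))
      w("  %-9s %-35s %5s%% (%d/%d)", g, tp$roi[i], tp$pct_label[i],
        tp$count[i], tp$n_group[i])
  }
  w("")
  w("Burden permutation tests (vs HC):")
  b <- results$burden
  for (i in seq_len(nrow(b)))
    w("  %-9s %-8s dir=%-7s diff=%6.2f p=%.4f", b$group_a[i], b$sign[i],
      b$direction[i], b$statistic[i], b$p[i])
  w("")
  gl <- results$glm
  sig <- gl[gl$p_fwe_roi_contrast_modality < 0.05, , drop = FALSE]
  w("Group GLM: %d tests (%d ROIs x %d contrasts x %d modalities); %d significant at the full-family tier",
    nrow(gl), length(unique(gl$roi)), length(unique(gl$contrast)),
    length(unique(gl$modality)), nrow(sig))
  w("Trait association: min p_unc = %.4g (%s %s)",
    min(assoc$p_unc), assoc$modality[which.min(assoc$p_unc)],
    assoc$roi[which.min(assoc$p_unc)])
  invisible(NULL)
}
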