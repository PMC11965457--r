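# Shared fixtures: small dictionaries and cohort specs so individual tests
# stay fast. Everything is generated in code; no data files.

small_dictionary <- function(n_thickness = 3, n_area = 3, n_volume = 3) {
  d <- default_roi_dictionary()
  rbind(utils::head(d[d$modality == "thickness", ], n_thickness),
        utils::head(d[d$modality == "area", ], n_area),
        utils::head(d[d$modality == "volume", ], n_volume))
}

# One training + one transfer site, useful when site effects are a nuisance.
two_sites <- function(offset_sd = c(0, 0.4), scale = c(1, 1.15)) {
  data.frame(site = c("siteA", "siteB"), offset_sd = offset_sd,
             scale = scale, role = c("train", "transfer"),
             stringsAsFactors = FALSE)
}

one_site <- function() {
  data.frame(site = "siteA", offset_sd = 0, scale = 1, role = "train",
             stringsAsFactors = FALSE)
}

small_spec <- function(group_sizes = c("REF" = 300, "CALIB" = 60,
                                       "HC" = 60, "SSD-V" = 38),
                       dictionary = small_dictionary(),
                       sites = two_sites(), seed = 42, ...) {
  cohort_spec(group_sizes = group_sizes, dictionary = dictionary,
              sites = sites, seed = seed, ...)
}

subset_group <- function(data, groups) {
  keep <- data$covariates$group %in% groups
  roi_dataset(data$values[keep, , drop = FALSE],
              data$covariates[keep, , drop = FALSE], data$modality)
}

# Deviation matrix with standard-normal entries, for null-behaviour tests.
null_devmat <- function(n, R, seed = 1, modality = "thickness") {
  set.seed(seed)
  z <- matrix(rnorm(n * R), n, R,
              dimnames = list(sprintf("s%04d", seq_len(n)),
                              sprintf("roi%03d", seq_len(R))))
  deviation_matrix(z, modality = modality)
}
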