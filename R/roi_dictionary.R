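#' ROI dictionaries
#'
#' A ROI dictionary is a data frame with columns \code{roi} (unique name),
#' \code{hemisphere} (\code{"left"}, \code{"right"} or \code{"none"}),
#' \code{modality} (\code{"thickness"}, \code{"area"} or \code{"volume"})
#' and \code{lobe} (free-text anatomical tag). The default dictionary
#' covers a Destrieux-style cortical parcellation (74 regions per
#' hemisphere, listed once for thickness and once for area: 148 + 148
#' columns) plus 31 subcortical/ventricular volume structures, 327 regions
#' in total. The dictionary is fully configurable: any data frame with the
#' same columns is accepted wherever a dictionary is expected.
#'
#' @name roi_dictionary
NULL

destrieux_labels <- function() {
  c("G_and_S_frontomargin", "G_and_S_occipital_inf", "G_and_S_paracentral",
    "G_and_S_subcentral", "G_and_S_transv_frontopol", "G_and_S_cingul-Ant",
    "G_and_S_cingul-Mid-Ant", "G_and_S_cingul-Mid-Post",
    "G_cingul-Post-dorsal", "G_cingul-Post-ventral", "G_cuneus",
    "G_front_inf-Opercular", "G_front_inf-Orbital", "G_front_inf-Triangul",
    "G_front_middle", "G_front_sup", "G_Ins_lg_and_S_cent_ins",
    "G_insular_short", "G_occipital_middle", "G_occipital_sup",
    "G_oc-temp_lat-fusifor", "G_oc-temp_med-Lingual", "G_oc-temp_med-Parahip",
    "G_orbital", "G_pariet_inf-Angular", "G_pariet_inf-Supramar",
    "G_parietal_sup", "G_postcentral", "G_precentral", "G_precuneus",
    "G_rectus", "G_subcallosal", "G_temp_sup-G_T_transv",
    "G_temp_sup-Lateral", "G_temp_sup-Plan_polar", "G_temp_sup-Plan_tempo",
    "G_temporal_inf", "G_temporal_middle", "Lat_Fis-ant-Horizont",
    "Lat_Fis-ant-Vertical", "Lat_Fis-post", "Pole_occipital",
    "Pole_temporal", "S_calcarine", "S_central", "S_cingul-Marginalis",
    "S_circular_insula_ant", "S_circular_insula_inf",
    "S_circular_insula_sup", "S_collat_transv_ant", "S_collat_transv_post",
    "S_front_inf", "S_front_middle", "S_front_sup", "S_interm_prim-Jensen",
    "S_intrapariet_and_P_trans", "S_oc_middle_and_Lunatus",
    "S_oc_sup_and_transversal", "S_occipital_ant", "S_oc-temp_lat",
    "S_oc-temp_med_and_Lingual", "S_orbital_lateral",
    "S_orbital_med-olfact", "S_orbital-H_Shaped", "S_parieto_occipital",
    "S_pericallosal", "S_postcentral", "S_precentral-inf-part",
    "S_precentral-sup-part", "S_suborbital", "S_subparietal",
    "S_temporal_inf", "S_temporal_sup", "S_temporal_transverse")
}

subcortical_labels <- function() {
  bilat <- c("Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
             "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC",
             "Cerebellum-Cortex", "Cerebellum-White-Matter",
             "Lateral-Ventricle", "Inf-Lat-Vent", "choroid-plexus")
  c(paste0("Left-", bilat), paste0("Right-", bilat),
    "Brain-Stem", "CSF", "3rd-Ventricle", "4th-Ventricle", "Optic-Chiasm")
}

lobe_tag <- function(label) {
  frontal <- "front|precentral|orbital|rectus|subcallosal|paracentral|central_ins|suborbital|frontomargin|transv_frontopol"
  parietal <- "pariet|postcentral|precuneus|supramar|angular|subparietal|interm_prim|cingul-Marginalis"
  temporal <- "temp|fusifor|Parahip|Lat_Fis"
  occipital <- "occipital|cuneus|calcarine|Lingual|oc_|oc-|Pole_occipital"
  insular <- "insula|Ins_lg"
  cingulate <- "cingul|pericallosal"
  ifelse(grepl(insular, label), "insula",
  ifelse(grepl(cingulate, label), "cingulate",
  ifelse(grepl(occipital, label), "occipital",
  ifelse(grepl(temporal, label), "temporal",
  ifelse(grepl(parietal, label), "parietal",
  ifelse(grepl(frontal, label), "frontal", "other"))))))
}

#' Default ROI dictionary (327 regions)
#'
#' @param modality optional filter: one of \code{"thickness"},
#'   \code{"area"}, \code{"volume"}; default returns all three.
#' @return data frame with columns \code{roi}, \code{hemisphere},
#'   \code{modality}, \code{lobe}.
#' @export
#' @examples
#' d <- default_roi_dictionary()
#' table(d$modality) # 148 thickness, 148 area, 31 volume
default_roi_dictionary <- function(modality = NULL) {
  ctx <- destrieux_labels()
  cortical <- function(mod) data.frame(
    roi = c(paste0("lh_", ctx), paste0("rh_", ctx)),
    hemisphere = rep(c("left", "right"), each = length(ctx)),
    modality = mod,
    lobe = rep(lobe_tag(ctx), 2L),
    stringsAsFactors = FALSE)
  sub <- subcortical_labels()
  subc <- data.frame(
    roi = sub,
    hemisphere = ifelse(startsWith(sub, "Left-"), "left",
                 ifelse(startsWith(sub, "Right-"), "right", "none")),
    modality = "volume",
    lobe = "subcortical",
    stringsAsFactors = FALSE)
  out <- rbind(cortical("thickness"), cortical("area"), subc)
  rownames(out) <- NULL
  if (!is.null(modality)) {
    modality <- match.arg(modality, c("thickness", "area", "volume"))
    out <- out[out$modality == modality, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

validate_roi_dictionary <- function(dictionary) {
  need <- c("roi", "hemisphere", "modality", "lobe")
  miss <- setdiff(need, names(dictionary))
  if (length(miss))
    stop_field("dictionary", paste("missing columns:", paste(miss, collapse = ", ")))
  key <- paste(dictionary$modality, dictionary$roi)
  if (anyDuplicated(key))
    stop_field("dictionary", "duplicate (modality, roi) entries")
  invisible(dictionary)
}
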