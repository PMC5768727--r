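# The 116-region Automated Anatomical Labeling atlas, in its conventional
# order: 45 left/right cortical-subcortical pairs, 9 cerebellar pairs, 8
# vermis regions.

#' AAL-116 region labels
#'
#' The standard label set of the 116-region Automated Anatomical Labeling
#' parcellation, in atlas order with `_L`/`_R` hemisphere suffixes.
#'
#' @return character vector of 116 region names.
#' @export
aal_labels <- function() {
  pairs <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf",
    "Cerebelum_Crus1", "Cerebelum_Crus2", "Cerebelum_3", "Cerebelum_4_5",
    "Cerebelum_6", "Cerebelum_7b", "Cerebelum_8", "Cerebelum_9",
    "Cerebelum_10")
  vermis <- c("Vermis_1_2", "Vermis_3", "Vermis_4_5", "Vermis_6",
              "Vermis_7", "Vermis_8", "Vermis_9", "Vermis_10")
  c(as.vector(t(cbind(paste0(pairs, "_L"), paste0(pairs, "_R")))), vermis)
}

# map from the short region labels common in the musicianship-decoding
# literature to AAL stems
.aal_short_map <- c(
  STG = "Temporal_Sup", MTG = "Temporal_Mid", ITG = "Temporal_Inf",
  ACG = "Cingulum_Ant", MCG = "Cingulum_Mid", PCG = "Cingulum_Post",
  IFGoper = "Frontal_Inf_Oper", IFGtri = "Frontal_Inf_Tri",
  IFGorb = "Frontal_Inf_Orb", MFG = "Frontal_Mid",
  MFGorb = "Frontal_Mid_Orb", SFG = "Frontal_Sup", CAU = "Caudate",
  PUT = "Putamen", THA = "Thalamus", HES = "Heschl", INS = "Insula")

#' Resolve short region labels to AAL names
#'
#' Maps literature-style short labels (e.g. `"STG"`, `"ACG"`, `"IFGoper"`,
#' `"CAU"`, or hemisphere-qualified forms like `"rSTG"` / `"STG_L"`) to the
#' full AAL label(s). Unqualified labels expand to both hemispheres.
#'
#' @param short character vector of short labels.
#' @return character vector of AAL labels.
#' @export
aal_lookup <- function(short) {
  out <- lapply(short, function(s) {
    hemi <- NULL
    stem <- s
    if (grepl("^[lr]", s) && substring(s, 2L) %in% names(.aal_short_map)) {
      hemi <- toupper(substring(s, 1L, 1L))
      stem <- substring(s, 2L)
    } else if (grepl("_[LR]$", s)) {
      hemi <- sub("^.*_", "", s)
      stem <- sub("_[LR]$", "", s)
    }
    if (!stem %in% names(.aal_short_map))
      stop("aal_lookup: unknown short label '", s, "'; known labels: ",
           paste(names(.aal_short_map), collapse = ", "))
    full <- .aal_short_map[[stem]]
    if (is.null(hemi)) paste0(full, c("_L", "_R")) else paste0(full, "_", hemi)
  })
  unlist(out)
}
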