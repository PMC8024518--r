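# Atlas node tables: fixed node ordering for all matrices in the package.

# 74 cortical labels per hemisphere (Destrieux 2010 / FreeSurfer a2009s naming)
# with a conventional lobe assignment. Sulci straddling lobe boundaries are
# assigned to the lobe holding most of their extent.
.destrieux_cortical <- function() {
  lab <- c(
    "G_and_S_frontomargin"      = "frontal",
    "G_and_S_occipital_inf"     = "occipital",
    "G_and_S_paracentral"       = "frontal",
    "G_and_S_subcentral"        = "frontal",
    "G_and_S_transv_frontopol"  = "frontal",
    "G_and_S_cingul-Ant"        = "limbic",
    "G_and_S_cingul-Mid-Ant"    = "limbic",
    "G_and_S_cingul-Mid-Post"   = "limbic",
    "G_cingul-Post-dorsal"      = "limbic",
    "G_cingul-Post-ventral"     = "limbic",
    "G_cuneus"                  = "occipital",
    "G_front_inf-Opercular"     = "frontal",
    "G_front_inf-Orbital"       = "frontal",
    "G_front_inf-Triangul"      = "frontal",
    "G_front_middle"            = "frontal",
    "G_front_sup"               = "frontal",
    "G_Ins_lg_and_S_cent_ins"   = "insular",
    "G_insular_short"           = "insular",
    "G_occipital_middle"        = "occipital",
    "G_occipital_sup"           = "occipital",
    "G_oc-temp_lat-fusifor"     = "temporal",
    "G_oc-temp_med-Lingual"     = "occipital",
    "G_oc-temp_med-Parahip"     = "limbic",
    "G_orbital"                 = "frontal",
    "G_pariet_inf-Angular"      = "parietal",
    "G_pariet_inf-Supramar"     = "parietal",
    "G_parietal_sup"            = "parietal",
    "G_postcentral"             = "parietal",
    "G_precentral"              = "frontal",
    "G_precuneus"               = "parietal",
    "G_rectus"                  = "frontal",
    "G_subcallosal"             = "limbic",
    "G_temp_sup-G_T_transv"     = "temporal",
    "G_temp_sup-Lateral"        = "temporal",
    "G_temp_sup-Plan_polar"     = "temporal",
    "G_temp_sup-Plan_tempo"     = "temporal",
    "G_temporal_inf"            = "temporal",
    "G_temporal_middle"         = "temporal",
    "Lat_Fis-ant-Horizont"      = "frontal",
    "Lat_Fis-ant-Vertical"      = "frontal",
    "Lat_Fis-post"              = "temporal",
    "Pole_occipital"            = "occipital",
    "Pole_temporal"             = "temporal",
    "S_calcarine"               = "occipital",
    "S_central"                 = "frontal",
    "S_cingul-Marginalis"       = "limbic",
    "S_circular_insula_ant"     = "insular",
    "S_circular_insula_inf"     = "insular",
    "S_circular_insula_sup"     = "insular",
    "S_collat_transv_ant"       = "temporal",
    "S_collat_transv_post"      = "occipital",
    "S_front_inf"               = "frontal",
    "S_front_middle"            = "frontal",
    "S_front_sup"               = "frontal",
    "S_interm_prim-Jensen"      = "parietal",
    "S_intrapariet_and_P_trans" = "parietal",
    "S_oc_middle_and_Lunatus"   = "occipital",
    "S_oc_sup_and_transversal"  = "occipital",
    "S_occipital_ant"           = "occipital",
    "S_oc-temp_lat"             = "temporal",
    "S_oc-temp_med_and_Lingual" = "temporal",
    "S_orbital_lateral"         = "frontal",
    "S_orbital_med-olfact"      = "frontal",
    "S_orbital-H_Shaped"        = "frontal",
    "S_parieto_occipital"       = "occipital",
    "S_pericallosal"            = "limbic",
    "S_postcentral"             = "parietal",
    "S_precentral-inf-part"     = "frontal",
    "S_precentral-sup-part"     = "frontal",
    "S_suborbital"              = "frontal",
    "S_subparietal"             = "parietal",
    "S_temporal_inf"            = "temporal",
    "S_temporal_sup"            = "temporal",
    "S_temporal_transverse"     = "temporal"
  )
  tibble::tibble(name = names(lab), lobe = unname(lab))
}

.subcortical <- function() {
  tibble::tibble(
    name = c("Thalamus", "Caudate", "Putamen", "Pallidum",
             "Hippocampus", "Amygdala", "Accumbens"),
    lobe = c("other", "basal_ganglia", "basal_ganglia", "basal_ganglia",
             "limbic", "limbic", "basal_ganglia")
  )
}

.valid_lobes <- c("frontal", "parietal", "temporal", "occipital",
                  "limbic", "insular", "basal_ganglia", "other")

#' Default 162-node cortical + subcortical atlas table
#'
#' Node table anchoring the row/column order of every connectivity matrix:
#' 148 cortical regions (74 Destrieux-atlas labels per hemisphere) followed by
#' 14 subcortical regions (7 per hemisphere). Node ids are 0-based; the `scale`
#' column is the per-ROI multiplier applied to conditional connection
#' probabilities (1 unless the user supplies a seed-size scaling).
#'
#' @return A tibble with columns `node_id`, `name`, `hemisphere`, `lobe`,
#'   `is_cortical`, `scale`.
#' @examples
#' atlas <- destrieux_atlas()
#' table(atlas$is_cortical)
#' @export
destrieux_atlas <- function() {
  cort <- .destrieux_cortical()
  sub <- .subcortical()
  nodes <- dplyr::bind_rows(
    tibble::tibble(name = paste0("lh_", cort$name), hemisphere = "left",
                   lobe = cort$lobe, is_cortical = TRUE),
    tibble::tibble(name = paste0("rh_", cort$name), hemisphere = "right",
                   lobe = cort$lobe, is_cortical = TRUE),
    tibble::tibble(name = paste0("lh_", sub$name), hemisphere = "left",
                   lobe = sub$lobe, is_cortical = FALSE),
    tibble::tibble(name = paste0("rh_", sub$name), hemisphere = "right",
                   lobe = sub$lobe, is_cortical = FALSE)
  )
  nodes$node_id <- seq_len(nrow(nodes)) - 1L
  nodes$scale <- 1
  validate_atlas(nodes[, c("node_id", "name", "hemisphere", "lobe",
                           "is_cortical", "scale")])
}

#' Generic atlas for synthetic networks of arbitrary size
#'
#' Used by the synthetic-cohort generator when `n_nodes` differs from the
#' default 162-node parcellation. Nodes are split into two pseudo-hemispheres
#' and lobes are cycled so lobe-level summaries stay exercisable.
#'
#' @param n_nodes Number of nodes.
#' @return An atlas tibble with the same schema as [destrieux_atlas()].
#' @export
synthetic_atlas <- function(n_nodes) {
  stopifnot(n_nodes >= 1)
  ids <- seq_len(n_nodes) - 1L
  tibble::tibble(
    node_id = ids,
    name = sprintf("node_%03d", ids),
    hemisphere = ifelse(ids < n_nodes / 2, "left", "right"),
    lobe = .valid_lobes[(ids %% length(.valid_lobes)) + 1L],
    is_cortical = TRUE,
    scale = 1
  )
}

#' Validate an atlas node table
#'
#' Checks the invariants every downstream stage relies on: contiguous 0-based
#' node ids, unique names, known hemisphere and lobe levels.
#'
#' @param atlas A data frame with the [destrieux_atlas()] schema.
#' @return The atlas as a tibble, invisibly unchanged, or an error.
#' @export
validate_atlas <- function(atlas) {
  atlas <- tibble::as_tibble(atlas)
  req <- c("node_id", "name", "hemisphere", "lobe", "is_cortical")
  missing <- setdiff(req, names(atlas))
  if (length(missing) > 0) {
    abort(paste0("atlas is missing column(s): ", paste(missing, collapse = ", ")),
          class = "netsweep_schema_error")
  }
  if (!identical(as.integer(atlas$node_id), seq_len(nrow(atlas)) - 1L)) {
    abort("atlas node_id must be 0..N-1 with no gaps, in order",
          class = "netsweep_schema_error")
  }
  if (anyDuplicated(atlas$name) > 0) {
    abort("atlas names must be unique", class = "netsweep_schema_error")
  }
  if (!all(atlas$hemisphere %in% c("left", "right", "midline"))) {
    abort("atlas hemisphere must be left/right/midline",
          class = "netsweep_schema_error")
  }
  if (!all(atlas$lobe %in% .valid_lobes)) {
    abort(paste0("unknown lobe label(s): ",
                 paste(setdiff(atlas$lobe, .valid_lobes), collapse = ", ")),
          class = "netsweep_schema_error")
  }
  if (is.null(atlas$scale)) atlas$scale <- 1
  atlas
}
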