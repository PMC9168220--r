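# Desikan-Killiany cortical labels in standard aparc.stats order (34 per
# hemisphere). The non-cortical block is Brain-Stem followed by the left then
# right aseg structures, so region indices match the conventional 87-parcel
# numbering (e.g. left thalamus = region 71, 1-based).
.dk_cortical <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula")

.dk_lobe <- c(
  "temporal", "cingulate", "frontal", "occipital",
  "temporal", "temporal", "parietal", "temporal",
  "cingulate", "occipital", "frontal", "occipital",
  "frontal", "temporal", "temporal", "frontal",
  "frontal", "frontal", "frontal", "occipital",
  "parietal", "cingulate", "frontal", "parietal",
  "cingulate", "frontal", "frontal",
  "parietal", "temporal", "parietal", "frontal",
  "temporal", "temporal", "insula")

.aseg_structures <- c(
  "Cerebellum-Cortex", "Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
  "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC")

#' Region atlas for the 87-parcel morphometric parcellation
#'
#' Builds the region table used throughout the pipeline: 68 Desikan-Killiany
#' cortical parcels (34 per hemisphere, described by cortical thickness,
#' surface area and mean curvature) followed by 19 non-cortical parcels
#' (brainstem, subcortical nuclei and cerebellum, described by volume).
#'
#' @param n_cortical,n_noncortical Region counts. The defaults give the
#'   standard 87-parcel atlas; smaller values produce a reduced synthetic
#'   atlas (generic region names) for simulation studies.
#' @return A data.frame of class `region_atlas` with columns `region_id`
#'   (0-based), `name`, `hemisphere` (`"left"`, `"right"` or `"midline"`),
#'   `lobe` and `cortical` (logical).
#' @examples
#' atlas <- region_atlas()
#' table(atlas$cortical)
#' atlas$name[c(15, 20, 71)]
#' @export
region_atlas <- function(n_cortical = 68L, n_noncortical = 19L) {
  n_cortical <- as.integer(n_cortical)
  n_noncortical <- as.integer(n_noncortical)
  if (n_cortical < 2L || n_noncortical < 0L)
    stop("need at least 2 cortical regions and a nonnegative non-cortical count")
  if (n_cortical == 68L) {
    cort_names <- c(paste0("lh-", .dk_cortical), paste0("rh-", .dk_cortical))
    cort_hemi <- rep(c("left", "right"), each = 34L)
    cort_lobe <- rep(.dk_lobe, 2L)
  } else {
    cort_names <- sprintf("ctx-%03d", seq_len(n_cortical))
    cort_hemi <- rep("midline", n_cortical)
    cort_lobe <- rep("synthetic", n_cortical)
  }
  if (n_noncortical == 19L) {
    nc_names <- c("Brain-Stem",
                  paste0("Left-", .aseg_structures),
                  paste0("Right-", .aseg_structures))
    nc_hemi <- c("midline", rep("left", 9L), rep("right", 9L))
    nc_lobe <- c("brainstem", rep(c("cerebellum", rep("subcortical", 8L)), 2L))
  } else if (n_noncortical > 0L) {
    nc_names <- sprintf("subctx-%03d", seq_len(n_noncortical))
    nc_hemi <- rep("midline", n_noncortical)
    nc_lobe <- rep("synthetic", n_noncortical)
  } else {
    nc_names <- character(0)
    nc_hemi <- character(0)
    nc_lobe <- character(0)
  }
  atlas <- data.frame(
    region_id = seq_len(n_cortical + n_noncortical) - 1L,
    name = c(cort_names, nc_names),
    hemisphere = c(cort_hemi, nc_hemi),
    lobe = c(cort_lobe, nc_lobe),
    cortical = c(rep(TRUE, n_cortical), rep(FALSE, n_noncortical)),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(atlas$name))
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}
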