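#' Canonical brain region vocabulary
#'
#' The eleven dissected regions used throughout the package, in anatomical
#' order, plus the derived `"Whole Brain"` pseudo-region (the sum of all
#' dissected regions except the olfactory bulb, see
#' [aggregate_whole_brain()]).
#'
#' @param include_whole_brain if `TRUE`, append `"Whole Brain"` to the list.
#' @return character vector of region names.
#' @export
#' @examples
#' brain_regions()
brain_regions <- function(include_whole_brain = FALSE) {
  r <- c(
    "Olfactory Bulb", "Striatum", "Frontal Cortex", "Hypothalamus",
    "Hippocampus", "Thalamus", "Parietal Cortex", "Occipital Cortex",
    "Cerebellum", "Midbrain", "Pons/Medulla"
  )
  if (include_whole_brain) c(r, "Whole Brain") else r
}

.WHOLE_BRAIN <- "Whole Brain"
.OLFACTORY <- "Olfactory Bulb"

.group_key <- function(genotype, sex) paste(genotype, sex, sep = ".")
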