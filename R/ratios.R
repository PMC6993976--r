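# Brain/serum ratios, the albumin vascular-space correction, and whole-brain
# aggregation.

#' Brain/serum ratio
#'
#' Tissue radioactivity per gram divided by serum radioactivity per
#' microliter: `(tissue_cpm / weight_g) / (serum_cpm / aliquot_ul)`, in uL/g.
#' This is the apparent volume of serum whose activity is contained in one
#' gram of tissue.
#'
#' @param tissue_cpm counts in the tissue sample (>= 0).
#' @param tissue_weight_g tissue wet weight, g (> 0).
#' @param serum_cpm counts in the serum aliquot (> 0).
#' @param aliquot_ul aliquot volume, uL (> 0, default 50).
#' @return ratio(s) in uL/g. Vectorised over all arguments.
#' @export
#' @examples
#' brain_serum_ratio(500, 0.1, 5000, 50)  # 50 uL/g
brain_serum_ratio <- function(tissue_cpm, tissue_weight_g, serum_cpm,
                              aliquot_ul = 50) {
  if (any(!is.finite(tissue_weight_g)) || any(tissue_weight_g <= 0))
    stop("tissue weight must be positive", call. = FALSE)
  if (any(!is.finite(serum_cpm)) || any(serum_cpm <= 0))
    stop("serum counts must be positive", call. = FALSE)
  if (any(aliquot_ul <= 0))
    stop("aliquot volume must be positive", call. = FALSE)
  if (any(tissue_cpm < 0))
    stop("tissue counts must be >= 0", call. = FALSE)
  (tissue_cpm / tissue_weight_g) / (serum_cpm / aliquot_ul)
}

#' Vascular-space-corrected brain/serum ratio
#'
#' Subtracts the co-injected vascular marker's brain/serum ratio from the
#' test tracer's, removing the contribution of tracer still in the vascular
#' blood. Negative results are legitimate (sampling noise at early times can
#' push the corrected ratio below zero) and are preserved, never clamped.
#'
#' @param tracer_bs test-tracer B/S ratio(s), uL/g.
#' @param marker_bs vascular-marker B/S ratio(s), uL/g.
#' @return delta B/S, uL/g.
#' @export
delta_bs <- function(tracer_bs, marker_bs) {
  stopifnot(all(is.finite(tracer_bs)), all(is.finite(marker_bs)))
  tracer_bs - marker_bs
}

#' Whole-brain aggregation
#'
#' Builds the `"Whole Brain"` pseudo-region by summing weights and counts
#' (each isotope separately) over the dissected regions of each animal,
#' excluding the olfactory bulb by default. Because counts and weights are
#' summed before the ratio is taken, the whole-brain B/S ratio equals the
#' region-weight-weighted mean of the included regional ratios.
#'
#' @param regions data frame with columns `id`, `region`, `weight_g`,
#'   `tracer_cpm`, `marker_cpm` (the `regions` table of a `study_dataset`).
#' @param exclude region name(s) left out of the sum.
#' @return data frame with one `"Whole Brain"` row per animal id.
#' @export
aggregate_whole_brain <- function(regions, exclude = .OLFACTORY) {
  keep <- regions[!(regions$region %in% exclude), , drop = FALSE]
  if (!nrow(keep))
    stop("no regions left to aggregate after excluding: ",
         paste(exclude, collapse = ", "), call. = FALSE)
  ids <- unique(regions$id)
  agg <- function(v) tapply(v, factor(keep$id, levels = ids), sum)
  out <- data.frame(
    id = ids,
    region = .WHOLE_BRAIN,
    weight_g = as.numeric(agg(keep$weight_g)),
    tracer_cpm = as.numeric(agg(keep$tracer_cpm)),
    marker_cpm = as.numeric(agg(keep$marker_cpm)),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$weight_g))
    stop("animal(s) with no regions after exclusion: ",
         paste(out$id[is.na(out$weight_g)], collapse = ", "), call. = FALSE)
  rownames(out) <- NULL
  out
}
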