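#' Region atlas tables
#'
#' A region atlas maps matrix columns to anatomical labels. It is a
#' `data.frame` with columns `region_id` (contiguous 0-based integer ids;
#' matrix column `k` corresponds to `region_id == k - 1`), `name`,
#' `hemisphere` (`"left"` or `"right"`) and `lobe` (one of the lobe
#' categories used for hub summaries).
#'
#' @param region_id contiguous 0-based integer ids.
#' @param name character region labels, unique.
#' @param hemisphere `"left"`/`"right"` per region.
#' @param lobe lobe category per region.
#' @return a validated `region_atlas` data.frame.
#' @seealso [synthetic_atlas()], [summarize_hubs()]
#' @export
region_atlas <- function(region_id, name, hemisphere, lobe) {
  atlas <- data.frame(
    region_id = as.integer(region_id),
    name = as.character(name),
    hemisphere = as.character(hemisphere),
    lobe = as.character(lobe),
    stringsAsFactors = FALSE
  )
  validate_atlas(atlas)
}

#' @rdname region_atlas
#' @param atlas a candidate atlas data.frame.
#' @export
validate_atlas <- function(atlas) {
  req <- c("region_id", "name", "hemisphere", "lobe")
  if (!all(req %in% names(atlas)))
    stop_covnet("atlas must have columns: ", paste(req, collapse = ", "))
  n <- nrow(atlas)
  if (!identical(sort(atlas$region_id), 0:(n - 1L)))
    stop_covnet("atlas region_ids must be contiguous 0-based integers")
  if (anyDuplicated(atlas$name))
    stop_covnet("atlas region names must be unique")
  if (!all(atlas$hemisphere %in% c("left", "right")))
    stop_covnet("atlas hemisphere must be 'left' or 'right'")
  if (!all(atlas$lobe %in% covnet_lobes()))
    stop_covnet("atlas lobe must be one of: ", paste(covnet_lobes(), collapse = ", "))
  atlas <- atlas[order(atlas$region_id), , drop = FALSE]
  rownames(atlas) <- NULL
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}

#' @rdname region_atlas
#' @export
covnet_lobes <- function() {
  c("frontal", "temporal", "parietal", "occipital",
    "limbic", "insular", "parieto-frontal", "occipito-temporal")
}

#' Synthetic region atlas
#'
#' Builds an anatomy-free atlas for simulated cohorts: regions are split
#' evenly into left and right hemispheres and lobes are assigned
#' round-robin within each hemisphere, which is enough to exercise the
#' hemisphere/lobe hub summaries without real parcellation data.
#'
#' @param n_regions number of regions (>= 2).
#' @return a `region_atlas` with `n_regions` rows.
#' @examples
#' synthetic_atlas(8)
#' @export
synthetic_atlas <- function(n_regions) {
  if (n_regions < 2) stop_covnet("n_regions must be >= 2")
  n_left <- ceiling(n_regions / 2)
  hemi <- c(rep("left", n_left), rep("right", n_regions - n_left))
  lobes <- covnet_lobes()
  lobe <- c(lobes[(seq_len(n_left) - 1L) %% length(lobes) + 1L],
            lobes[(seq_len(n_regions - n_left) - 1L) %% length(lobes) + 1L])
  side <- ifelse(hemi == "left", "L", "R")
  idx <- stats::ave(seq_len(n_regions), hemi, FUN = seq_along)
  region_atlas(
    region_id = 0:(n_regions - 1L),
    name = sprintf("%s_region_%03d", side, idx),
    hemisphere = hemi,
    lobe = lobe
  )
}
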