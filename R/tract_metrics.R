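# Bundle-wise aggregation of voxel maps and WMH volumetrics.

#' Aggregate a scalar map over left and right bundle masks
#'
#' Unweighted mean of in-mask voxels per side, and the bilateral mean of the
#' two side means (left/right measures are averaged for analysis).
#'
#' @param map 3D numeric array.
#' @param left_mask,right_mask logical arrays on the same grid.
#' @return named numeric: `left`, `right`, `bilateral`.
#' @export
aggregate_tract <- function(map, left_mask, right_mask) {
  stopifnot(identical(dim(map), dim(left_mask)), identical(dim(map), dim(right_mask)))
  if (!any(left_mask)) stop("aggregate_tract: empty left mask")
  if (!any(right_mask)) stop("aggregate_tract: empty right mask")
  l <- mean(map[left_mask])
  r <- mean(map[right_mask])
  c(left = l, right = r, bilateral = (l + r) / 2)
}

#' Percent change of a corrected measure relative to its conventional value
#'
#' `((corrected - conventional) / conventional) * 100`.
#'
#' @param conventional conventional DTI measure value (nonzero).
#' @param corrected free-water-corrected value.
#' @return percent change (vectorized).
#' @export
percent_change <- function(conventional, corrected) {
  if (any(conventional == 0)) stop("percent_change: conventional measure is zero")
  (corrected - conventional) / conventional * 100
}

#' White-matter-hyperintensity volumetrics
#'
#' Total WMH volume in ml, the WM-normalized log-transformed burden
#' `ln(WMH volume / WM volume + eps)` (with `eps` = one voxel volume over the
#' WM volume, keeping lesion-free subjects finite), the bundle's WMH coverage
#' `100 * |bundle & WMH| / |bundle|`, and the bundle volume as a percentage of
#' the intracranial volume.
#'
#' @param wmh_mask,wm_mask,bundle_mask,icv_mask logical arrays on one grid.
#' @param voxel_volume volume of one voxel in ml.
#' @return named numeric: `wmh_ml`, `wmh_log`, `wmh_bundle_pct`,
#'   `bundle_pctiv`.
#' @export
wmh_volumetrics <- function(wmh_mask, wm_mask, bundle_mask, icv_mask,
                            voxel_volume = 0.008) {
  if (!any(wm_mask)) stop("wmh_volumetrics: empty white-matter mask")
  if (!any(icv_mask)) stop("wmh_volumetrics: empty intracranial mask")
  n_wmh <- sum(wmh_mask)
  n_wm <- sum(wm_mask)
  n_bundle <- sum(bundle_mask)
  eps <- 1 / n_wm
  c(wmh_ml = n_wmh * voxel_volume,
    wmh_log = log(n_wmh / n_wm + eps),
    wmh_bundle_pct = if (n_bundle > 0) 100 * sum(bundle_mask & wmh_mask) / n_bundle else NA_real_,
    bundle_pctiv = 100 * n_bundle / sum(icv_mask))
}

#' Per-subject tract summary from fitted maps
#'
#' Aggregates every conventional and corrected map over the bundle masks and
#' appends WMH volumetrics and per-measure percent changes, producing one row
#' of the cohort table.
#'
#' @param dti output of [fit_dti_volume()].
#' @param fw output of [fit_fw_volume()].
#' @param phantom the `phantom_volume` supplying masks and voxel size.
#' @return one-row data.frame: `<measure>_left/right` and bilateral
#'   `<measure>` for fa, md, rd, ad, fat, mdt, rdt, adt, fw; volumetrics;
#'   `pct_change_<measure>` for the four tensor scalars.
#' @export
tract_summary <- function(dti, fw, phantom) {
  lm_ <- phantom$masks$left_bundle
  rm_ <- phantom$masks$right_bundle
  maps <- c(dti[c("fa", "md", "rd", "ad")], fw[c("fat", "mdt", "rdt", "adt", "fw")])
  row <- list()
  for (m in names(maps)) {
    agg <- aggregate_tract(maps[[m]], lm_, rm_)
    row[[paste0(m, "_left")]] <- agg[["left"]]
    row[[paste0(m, "_right")]] <- agg[["right"]]
    row[[m]] <- agg[["bilateral"]]
  }
  vol <- wmh_volumetrics(phantom$masks$wmh, phantom$masks$white_matter,
                         lm_ | rm_, phantom$masks$intracranial,
                         voxel_volume = phantom$voxel_size^3 / 1000)
  row <- c(row, as.list(vol))
  for (m in c("fa", "md", "rd", "ad")) {
    row[[paste0("pct_change_", m)]] <-
      percent_change(row[[m]], row[[paste0(m, "t")]])
  }
  as.data.frame(row)
}
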