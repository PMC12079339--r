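# Atlas cosine-similarity decomposition of pattern maps and relative
# regional contributions across models.

parc_labels <- function(parc, level) {
  if (level == "roi") {
    list(lab = parc$roi,
         table = data.frame(label = parc$roi_table$label,
                            name = parc$roi_table$roi_name))
  } else {
    list(lab = parc$network,
         table = data.frame(label = parc$network_table$network_label,
                            name = parc$network_table$network_name))
  }
}

#' Regional cosine similarity of a pattern map
#'
#' The map is rectified to absolute values (all voxels maintained as positive
#' for interpretation), then for each region the cosine between the
#' rectified map restricted to the region and the region indicator is
#' computed — the map's concentration in that region
#' (`sum(|m|) / (||m|| * sqrt(n))` over the region's voxels). A region where
#' the map is identically zero gets cosine 0; a region with no voxels is
#' reported as missing. Ribbon values are the cosines normalized to the
#' maximum across regions.
#'
#' @param map Numeric voxel vector (weight or core-system map), or a
#'   `core_system_map`.
#' @param parc A `parcellation` on the same voxel space.
#' @param level `"roi"` or `"network"`.
#' @return Data frame (class `similarity_decomposition`) with `label`,
#'   `name`, `n_voxels`, `cosine`, `ribbon`.
#' @export
regional_cosine <- function(map, parc, level = c("roi", "network")) {
  level <- match.arg(level)
  if (inherits(map, "core_system_map")) map <- map$weights
  if (inherits(map, "linear_pattern_model")) map <- map$weights
  pl <- parc_labels(parc, level)
  if (length(map) != length(pl$lab))
    stopf("map has %d voxels but parcellation labels %d", length(map),
          length(pl$lab))
  m <- abs(map)
  out <- pl$table
  out$n_voxels <- as.integer(table(factor(pl$lab, levels = out$label)))
  out$cosine <- vapply(out$label, function(l) {
    idx <- pl$lab == l
    if (!any(idx)) return(NA_real_)
    v <- m[idx]
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) return(0)
    sum(v) / (nrm * sqrt(sum(idx)))
  }, 0)
  mx <- max(out$cosine, na.rm = TRUE)
  out$ribbon <- if (mx > 0) out$cosine / mx else out$cosine
  class(out) <- c("similarity_decomposition", "data.frame")
  out
}

#' Relative regional contributions of several pattern maps
#'
#' Default (`mode = "argmax"`, following the voxel-winner definition): within
#' each region every voxel is assigned to the map with the highest rectified
#' value there (ties split equally) and each map's share is the percentage of
#' region voxels it wins; shares sum to 100 per region. A region where every
#' map is identically zero is reported missing. `mode = "cosine_ratio"`
#' instead splits the region in proportion to each map's regional cosine.
#'
#' @param maps Named list of >= 2 numeric voxel vectors (or
#'   `core_system_map` / `linear_pattern_model` objects).
#' @param parc A `parcellation`.
#' @param level `"roi"` or `"network"`.
#' @param mode `"argmax"` (default) or `"cosine_ratio"`.
#' @return Long data frame with `label`, `name`, `model`, `share` (percent).
#' @export
contribution_shares <- function(maps, parc, level = c("roi", "network"),
                                mode = c("argmax", "cosine_ratio")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (length(maps) < 2) stopf("need at least 2 maps")
  if (is.null(names(maps)) || any(names(maps) == ""))
    names(maps) <- sprintf("map%d", seq_along(maps))
  vals <- lapply(maps, function(m) {
    if (inherits(m, "core_system_map")) m <- m$weights
    if (inherits(m, "linear_pattern_model")) m <- m$weights
    abs(as.numeric(m))
  })
  V <- length(vals[[1]])
  if (any(vapply(vals, length, 0L) != V)) stopf("maps are not aligned")
  pl <- parc_labels(parc, level)
  if (length(pl$lab) != V) stopf("maps and parcellation are not aligned")
  M <- do.call(cbind, vals)
  res <- expand.grid(label = pl$table$label, model = names(maps),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$name <- pl$table$name[match(res$label, pl$table$label)]
  res$share <- NA_real_
  if (mode == "argmax") {
    mx <- do.call(pmax, vals)
    winners <- M == mx                       # ties: multiple TRUE per row
    credit <- winners / rowSums(winners)
    for (l in pl$table$label) {
      idx <- pl$lab == l
      if (!any(idx)) next
      if (all(mx[idx] == 0)) next            # all-zero region: missing
      sh <- 100 * colSums(credit[idx, , drop = FALSE]) / sum(idx)
      res$share[res$label == l] <- sh[res$model[res$label == l]]
    }
  } else {
    for (l in pl$table$label) {
      idx <- pl$lab == l
      if (!any(idx)) next
      cs <- vapply(vals, function(v) {
        nrm <- sqrt(sum(v[idx]^2))
        if (nrm == 0) 0 else sum(v[idx]) / (nrm * sqrt(sum(idx)))
      }, 0)
      if (all(cs == 0)) next
      sh <- 100 * cs / sum(cs)
      res$share[res$label == l] <- sh[res$model[res$label == l]]
    }
  }
  class(res) <- c("similarity_decomposition", "data.frame")
  res
}
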