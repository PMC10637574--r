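#' Focality of a modulation-depth map
#'
#' Cube root of the brain volume whose MD exceeds half the MD at the target
#' location, in cm. Smaller values mean more focal stimulation. The measure
#' is invariant to rescaling the map, since the threshold is relative.
#'
#' @param md a `ti_mdmap` (or a list with `values` and `node_volume`).
#' @param target_node index of the target brain node; its MD must be > 0.
#' @return focality length in cm.
#' @export
focality <- function(md, target_node) {
  md_t <- md$values[target_node]
  if (is.na(md_t) || md_t <= 0)
    stop("MD at the target is zero: focality undefined")
  vol_mm3 <- sum(md$node_volume * (md$values > 0.5 * md_t))
  (vol_mm3 / 1000)^(1 / 3)  # mm^3 -> cm^3, then cube root
}

# 6-connected components of a logical set of brain nodes on the regular grid.
# Returns an integer component label per selected node (0 elsewhere).
grid_components <- function(sel_brain, brain_idx, dims) {
  full <- logical(prod(dims))
  full[brain_idx[sel_brain]] <- TRUE
  comp <- integer(prod(dims))
  strides <- c(1L, dims[1], dims[1] * dims[2])
  ix <- arrayInd(brain_idx, dims)
  pos <- integer(prod(dims)); pos[brain_idx] <- seq_along(brain_idx)
  label <- 0L
  for (start in brain_idx[sel_brain]) {
    if (comp[start] != 0L) next
    label <- label + 1L
    queue <- start
    comp[start] <- label
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cxyz <- arrayInd(cur, dims)
      for (axis in 1:3) for (sgn in c(-1L, 1L)) {
        ci <- cxyz[axis] + sgn
        if (ci < 1L || ci > dims[axis]) next
        nb <- cur + sgn * strides[axis]
        if (full[nb] && comp[nb] == 0L) {
          comp[nb] <- label
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp[brain_idx]
}

#' Hotspot decomposition of a modulation-depth map
#'
#' Connected regions (6-neighborhood on the grid) of nodes whose MD exceeds
#' `rel_threshold` times the global maximum, sorted by peak MD descending.
#' More than one hotspot can occur, and none need lie midway between the
#' stimulating electrode pairs.
#'
#' @param md a `ti_mdmap`.
#' @param rel_threshold fraction of the global maximum in (0, 1); default 0.5
#'   to mirror the focality definition.
#' @return a data.frame with one row per region: `peak_node`, `peak_md`
#'   (V/m), `volume_cm3`, and the peak coordinate in mm. Empty if no node is
#'   suprathreshold.
#' @export
hotspots <- function(md, rel_threshold = 0.5) {
  stopifnot(inherits(md, "ti_mdmap"))
  if (rel_threshold <= 0 || rel_threshold >= 1)
    stop("rel_threshold must be in (0, 1)")
  thr <- rel_threshold * max(md$values)
  sel <- md$values > thr
  empty <- data.frame(region = integer(0), peak_node = integer(0),
                      peak_md = numeric(0), volume_cm3 = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0))
  if (!any(sel)) return(empty)
  comp <- grid_components(sel, md$brain_idx, md$dim)
  labs <- setdiff(unique(comp), 0L)
  rows <- lapply(labs, function(l) {
    nodes <- which(comp == l)
    pk <- nodes[which.max(md$values[nodes])]
    data.frame(peak_node = pk, peak_md = md$values[pk],
               volume_cm3 = length(nodes) * md$node_volume / 1000,
               x = md$coords[pk, 1], y = md$coords[pk, 2],
               z = md$coords[pk, 3])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak_md), , drop = FALSE]
  out <- cbind(region = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Target / off-target summary report
#'
#' For each probed location and direction: the two per-montage projected
#' field amplitudes, the peak of the projected total field over time, and the
#' static MD. This is the tabular counterpart of the target-vs-off-target
#' comparisons one reads off the field and envelope traces.
#'
#' @param lf a `ti_leadfield`.
#' @param proto a `ti_protocol`.
#' @param target,off_target brain-node indices.
#' @param directions character vector of direction modes.
#' @return a data.frame with one row per (location, direction).
#' @export
md_report <- function(lf, proto, target, off_target,
                      directions = c("radial_in", "posterior_anterior")) {
  stopifnot(inherits(lf, "ti_leadfield"), inherits(proto, "ti_protocol"))
  nodes <- c(target = target, off_target = off_target)
  field <- total_field(lf, proto, nodes = nodes)
  rows <- list()
  for (mode in directions) {
    d <- direction_field(field$coords, mode)
    sf <- project_field(field, d)
    peak <- apply(abs(sf$x), 1, max)
    for (i in seq_along(nodes)) {
      rows[[length(rows) + 1]] <- data.frame(
        location = names(nodes)[i], node = nodes[i], direction = mode,
        p1 = sf$p1[i], p2 = sf$p2[i],
        peak_field = peak[i],
        md = md_static(sf$p1[i], sf$p2[i]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
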