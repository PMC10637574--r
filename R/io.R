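#' Write a lead field to a directory container
#'
#' The container is a directory holding a JSON manifest (units, reference
#' label, electrode order, grid metadata) plus flat CSV matrices for the
#' field entries, node coordinates and brain-mask indices — a portable,
#' text-only serialization of the forward model.
#'
#' @param lf a `ti_leadfield`.
#' @param path directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_leadfield <- function(lf, path) {
  stopifnot(inherits(lf, "ti_leadfield"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ne <- length(lf$electrode_labels)
  manifest <- list(
    format = "tistim-leadfield-v1",
    units = lf$units,
    reference_label = lf$reference_label,
    electrode_labels = lf$electrode_labels,
    n_nodes = nrow(lf$coords),
    grid_dim = lf$dim,
    grid_axes_range = range(lf$axes),
    grid_spacing = lf$grid_spacing,
    layer_radii = lf$head$layer_radii,
    layer_conductivities = lf$head$layer_conductivities,
    electrode_positions = data.frame(
      label = lf$layout$labels,
      x = lf$layout$positions[, 1],
      y = lf$layout$positions[, 2],
      z = lf$layout$positions[, 3]),
    electrode_radius = lf$layout$electrode_radius)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # entries flattened electrode-major: rows = electrodes x component
  flat <- matrix(aperm(lf$entries, c(2, 1, 3)), nrow = nrow(lf$coords))
  data.table::fwrite(data.table::as.data.table(flat),
                     file.path(path, "leadfield.csv"))
  data.table::fwrite(data.table::as.data.table(lf$coords),
                     file.path(path, "coords.csv"))
  data.table::fwrite(data.table::data.table(brain_idx = lf$brain_idx),
                     file.path(path, "brain_mask.csv"))
  invisible(path)
}

#' Read a lead field container written by [write_leadfield()]
#'
#' @param path container directory.
#' @return a `ti_leadfield`.
#' @export
read_leadfield <- function(path) {
  if (!file.exists(file.path(path, "manifest.json")))
    stop("no lead-field manifest found in '", path, "'")
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "tistim-leadfield-v1"))
    stop("not a tistim lead-field container: ", path)
  coords <- as.matrix(data.table::fread(file.path(path, "coords.csv")))
  colnames(coords) <- c("x", "y", "z")
  flat <- as.matrix(data.table::fread(file.path(path, "leadfield.csv")))
  ne <- length(man$electrode_labels)
  entries <- aperm(array(flat, dim = c(nrow(coords), ne, 3)), c(2, 1, 3))
  brain_idx <- data.table::fread(file.path(path, "brain_mask.csv"))$brain_idx
  head <- sphere_head_model(man$layer_radii, man$layer_conductivities,
                            grid_spacing = man$grid_spacing,
                            grid_extent = max(man$grid_axes_range))
  pos <- as.matrix(man$electrode_positions[, c("x", "y", "z")])
  storage.mode(pos) <- "double"
  rownames(pos) <- man$electrode_positions$label
  layout <- structure(list(labels = man$electrode_positions$label,
                           positions = pos,
                           reference_label = man$reference_label,
                           electrode_radius = man$electrode_radius),
                      class = "ti_layout")
  structure(list(entries = entries, electrode_labels = man$electrode_labels,
                 reference_label = man$reference_label, coords = coords,
                 brain_idx = brain_idx, dim = man$grid_dim,
                 axes = head$axes, grid_spacing = man$grid_spacing,
                 layout = layout, head = head, units = man$units),
            class = "ti_leadfield")
}

#' Write montages to CSV
#'
#' Columns `label`, `current_mA`, `frequency_hz`, `phase_rad`; one block per
#' frequency.
#'
#' @param montages list of `ti_montage`.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_montages <- function(montages, path) {
  if (inherits(montages, "ti_montage")) montages <- list(montages)
  rows <- do.call(rbind, lapply(montages, function(m)
    data.frame(label = names(m$currents), current_mA = unname(m$currents),
               frequency_hz = m$frequency, phase_rad = m$phase)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read montages from CSV
#'
#' @param path CSV written by [write_montages()] (or hand-made with the same
#'   columns).
#' @return list of `ti_montage`, one per distinct frequency, ordered by
#'   first appearance.
#' @export
read_montages <- function(path) {
  df <- utils::read.csv(path)
  need <- c("label", "current_mA", "frequency_hz")
  if (!all(need %in% names(df)))
    stop("montage CSV needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$phase_rad)) df$phase_rad <- 0
  lapply(unique(df$frequency_hz), function(f) {
    blk <- df[df$frequency_hz == f, ]
    cur <- blk$current_mA
    names(cur) <- blk$label
    montage(cur, frequency = f, phase = blk$phase_rad[1])
  })
}

#' Export a per-node time series to CSV
#'
#' Two columns, `t` (s) and `value`, for one probed node of a scalar field or
#' envelope.
#'
#' @param obj a `ti_scalar_field` or `ti_envelope`.
#' @param node row (node) index.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(obj, node, path) {
  vals <- if (inherits(obj, "ti_envelope")) obj$env[node, ] else obj$x[node, ]
  utils::write.csv(data.frame(t = obj$times, value = vals), path,
                   row.names = FALSE)
  invisible(path)
}
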