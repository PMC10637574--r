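# Azimuthal-equidistant projection of scalp positions: 2-D radius equals the
# polar angle from the vertex, azimuth preserved (top-down view, nose +y).
scalp_projection <- function(positions) {
  R <- sqrt(rowSums(positions^2))
  theta <- acos(pmin(pmax(positions[, 3] / R, -1), 1))
  phi <- atan2(positions[, 2], positions[, 1])
  data.frame(px = theta * cos(phi), py = theta * sin(phi))
}

#' Topoplot of a montage
#'
#' Electrode positions in a 2-D polar (top-down) projection, colored by the
#' signed injected current on a symmetric diverging scale centered at zero.
#' Electrodes not in the montage are drawn neutral (0 mA), mirroring the
#' "candidate electrodes" convention of montage topoplots.
#'
#' @param montage a `ti_montage`.
#' @param layout a `ti_layout` containing every montage label.
#' @return a `ti_figure`: `$data` (label, projected x/y, current_mA) and
#'   `$plot` (ggplot object).
#' @export
render_montage <- function(montage, layout) {
  stopifnot(inherits(montage, "ti_montage"), inherits(layout, "ti_layout"))
  missing <- setdiff(names(montage$currents), layout$labels)
  if (length(missing))
    stop("montage labels not in layout: ", paste(missing, collapse = ", "))
  cur <- stats::setNames(numeric(length(layout$labels)), layout$labels)
  cur[names(montage$currents)] <- montage$currents
  df <- cbind(data.frame(label = layout$labels,
                         current_mA = unname(cur)),
              scalp_projection(layout$positions))
  lim <- max(abs(df$current_mA), 1e-12)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py,
                                        fill = .data$current_mA)) +
    ggplot2::geom_point(shape = 21, size = 6, colour = "grey40") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-lim, lim),
                                  name = "mA") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(montage$frequency, " Hz montage"),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  structure(list(data = df, plot = p), class = "ti_figure")
}

#' @export
print.ti_figure <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

# Extract the axial slice nearest plane_z from per-brain-node values.
axial_slice_data <- function(values, coords, axes, plane_z) {
  if (plane_z < min(axes) || plane_z > max(axes))
    stop("plane_z = ", plane_z, " mm is outside the grid")
  z0 <- axes[which.min(abs(axes - plane_z))]
  sel <- coords[, 3] == z0
  if (!any(sel)) stop("slice plane does not intersect the brain mask")
  data.frame(x = coords[sel, 1], y = coords[sel, 2], value = values[sel],
             node = which(sel), z = z0)
}

#' Axial slice map of a volume
#'
#' Renders one axial plane of an MD map (or any per-brain-node scalar) as a
#' raster masked to the brain, with the target marked by a circle and the
#' off-target by a cross. The rendered values are the volume's values
#' exactly: no interpolation.
#'
#' @param volume a `ti_mdmap`, or a numeric vector of per-brain-node values
#'   (then `lf` must be given).
#' @param plane_z axial plane in mm (snapped to the nearest grid plane).
#' @param lf lead field supplying grid metadata when `volume` is a vector.
#' @param target,off_target optional brain-node indices to mark.
#' @param limits optional color limits (kept fixed across animation frames).
#' @return a `ti_figure` with `$data` (x, y, value, node) and `$plot`.
#' @export
render_slice <- function(volume, plane_z, lf = NULL, target = NULL,
                         off_target = NULL, limits = NULL) {
  if (inherits(volume, "ti_mdmap")) {
    values <- volume$values; coords <- volume$coords; axes <- volume$axes
  } else {
    if (is.null(lf)) stop("supply lf when volume is a plain vector")
    values <- volume; coords <- lf$coords; axes <- lf$axes
  }
  df <- axial_slice_data(values, coords, axes, plane_z)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = limits, name = "V/m") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  subtitle = paste0("z = ", df$z[1], " mm")) +
    ggplot2::theme_minimal()
  mark <- function(node, shape) {
    if (is.null(node)) return(NULL)
    ggplot2::annotate("point", x = coords[node, 1], y = coords[node, 2],
                      shape = shape, size = 4, stroke = 1.2, colour = "black")
  }
  p <- p + mark(target, 1) + mark(off_target, 4)
  structure(list(data = df, plot = p), class = "ti_figure")
}

# Closed-form two-tone envelope from signed per-montage projected amplitudes
# (used for per-frame slice maps, where a full numeric Hilbert pass over all
# nodes would be wasteful): |p1 e^{i(w1 t+f1)} + p2 e^{i(w2 t+f2)}|.
two_tone_envelope <- function(p1, p2, omega, phase, t) {
  dphi <- (omega[2] - omega[1]) * t + (phase[2] - phase[1])
  sqrt(p1^2 + p2^2 + 2 * p1 * p2 * cos(dphi))
}

#' Assemble the data for every animation frame
#'
#' Pure data layer of [animate()]: per frame, the cursor time, the injected
#' current waveforms, the 3-D field vectors and Lissajous traces at the two
#' probed nodes, the projected-field traces with their numeric envelope, and
#' axial slice maps of the instantaneous projected field and instantaneous
#' MD through the target. Color limits are fixed across frames.
#'
#' @param lf a `ti_leadfield`.
#' @param proto a `ti_protocol`.
#' @param target,off_target brain-node indices.
#' @param fps frames per second (default 25).
#' @param direction direction mode for the projected quantities.
#' @return a `ti_frames` list: shared traces (`times`, `currents`, `probe`)
#'   and one entry per frame under `frames`.
#' @export
animation_frames <- function(lf, proto, target, off_target, fps = 25,
                             direction = "radial_in") {
  stopifnot(inherits(lf, "ti_leadfield"), inherits(proto, "ti_protocol"))
  n_frames <- round(proto$duration * fps)
  frame_t <- (seq_len(n_frames) - 1) / fps
  probe_nodes <- c(target = target, off_target = off_target)

  field_probe <- total_field(lf, proto, nodes = probe_nodes)
  d_probe <- direction_field(field_probe$coords, direction)
  sf_probe <- project_field(field_probe, d_probe)
  env_probe <- envelope(sf_probe)
  liss <- lapply(probe_nodes, function(nd) lissajous(lf, proto, nd))

  dvol <- direction_field(lf, direction)
  field_all <- total_field(lf, proto)
  p1 <- rowSums(field_all$F1 * dvol$vectors)
  p2 <- rowSums(field_all$F2 * dvol$vectors)
  env_min <- abs(abs(p1) - abs(p2))          # temporal envelope minimum
  plane_z <- lf$coords[target, 3]
  e_lim <- max(abs(p1) + abs(p2))
  md_lim <- max(md_static(p1, p2))

  i1 <- proto$montage_a; i2 <- proto$montage_b
  currents <- data.frame(
    t = proto$times,
    a = max(abs(i1$currents)) * sin(2 * pi * i1$frequency * proto$times +
                                    i1$phase),
    b = max(abs(i2$currents)) * sin(2 * pi * i2$frequency * proto$times +
                                    i2$phase))

  frames <- lapply(seq_len(n_frames), function(k) {
    t <- frame_t[k]
    s1 <- sin(field_all$omega[1] * t + field_all$phase[1])
    s2 <- sin(field_all$omega[2] * t + field_all$phase[2])
    e_slice <- p1 * s1 + p2 * s2
    md_slice <- two_tone_envelope(p1, p2, field_all$omega, field_all$phase,
                                  t) - env_min
    list(index = k, time = t,
         E_vec = field_at(field_probe, t),
         e_slice = e_slice, md_slice = md_slice)
  })
  structure(list(times = proto$times, fps = fps, n_frames = n_frames,
                 frame_times = frame_t, currents = currents,
                 probe = list(nodes = probe_nodes, scalar = sf_probe,
                              envelope = env_probe, lissajous = liss),
                 plane_z = plane_z, direction = direction,
                 limits = list(field = c(-e_lim, e_lim),
                               md = c(0, md_lim)),
                 lf_meta = list(coords = lf$coords, axes = lf$axes),
                 frames = frames),
            class = "ti_frames")
}

render_frame <- function(fr, frame) {
  co <- fr$lf_meta$coords
  base_args <- list(axes = fr$lf_meta$axes)
  e_fig <- render_slice(frame$e_slice, fr$plane_z,
                        lf = list(coords = co, axes = fr$lf_meta$axes),
                        target = fr$probe$nodes[1], off_target = fr$probe$nodes[2],
                        limits = fr$limits$field)
  md_fig <- render_slice(frame$md_slice, fr$plane_z,
                         lf = list(coords = co, axes = fr$lf_meta$axes),
                         target = fr$probe$nodes[1],
                         off_target = fr$probe$nodes[2],
                         limits = fr$limits$md)
  tr <- data.frame(t = fr$times,
                   target = fr$probe$scalar$x[1, ],
                   env_target = fr$probe$envelope$env[1, ],
                   off = fr$probe$scalar$x[2, ],
                   env_off = fr$probe$envelope$env[2, ])
  p_tr <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$target), colour = "#b2182b") +
    ggplot2::geom_line(ggplot2::aes(y = .data$env_target),
                       linetype = "dashed", colour = "black") +
    ggplot2::geom_vline(xintercept = frame$time, colour = "black") +
    ggplot2::labs(x = "t (s)", y = "E (V/m)", subtitle = "target") +
    ggplot2::theme_minimal()
  p_cur <- ggplot2::ggplot(fr$currents, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$a), colour = "#2166ac") +
    ggplot2::geom_line(ggplot2::aes(y = .data$b), colour = "#b2182b") +
    ggplot2::geom_vline(xintercept = frame$time, colour = "black") +
    ggplot2::labs(x = "t (s)", y = "I (mA)") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    (p_cur + p_tr) / (e_fig$plot + md_fig$plot)
  } else {
    md_fig$plot
  }
}

#' Animate the full stimulation dynamics
#'
#' Writes one PNG per frame combining the current waveforms (with a moving
#' time cursor), the projected-field traces with dashed envelope overlay, and
#' instantaneous axial slice maps of the projected field and the
#' instantaneous MD, all with color scales fixed across frames. Defaults
#' render 1 s of 10/12 Hz dynamics at 25 fps. Encoded video output is not
#' produced directly: if `out` names an .mp4/.gif file, a PNG frame directory
#' is written next to it with a warning, ready for an external encoder.
#'
#' @param lf a `ti_leadfield`.
#' @param proto a `ti_protocol`.
#' @param target,off_target brain-node indices.
#' @param out output directory for the frames (or a video filename, see
#'   above).
#' @param fps frames per second.
#' @param direction direction mode.
#' @param render if `FALSE`, assemble the frame data but write no images.
#' @param width,height device size in pixels.
#' @return the `ti_frames` object, invisibly, with `$files` naming the
#'   written frames.
#' @export
animate <- function(lf, proto, target, off_target, out, fps = 25,
                    direction = "radial_in", render = TRUE,
                    width = 900, height = 700) {
  if (grepl("\\.(mp4|gif|avi|mov)$", out, ignore.case = TRUE)) {
    warning("no video encoder available; writing a PNG frame directory ",
            "instead of ", basename(out))
    out <- sub("\\.[A-Za-z0-9]+$", "_frames", out)
  }
  fr <- animation_frames(lf, proto, target, off_target, fps = fps,
                         direction = direction)
  files <- character(0)
  if (render) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(out, sprintf("frame_%04d.png", seq_len(fr$n_frames)))
    for (k in seq_len(fr$n_frames)) {
      grDevices::png(files[k], width = width, height = height)
      print(render_frame(fr, fr$frames[[k]]))
      grDevices::dev.off()
    }
  }
  fr$files <- files
  invisible(fr)
}
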