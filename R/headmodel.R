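#' Concentric-sphere volume-conductor head model
#'
#' Defines a layered spherical phantom (innermost layer first, e.g.
#' brain / CSF / skull / scalp) sampled on a regular cubic grid. The phantom
#' stands in for an MRI-derived head when a redistributable forward model is
#' needed: the physics (Laplace's equation for quasi-static current flow) is
#' the same, only the geometry is idealized.
#'
#' @param layer_radii numeric, strictly increasing layer outer radii in mm.
#' @param layer_conductivities numeric, one conductivity (S/m) per layer.
#' @param grid_spacing grid step in mm.
#' @param grid_extent half-width of the cubic grid in mm; must enclose the
#'   outermost sphere. Default: outermost radius rounded up to the grid.
#' @return an object of class `ti_head` with the grid axes, dimensions and a
#'   per-node tissue mask (0 = outside the head, 1 = innermost layer, ...).
#' @export
#' @examples
#' head <- sphere_head_model(c(85, 88, 91, 92), c(0.2, 1.65, 0.01, 0.465),
#'                           grid_spacing = 8)
#' table(head$mask)
sphere_head_model <- function(layer_radii, layer_conductivities,
                              grid_spacing = 4, grid_extent = NULL) {
  layer_radii <- as.numeric(layer_radii)
  layer_conductivities <- as.numeric(layer_conductivities)
  if (length(layer_radii) != length(layer_conductivities))
    stop("need one conductivity per layer")
  if (any(diff(layer_radii) <= 0)) stop("layer radii must be strictly increasing")
  if (any(layer_conductivities <= 0)) stop("conductivities must be positive")
  if (grid_spacing <= 0) stop("grid_spacing must be positive")
  r_out <- layer_radii[length(layer_radii)]
  if (is.null(grid_extent))
    grid_extent <- grid_spacing * ceiling((r_out + grid_spacing / 2) / grid_spacing)
  if (grid_extent < r_out)
    stop("grid_extent (", grid_extent, " mm) does not enclose the outer sphere (",
         r_out, " mm)")
  ax <- seq(-grid_extent, grid_extent, by = grid_spacing)
  n <- length(ax)
  # per-node radius via outer sums of squares (x fastest, then y, then z)
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  mask <- array(0L, dim = c(n, n, n))
  for (k in rev(seq_along(layer_radii)))
    mask[r2 <= layer_radii[k]^2] <- k
  structure(list(
    layer_radii = layer_radii,
    layer_conductivities = layer_conductivities,
    grid_spacing = grid_spacing,
    grid_extent = grid_extent,
    axes = ax,
    dim = c(n, n, n),
    mask = mask
  ), class = "ti_head")
}

#' Default four-layer phantom
#'
#' Brain 85 / CSF 88 / skull 91 / scalp 92 mm with standard literature
#' conductivities (0.2, 1.65, 0.01, 0.465 S/m).
#'
#' @param grid_spacing grid step in mm (default 4).
#' @param ... passed to [sphere_head_model()].
#' @return a `ti_head` object.
#' @export
default_head_model <- function(grid_spacing = 4, ...) {
  sphere_head_model(layer_radii = c(85, 88, 91, 92),
                    layer_conductivities = c(0.2, 1.65, 0.01, 0.465),
                    grid_spacing = grid_spacing, ...)
}

#' @export
print.ti_head <- function(x, ...) {
  cat("<ti_head> ", length(x$layer_radii), "-layer sphere, outer radius ",
      max(x$layer_radii), " mm\n", sep = "")
  cat("  grid: ", paste(x$dim, collapse = " x "), " nodes at ",
      x$grid_spacing, " mm (", sum(x$mask > 0), " head nodes)\n", sep = "")
  invisible(x)
}

node_coords_all <- function(head) {
  ax <- head$axes
  n <- head$dim[1]
  cbind(x = rep.int(ax, n * n),
        y = rep.int(rep(ax, each = n), n),
        z = rep(ax, each = n * n))
}

#' Place a ring-based electrode layout on the scalp sphere
#'
#' Electrodes sit on rings of constant polar angle on the outer sphere plus a
#' single vertex electrode, a parameterized stand-in for standard 10-10
#' placements on a real scalp. Labels are deterministic: `E0` is the vertex,
#' then `E1`, `E2`, ... ring by ring from the vertex down. Rings are staggered
#' in azimuth for better packing.
#'
#' @param head a `ti_head`.
#' @param n_rings number of rings (>= 1).
#' @param n_per_ring electrodes per ring (>= 2).
#' @param reference_label label of the fixed reference (cathode); must be one
#'   of the generated labels (default the vertex, `"E0"`).
#' @param theta_max polar angle (radians) of the lowest ring; default 2*pi/3
#'   (120 degrees, reaching below the "ears" of the phantom).
#' @param electrode_radius radius in mm of the circular scalp patch each
#'   electrode occupies (default 6 mm, a high-definition electrode).
#' @return a `ti_layout`: labels, 3-D positions (mm) on the outer sphere,
#'   reference label and patch radius.
#' @export
place_electrodes <- function(head, n_rings, n_per_ring,
                             reference_label = "E0",
                             theta_max = 2 * pi / 3,
                             electrode_radius = 6) {
  stopifnot(inherits(head, "ti_head"))
  if (n_rings < 1 || n_per_ring < 2) stop("need n_rings >= 1 and n_per_ring >= 2")
  if (n_rings * n_per_ring + 1 < 3) stop("need at least 3 electrodes")
  R <- max(head$layer_radii)
  pos <- matrix(c(0, 0, R), nrow = 1)
  for (k in seq_len(n_rings)) {
    theta <- k * theta_max / n_rings
    phi <- 2 * pi * (seq_len(n_per_ring) - 1) / n_per_ring +
      (k - 1) * pi / n_per_ring
    pos <- rbind(pos, cbind(R * sin(theta) * cos(phi),
                            R * sin(theta) * sin(phi),
                            R * cos(theta) * rep(1, n_per_ring)))
  }
  labels <- paste0("E", seq_len(nrow(pos)) - 1L)
  rownames(pos) <- labels
  if (!reference_label %in% labels)
    stop("reference_label '", reference_label, "' is not a generated label")
  dmin <- min(stats::dist(pos))
  min_needed <- max(2 * electrode_radius, head$grid_spacing)
  if (dmin <= min_needed)
    stop("electrodes too close for this grid/patch size: minimum spacing ",
         signif(dmin, 4), " mm, need > ", min_needed, " mm")
  structure(list(labels = labels, positions = pos,
                 reference_label = reference_label,
                 electrode_radius = electrode_radius),
            class = "ti_layout")
}

#' @export
print.ti_layout <- function(x, ...) {
  cat("<ti_layout> ", length(x$labels), " electrodes (reference ",
      x$reference_label, "), patch radius ", x$electrode_radius, " mm\n",
      sep = "")
  invisible(x)
}

# Nodes of the outer grid shell belonging to an electrode patch: head nodes
# within one spacing of the scalp surface and within the patch radius of the
# electrode centre.
electrode_patch_nodes <- function(head, layout, label) {
  p <- layout$positions[label, ]
  R <- max(head$layer_radii)
  h <- head$grid_spacing
  xyz <- node_coords_all(head)
  r <- sqrt(rowSums(xyz^2))
  shell <- head$mask > 0 & r > R - 1.5 * h
  d2 <- (xyz[, 1] - p[1])^2 + (xyz[, 2] - p[2])^2 + (xyz[, 3] - p[3])^2
  idx <- which(shell & d2 <= max(layout$electrode_radius, h)^2)
  if (length(idx) == 0) {
    # fall back to the nearest shell node (very coarse grids)
    cand <- which(shell)
    idx <- cand[which.min(d2[cand])]
  }
  idx
}

# Finite-difference discretization of div(sigma grad V) = 0 on the head mask.
# 7-point stencil; face conductivity = harmonic mean of the two node
# conductivities; faces to outside the head carry no current (insulating
# Neumann boundary). Returns the SPD (singular, pure-Neumann) system matrix
# over head nodes and the head-node index map.
fd_system <- function(head) {
  dims <- head$dim
  inside <- head$mask > 0
  n_in <- sum(inside)
  node_id <- array(0L, dim = dims)
  node_id[inside] <- seq_len(n_in)
  sigma <- array(0, dim = dims)
  sigma[inside] <- head$layer_conductivities[head$mask[inside]]
  h_m <- head$grid_spacing / 1000  # conductance sigma * h in S (h in metres)

  ii <- integer(0); jj <- integer(0); cc <- numeric(0)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  strides <- c(1L, nx, nx * ny)
  lin <- which(inside)
  ixyz <- arrayInd(lin, dims)
  for (axis in 1:3) {
    has_nb <- ixyz[, axis] < dims[axis]
    a <- lin[has_nb]
    b <- a + strides[axis]
    keep <- inside[b]
    a <- a[keep]; b <- b[keep]
    cond <- 2 * sigma[a] * sigma[b] / (sigma[a] + sigma[b]) * h_m
    ii <- c(ii, node_id[a]); jj <- c(jj, node_id[b]); cc <- c(cc, cond)
  }
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(-cc, -cc),
                            dims = c(n_in, n_in))
  Matrix::diag(A) <- -Matrix::rowSums(A)
  list(A = A, node_id = node_id, inside = lin, n = n_in)
}

# Jacobi-preconditioned conjugate gradients for the singular consistent
# Neumann system; iterates are kept orthogonal to the constant null vector.
cg_solve <- function(A, b, tol = 1e-8, max_iter = 50000L) {
  n <- length(b)
  b <- b - mean(b)
  d <- Matrix::diag(A)
  d[d <= 0] <- 1
  x <- numeric(n)
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b^2))
  if (b_norm == 0) return(list(x = x, iterations = 0L, residual = 0))
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (it %% 50 == 0) r <- r - mean(r)   # deflate null-space drift
    res <- sqrt(sum(r^2)) / b_norm
    if (res < tol) return(list(x = x - mean(x), iterations = it, residual = res))
    z <- r / d
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  stop("conjugate-gradient solve did not reach tol = ", tol,
       " in ", max_iter, " iterations (residual ", signif(res, 3), ")")
}

# Direct sparse Cholesky solve of the Neumann system with one grounded node;
# exact up to the gauge, which the caller re-fixes.
direct_solve <- function(A, b) {
  n <- length(b)
  b <- b - mean(b)
  keep <- 2:n
  Ak <- A[keep, keep]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Ak), LDL = FALSE, super = TRUE)
  x <- numeric(n)
  x[keep] <- as.numeric(Matrix::solve(ch, b[keep]))
  x - mean(x)
}

#' Solve Laplace's equation for one electrode pair
#'
#' Solves the quasi-static current-flow problem div(sigma grad V) = 0 on the
#' head mask with `current_mA` injected uniformly over the source electrode's
#' scalp patch and withdrawn at the sink patch (insulating boundary
#' elsewhere). The potential is gauged to zero mean over the head.
#'
#' @param head a `ti_head`.
#' @param source_label,sink_label electrode labels in `layout`.
#' @param layout a `ti_layout`.
#' @param current_mA injected current in mA.
#' @param tol relative residual tolerance of the iterative solve.
#' @param method `"auto"` (direct Cholesky for small grids, conjugate
#'   gradients for large ones), `"direct"` or `"cg"`.
#' @return a `ti_potential`: full-grid potential values (V, `NA` outside the
#'   head), grid metadata, and solver diagnostics.
#' @export
solve_laplace <- function(head, source_label, sink_label, layout,
                          current_mA = 1, tol = 1e-8,
                          method = c("auto", "direct", "cg")) {
  stopifnot(inherits(head, "ti_head"), inherits(layout, "ti_layout"))
  method <- match.arg(method)
  if (identical(source_label, sink_label)) stop("source and sink must differ")
  for (lab in c(source_label, sink_label))
    if (!lab %in% layout$labels) stop("unknown electrode label '", lab, "'")
  if (tol <= 0) stop("tol must be positive")
  sys <- fd_system(head)
  solve_laplace_sys(sys, head, source_label, sink_label, layout,
                    current_mA, tol, method)
}

solve_laplace_sys <- function(sys, head, source_label, sink_label, layout,
                              current_mA, tol, method = "auto") {
  b <- numeric(sys$n)
  src <- sys$node_id[electrode_patch_nodes(head, layout, source_label)]
  snk <- sys$node_id[electrode_patch_nodes(head, layout, sink_label)]
  I <- current_mA * 1e-3
  b[src] <- b[src] + I / length(src)
  b[snk] <- b[snk] - I / length(snk)
  if (method == "auto") method <- if (sys$n <= 200000) "direct" else "cg"
  if (method == "direct") {
    x <- direct_solve(sys$A, b)
    it <- NA_integer_
    res <- if (I == 0) 0 else
      sqrt(sum((as.numeric(sys$A %*% x) - (b - mean(b)))^2)) / sqrt(sum(b^2))
  } else {
    sol <- cg_solve(sys$A, b, tol = tol)
    x <- sol$x; it <- sol$iterations; res <- sol$residual
  }
  values <- array(NA_real_, dim = head$dim)
  values[sys$inside] <- x
  structure(list(values = values, dim = head$dim, axes = head$axes,
                 mask = head$mask, head = head,
                 source = source_label, sink = sink_label,
                 current_mA = current_mA,
                 patch_nodes = list(source = sys$inside[src],
                                    sink = sys$inside[snk]),
                 iterations = it, residual = res),
            class = "ti_potential")
}

#' @export
print.ti_potential <- function(x, ...) {
  cat("<ti_potential> ", x$source, " -> ", x$sink, ", ", x$current_mA,
      " mA; residual ", signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

# Central-difference negative gradient of the potential at the given linear
# grid indices, in V/m (grid is in mm). One-sided at mask edges.
efield_at <- function(pot, lin_idx) {
  v <- pot$values
  dims <- dim(v)
  h <- diff(pot$axes[1:2])
  strides <- c(1L, dims[1], dims[1] * dims[2])
  E <- matrix(0, nrow = length(lin_idx), ncol = 3)
  for (axis in 1:3) {
    up <- v[lin_idx + strides[axis]]
    dn <- v[lin_idx - strides[axis]]
    ctr <- v[lin_idx]
    both <- !is.na(up) & !is.na(dn)
    g <- numeric(length(lin_idx))
    g[both] <- (up[both] - dn[both]) / (2 * h)
    only_up <- !both & !is.na(up)
    g[only_up] <- (up[only_up] - ctr[only_up]) / h
    only_dn <- !both & !is.na(dn)
    g[only_dn] <- (ctr[only_dn] - dn[only_dn]) / h
    E[, axis] <- -g * 1000  # V/mm -> V/m
  }
  E
}

#' Build the lead field of a layout on a phantom
#'
#' Solves the forward problem once per non-reference electrode (1 mA injected
#' against the fixed reference) and stores the resulting E-field vector at
#' every brain-mask node: the linear operator mapping montage currents to the
#' brain E-field. Linearity makes any montage's field a weighted sum of rows.
#'
#' @param head a `ti_head`.
#' @param layout a `ti_layout` with at least 2 electrodes.
#' @param tol,method passed to the Laplace solver.
#' @param verbose print one line per electrode solve.
#' @return a `ti_leadfield` with `entries` (electrodes x brain nodes x 3, in
#'   V/m per mA), brain-node coordinates and grid metadata.
#' @export
build_leadfield <- function(head, layout, tol = 1e-8, method = "auto",
                            verbose = FALSE) {
  stopifnot(inherits(head, "ti_head"), inherits(layout, "ti_layout"))
  if (length(layout$labels) < 2) stop("need at least 2 electrodes")
  ref <- layout$reference_label
  others <- setdiff(layout$labels, ref)
  sys <- fd_system(head)
  brain_idx <- which(head$mask == 1L)
  xyz <- node_coords_all(head)
  coords <- xyz[brain_idx, , drop = FALSE]
  entries <- array(NA_real_, dim = c(length(others), length(brain_idx), 3))
  for (k in seq_along(others)) {
    lab <- others[k]
    pot <- tryCatch(
      solve_laplace_sys(sys, head, lab, ref, layout, 1, tol, method),
      error = function(e) stop("lead-field solve failed for electrode '",
                               lab, "': ", conditionMessage(e)))
    entries[k, , ] <- efield_at(pot, brain_idx)
    if (verbose) message("  solved ", lab, " -> ", ref,
                         " (residual ", signif(pot$residual, 3), ")")
  }
  structure(list(entries = entries, electrode_labels = others,
                 reference_label = ref, coords = coords,
                 brain_idx = brain_idx, dim = head$dim, axes = head$axes,
                 grid_spacing = head$grid_spacing,
                 layout = layout, head = head,
                 units = "V/m per mA"),
            class = "ti_leadfield")
}

#' @export
print.ti_leadfield <- function(x, ...) {
  cat("<ti_leadfield> ", length(x$electrode_labels), " electrodes vs ",
      x$reference_label, ", ", nrow(x$coords), " brain nodes at ",
      x$grid_spacing, " mm (", x$units, ")\n", sep = "")
  invisible(x)
}

#' Evaluate the field of a montage from a lead field
#'
#' Returns A(r) s: the per-node E-field vector (V/m) induced by the signed
#' electrode currents `currents` (mA). The reference electrode acts as the
#' balance: any current assigned to it is implied by the others and ignored.
#'
#' @param lf a `ti_leadfield`.
#' @param currents named numeric vector of currents in mA.
#' @return matrix (brain nodes x 3) in V/m.
#' @export
leadfield_field <- function(lf, currents) {
  stopifnot(inherits(lf, "ti_leadfield"))
  labs <- names(currents)
  unknown <- setdiff(labs, c(lf$electrode_labels, lf$reference_label))
  if (length(unknown))
    stop("unknown electrode label(s): ", paste(unknown, collapse = ", "))
  w <- numeric(length(lf$electrode_labels))
  names(w) <- lf$electrode_labels
  keep <- setdiff(labs, lf$reference_label)
  w[keep] <- currents[keep]
  F <- matrix(0, nrow = nrow(lf$coords), ncol = 3)
  for (comp in 1:3)
    F[, comp] <- as.numeric(w %*% lf$entries[, , comp])
  F
}

# Per-node projection of every lead-field row onto a direction field:
# P[node, electrode] = d(node) . E_electrode(node).
leadfield_projection <- function(lf, d) {
  P <- matrix(0, nrow = nrow(lf$coords), ncol = length(lf$electrode_labels))
  for (comp in 1:3)
    P <- P + t(lf$entries[, , comp]) * d[, comp]
  colnames(P) <- lf$electrode_labels
  P
}
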