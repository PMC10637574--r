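# Shared fixtures, built once per test run and cached.
.fix <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# Six-electrode four-layer phantom lead field on a coarse grid: the standard
# small forward model used across the suite.
phantom_lf6 <- function() fixture("lf6", function() {
  head <- sphere_head_model(c(85, 88, 91, 92), c(0.2, 1.65, 0.01, 0.465),
                            grid_spacing = 8)
  layout <- place_electrodes(head, 1, 5, reference_label = "E0")
  build_leadfield(head, layout)
})

# Synthetic lead field with random entries on a small all-brain cube grid;
# exercises montage algebra, metrics and optimizers without a solver run.
synthetic_lf <- function(n_elec = 6, n_side = 4, spacing = 4, seed = 1) {
  set.seed(seed)
  ax <- (seq_len(n_side) - (n_side + 1) / 2) * spacing
  coords <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  n_nodes <- nrow(coords)
  labels <- paste0("S", seq_len(n_elec - 1))
  entries <- array(stats::rnorm((n_elec - 1) * n_nodes * 3, sd = 0.1),
                   dim = c(n_elec - 1, n_nodes, 3))
  structure(list(entries = entries, electrode_labels = labels,
                 reference_label = "SREF", coords = coords,
                 brain_idx = seq_len(n_nodes), dim = rep(n_side, 3),
                 axes = ax, grid_spacing = spacing,
                 units = "V/m per mA"),
            class = "ti_leadfield")
}

# Build a ti_mdmap by hand from a value vector on a cube grid.
synthetic_mdmap <- function(values, n_side, spacing) {
  ax <- (seq_len(n_side) - (n_side + 1) / 2) * spacing
  coords <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  structure(list(values = values, coords = coords,
                 brain_idx = seq_len(nrow(coords)), dim = rep(n_side, 3),
                 axes = ax, node_volume = spacing^3,
                 grid_spacing = spacing, direction = "custom"),
            class = "ti_mdmap")
}

default_protocol <- function(lf_or_null = NULL, f = c(10, 12), dur = 1) {
  m1 <- montage(c(E1 = 1, E3 = -1), f[1])
  m2 <- montage(c(E2 = 1, E4 = -1), f[2], pi)
  stim_protocol(m1, m2, duration = dur)
}
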