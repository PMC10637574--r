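test_that("sphere head model validates geometry and masks layers", {
  head <- sphere_head_model(c(85, 88, 91, 92), c(0.2, 1.65, 0.01, 0.465),
                            grid_spacing = 8)
  expect_s3_class(head, "ti_head")
  expect_setequal(unique(as.integer(head$mask)), 0:4)
  # every masked node lies inside its layer's outer radius
  xyz <- tistim:::node_coords_all(head)
  r <- sqrt(rowSums(xyz^2))
  for (k in 1:4)
    expect_true(all(r[head$mask == k] <= head$layer_radii[k]))
  expect_true(all(r[head$mask == 0] > min(head$layer_radii)))

  expect_error(sphere_head_model(c(90, 85), c(1, 1)), "increasing")
  expect_error(sphere_head_model(92, -1), "positive")
  expect_error(sphere_head_model(92, 0.3, grid_extent = 50), "enclose")
})

test_that("electrode layouts sit on the scalp sphere and are deterministic", {
  head <- sphere_head_model(92, 0.33, grid_spacing = 8)
  lay <- place_electrodes(head, 1, 4, reference_label = "E0")
  expect_length(lay$labels, 5)
  expect_equal(unname(sqrt(rowSums(lay$positions^2))), rep(92, 5))
  lay2 <- place_electrodes(head, 1, 4, reference_label = "E0")
  expect_identical(lay, lay2)

  big <- place_electrodes(head, 4, 16, reference_label = "E0")
  expect_length(big$labels, 65)
  expect_gt(min(dist(big$positions)), 0)
  expect_true(all(abs(sqrt(rowSums(big$positions^2)) - 92) < 1e-9))

  expect_error(place_electrodes(head, 2, 60, reference_label = "E0"),
               "minimum spacing")
  expect_error(place_electrodes(head, 1, 4, reference_label = "Cz"),
               "not a generated label")
})

test_that("Laplace solve conserves structure: zero source, antisymmetry, gauge", {
  head <- sphere_head_model(92, 0.33, grid_spacing = 12)
  lay <- place_electrodes(head, 1, 4, reference_label = "E0")
  p0 <- solve_laplace(head, "E1", "E3", lay, current_mA = 0)
  vals <- p0$values[!is.na(p0$values)]
  expect_lt(diff(range(vals)), 1e-12)

  pa <- solve_laplace(head, "E1", "E3", lay, current_mA = 1)
  pb <- solve_laplace(head, "E3", "E1", lay, current_mA = 1)
  va <- pa$values[!is.na(pa$values)]
  vb <- pb$values[!is.na(pb$values)]
  expect_lt(max(abs(va + vb)), 1e-9 + 1e-6 * max(abs(va)))
  expect_lt(abs(mean(va)), 1e-12)  # zero-mean gauge

  expect_error(solve_laplace(head, "E1", "E1", lay), "differ")
  expect_error(solve_laplace(head, "E9", "E1", lay), "unknown electrode")
})

test_that("discrete maximum principle: potential extrema at electrodes or boundary", {
  head <- sphere_head_model(92, 0.33, grid_spacing = 8)
  lay <- place_electrodes(head, 1, 4, reference_label = "E0")
  pot <- solve_laplace(head, "E1", "E0", lay, current_mA = 1)
  inside <- which(!is.na(pot$values))
  # boundary nodes: head nodes missing at least one in-mask neighbour
  dims <- dim(pot$values)
  strides <- c(1, dims[1], dims[1] * dims[2])
  n_nb <- rep(0L, length(inside))
  for (s in strides) {
    n_nb <- n_nb + !is.na(pot$values[inside + s]) +
      !is.na(pot$values[inside - s])
  }
  special <- union(which(inside %in% unlist(pot$patch_nodes)),
                   which(n_nb < 6L))
  expect_true(which.max(pot$values[inside]) %in% special)
  expect_true(which.min(pot$values[inside]) %in% special)
})

test_that("FDM matches the analytic homogeneous-sphere series away from electrodes", {
  head <- sphere_head_model(92, 0.33, grid_spacing = 8)
  lay <- place_electrodes(head, 1, 2, reference_label = "E0")
  # antipodal pair: vertex and the ring reflected to the south pole
  lay$positions <- rbind(E0 = c(0, 0, 92), E1 = c(0, 0, -92))
  lay$labels <- c("E0", "E1")
  pot <- solve_laplace(head, "E0", "E1", lay, current_mA = 1)
  xyz <- tistim:::node_coords_all(head)
  r <- sqrt(rowSums(xyz^2))
  h <- head$grid_spacing
  shell <- which(!is.na(pot$values) & r <= 92 - h & r >= 92 - 3 * h)
  da <- sqrt(rowSums((xyz - rep(c(0, 0, 92), each = nrow(xyz)))^2))
  db <- sqrt(rowSums((xyz + rep(c(0, 0, 92), each = nrow(xyz)))^2))
  keep <- shell[da[shell] > 12 & db[shell] > 12]
  Va <- sphere_series_potential(xyz[keep, , drop = FALSE], c(0, 0, 92),
                                c(0, 0, -92), 92, 0.33, 1e-3)
  Vf <- pot$values[keep]
  Va <- Va - mean(Va); Vf <- Vf - mean(Vf)
  rel <- sqrt(mean((Vf - Va)^2) / mean(Va^2))
  expect_lt(rel, 0.08)  # coarse 8 mm grid; the fine-grid bound is 5%
})

test_that("lead field has one row per non-reference electrode, finite and live", {
  lf <- phantom_lf6()
  expect_equal(dim(lf$entries)[1], 5)
  expect_true(all(is.finite(lf$entries)))
  for (k in 1:5) expect_gt(max(abs(lf$entries[k, , ])), 0)
  expect_identical(lf$units, "V/m per mA")
})

test_that("montage field equals the montage-weighted row sum and the direct pair solve", {
  lf <- phantom_lf6()
  w <- c(E1 = 1.3, E2 = -0.4, E4 = -0.9)
  F <- leadfield_field(lf, w)
  Fsum <- 1.3 * lf$entries[1, , ] - 0.4 * lf$entries[2, , ] -
    0.9 * lf$entries[4, , ]
  expect_equal(F, Fsum, tolerance = 1e-12)  # exact superposition

  # separately solved two-electrode problem vs difference of rows
  pot <- solve_laplace(lf$head, "E1", "E2", lf$layout, current_mA = 1)
  Epair <- tistim:::efield_at(pot, lf$brain_idx)
  Frow <- lf$entries[1, , ] - lf$entries[2, , ]
  rel <- sqrt(sum((Epair - Frow)^2) / sum(Frow^2))
  expect_lt(rel, 1e-6)

  expect_error(leadfield_field(lf, c(Qz = 1)), "unknown electrode")
})
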