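test_that("lattice mean radius matches the closed-form barrel radius", {
  for (n in seq(8, 16, 2)) {
    for (S in c(8, 12, 15, 18)) {
      spec <- suppressWarnings(barrel_spec(n, S))
      m <- build_calpha_lattice(spec)
      ca <- ca_coords(m)
      r <- mean(sqrt(rowSums(ca[, 1:2]^2)))
      expect_equal(r, barrel_radius(n, S), tolerance = 0.02,
                   label = sprintf("mean radius (n=%d, S=%d)", n, S))
    }
  }
})

test_that("adjacent strands pair at the interstrand distance", {
  m <- get_model(10)
  rs <- m$residues
  ca <- m$xyz$ca
  b <- m$spec$interstrand_distance
  for (j in 0:9) {
    i1 <- which(rs$strand %in% j)
    i2 <- which(rs$strand %in% ((j + 1) %% 10))
    # every mid-strand residue must have a partner within b +/- 0.6
    for (q in i1[3:8]) {
      dmin <- min(sqrt(colSums((t(ca[i2, ]) - ca[q, ])^2)))
      expect_lt(abs(dmin - b), 0.6)
    }
  }
})

test_that("consecutive Calpha distances are canonical", {
  for (key in list(c(10, "cylinder"), c(12, "square"))) {
    m <- get_model(as.integer(key[1]), key[2])
    ca <- m$xyz$ca
    d <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(abs(d - 3.8) <= 0.31),
                label = paste("consecutive CA distances", key[2]))
  }
})

test_that("computed shear equals the blueprint shear across the design grid", {
  for (n in seq(8, 16, 2)) {
    for (S in 8:18) {
      m <- build_calpha_lattice(suppressWarnings(barrel_spec(n, S)))
      expect_identical(compute_shear(m), S,
                       label = sprintf("shear (n=%d, S=%d)", n, S))
    }
  }
})

test_that("computed shear agrees with the register-traversal oracle", {
  for (key in list(c(10, "cylinder"), c(12, "square"), c(12, "triangle"),
                   c(14, "oval"))) {
    m <- get_model(as.integer(key[1]), key[2])
    expect_identical(compute_shear(m), oracle_shear(m),
                     label = paste("oracle agreement", key[1], key[2]))
  }
})

test_that("hairpin closure yields the expected residue count and connectivity", {
  spec <- barrel_spec(10, strand_length = 10, loop_lengths = 2)
  m <- close_hairpins(build_calpha_lattice(spec))
  expect_identical(nrow(m$residues), 118L)   # 10*10 + 9*2
  d <- sqrt(rowSums(diff(m$xyz$ca)^2))
  expect_true(all(d <= 4.1))
  expect_identical(sum(m$residues$label == "loop"), 18L)
  # loops carry no TM annotation and closure leaves TM coordinates alone
  m0 <- build_calpha_lattice(spec)
  tm <- m$residues$label == "strand"
  expect_equal(m$xyz$ca[tm, ], ca_coords(m0), tolerance = 1e-12)
})

test_that("mixed loop lengths are honored in the residue count", {
  spec <- barrel_spec(10, loop_lengths = c(2, 3))
  m <- close_hairpins(build_calpha_lattice(spec))
  expect_identical(nrow(m$residues), 100L + sum(spec$loop_lengths))
})

test_that("sculpting flattens faces, localizes bending and keeps the wall length", {
  spec <- barrel_spec(12, cross_section = "square")
  m0 <- build_calpha_lattice(spec)
  km <- place_glycine_kinks(spec)
  m <- sculpt_cross_section(m0, km)
  rs <- m$residues
  C <- sqrt((spec$shear * 3.32)^2 + (12 * 4.6)^2)

  # faces: group TM residues by the circumferential interval between
  # consecutive corner columns; each face must be planar within 1 A RMS
  corner_t <- sort(m$curve$corner_t)
  u <- rs$u %% C
  face_id <- findInterval(u, corner_t)
  face_id[face_id == 0] <- length(corner_t)
  margin <- 2.0    # exclude the rounded corner neighborhoods
  for (f in unique(face_id)) {
    sel <- which(face_id == f)
    dist_to_corner <- pmin(
      abs(((u - corner_t[f]) + C / 2) %% C - C / 2),
      abs(((u - corner_t[(f %% 4) + 1]) + C / 2) %% C - C / 2))
    sel <- sel[dist_to_corner[sel] > margin]
    if (length(sel) < 6) next
    pl <- tmbarrel:::fit_plane(m$xyz$ca[sel, ])
    expect_lt(pl$rms, 1.0)
  }

  # circumference: paired interstrand spacing sums to n*b within 3%
  ca <- m$xyz$ca
  tot <- 0
  for (j in 0:11) {
    i1 <- which(rs$strand %in% j); i2 <- which(rs$strand %in% ((j + 1) %% 12))
    mid <- i1[5]
    tot <- tot + min(sqrt(colSums((t(ca[i2, ]) - ca[mid, ])^2)))
  }
  expect_lt(abs(tot - 12 * 4.6) / (12 * 4.6), 0.03)
})

test_that("sculpting with an empty kink map is the identity", {
  spec <- barrel_spec(10)
  m0 <- build_calpha_lattice(spec)
  m <- sculpt_cross_section(m0, place_glycine_kinks(spec, "cylinder"))
  expect_equal(m$xyz$ca, m0$xyz$ca, tolerance = 1e-12)
})

test_that("sculpting preserves residue count, shear and local geometry", {
  spec <- barrel_spec(12, cross_section = "square")
  m0 <- build_calpha_lattice(spec)
  m <- sculpt_cross_section(m0, place_glycine_kinks(spec))
  expect_identical(nrow(m$residues), nrow(m0$residues))
  expect_identical(compute_shear(m), compute_shear(m0))
  # consecutive distances move by at most 0.3 A within strands
  rs <- m$residues
  within <- which(diff(rs$strand) == 0)
  d0 <- sqrt(rowSums(diff(m0$xyz$ca)^2))[within]
  d1 <- sqrt(rowSums(diff(m$xyz$ca)^2))[within]
  expect_true(all(abs(d1 - d0) <= 0.3))
})

test_that("kink maps match the shape corner layout", {
  spec12 <- barrel_spec(12)
  km_sq <- place_glycine_kinks(spec12, "square")
  expect_identical(length(unique(km_sq$corner)), 4L)
  # one kink per strand crossing
  expect_true(all(table(km_sq$corner, km_sq$strand) <= 1))

  km_tri <- place_glycine_kinks(spec12, "triangle")
  expect_identical(length(unique(km_tri$corner)), 3L)
  # tight corners use stacked kinks
  crossing <- table(paste(km_tri$corner, km_tri$strand))
  expect_true(all(crossing == 2))

  km_oval <- place_glycine_kinks(spec12, "oval")
  expect_identical(length(unique(km_oval$corner)), 2L)

  expect_identical(nrow(place_glycine_kinks(spec12, "cylinder")), 0L)
  # a triangle needs at least 6 strands
  expect_error(place_glycine_kinks(suppressWarnings(barrel_spec(6)),
                                   "square"), "corners")
})
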