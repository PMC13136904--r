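test_that("patch centers follow the base and rim conventions", {
  geom <- cylinder_geometry(radius = 1.26, height = 2.64)
  pc <- patch_centers(cylinder_pose(), geom)
  expect_equal(unname(pc$stacking["plus", ]), c(0, 0, 1.32))
  expect_equal(unname(pc$stacking["minus", ]), c(0, 0, -1.32))
  # linker on the -axis base, azimuth measured from x-hat
  expect_equal(pc$linker, c(1.26, 0, -1.32))
  pc_plus <- patch_centers(cylinder_pose(), geom, linker_base = +1)
  expect_equal(pc_plus$linker, c(1.26, 0, 1.32))
  # azimuth rotates the rim point in the base plane
  pc_rot <- patch_centers(cylinder_pose(azimuth = pi / 2), geom)
  expect_equal(pc_rot$linker, c(0, 1.26, -1.32))
})

test_that("patch centers are rotation equivariant", {
  geom <- cylinder_geometry()
  pc_x <- patch_centers(cylinder_pose(axis = c(1, 0, 0)), geom)
  expect_equal(unname(pc_x$stacking["plus", ]), c(1.32, 0, 0))
  expect_equal(unname(pc_x$stacking["minus", ]), c(-1.32, 0, 0))
  # arbitrary axis: stacking centers stay at center +/- (H/2) axis
  set.seed(11)
  for (i in 1:20) {
    ax <- rand_unit_vec()
    cen <- rnorm(3)
    pc <- patch_centers(cylinder_pose(center = cen, axis = ax), geom)
    expect_equal(unname(pc$stacking["plus", ]), cen + 1.32 * ax)
    # linker stays on the rim: distance R_HC from the base center
    expect_equal(sqrt(sum((pc$linker - (cen - 1.32 * ax))^2)), 1.26)
    expect_lt(abs(sum((pc$linker - (cen - 1.32 * ax)) * ax)), 1e-12)
  }
})

test_that("cylinder overlap handles separated, identical, and contact cases", {
  geom <- cylinder_geometry(radius = 1.26, height = 2.64)
  pz <- function(z) cylinder_pose(center = c(0, 0, z))
  expect_false(cylinders_overlap(pz(0), pz(2.64 + 1e-3), geom))
  expect_true(cylinders_overlap(pz(0), pz(2.64 - 1e-3), geom))
  expect_true(cylinders_overlap(pz(0), pz(0), geom))
  # lateral contact
  px <- function(x) cylinder_pose(center = c(x, 0, 0))
  expect_false(cylinders_overlap(px(0), px(2 * 1.26 + 1e-3), geom))
  expect_true(cylinders_overlap(px(0), px(2 * 1.26 - 1e-3), geom))
  # cap against lateral surface of a perpendicular cylinder
  perp <- cylinder_pose(center = c(0, 0, 1.32 + 1.26 - 0.01), axis = c(1, 0, 0))
  expect_true(cylinders_overlap(pz(0), perp, geom))
  perp2 <- cylinder_pose(center = c(0, 0, 1.32 + 1.26 + 0.01), axis = c(1, 0, 0))
  expect_false(cylinders_overlap(pz(0), perp2, geom))
  expect_error(cylinders_overlap(pz(0), pz(1), cylinder_geometry(radius = 1e-9)),
               NA)  # tiny but positive radius is legal
  expect_error(cylinder_geometry(radius = 0), "positive")
  expect_error(cylinder_geometry(height = -1), "positive")
})

test_that("cylinder overlap agrees with the point-membership oracle", {
  set.seed(101)
  R <- 1.26; H <- 2.64
  geom <- cylinder_geometry(R, H)
  n_cases <- 400
  n_pts <- 4000
  for (k in seq_len(n_cases)) {
    ua <- rand_unit_vec(); ub <- rand_unit_vec()
    cb <- runif(3, -1, 1) * runif(1, 0, 4.5)
    got <- cylinders_overlap(cylinder_pose(axis = ua),
                             cylinder_pose(center = cb, axis = ub), geom)
    pts <- oracle_points_in_cyl(n_pts, c(0, 0, 0), ua, R, H)
    hit <- any(oracle_in_cyl(pts, cb, ub, R, H))
    if (!hit) {
      pts2 <- oracle_points_in_cyl(n_pts, cb, ub, R, H)
      hit <- any(oracle_in_cyl(pts2, c(0, 0, 0), ua, R, H))
    }
    if (hit) {
      # any sampled shared point proves interior overlap
      expect_true(got)
    } else if (got) {
      # claim of overlap without an oracle hit must be a thin contact:
      # slightly shrunken cylinders must separate
      shrunk <- cylinder_geometry(R * 0.97, H * 0.97)
      expect_false(cylinders_overlap(cylinder_pose(axis = ua),
                                     cylinder_pose(center = cb, axis = ub),
                                     shrunk))
    }
  }
})

test_that("pair energy implements the square wells and hard constraints", {
  geom <- cylinder_geometry()
  patches <- patch_spec()
  H <- geom$height
  # perfectly stacked: coaxial, facing bases in near contact
  stacked <- dimer_state(cylinder_pose(center = c(0, 0, 0)),
                         cylinder_pose(center = c(0, 0, H + 1e-4)),
                         geom, patches)
  expect_equal(pair_energy(stacked), -1)
  expect_true(is_stacked(stacked))
  # linker satisfied but stacking centers 0.6 nm apart (> 2 * 0.265)
  apart <- dimer_state(cylinder_pose(center = c(0, 0, 0)),
                       cylinder_pose(center = c(0, 0, H + 0.6)),
                       geom, patches)
  expect_equal(pair_energy(apart), 0)
  expect_false(is_stacked(apart))
  # linker patch centers beyond 2 * R0 = 1.06: hard violation
  far <- dimer_state(cylinder_pose(center = c(0, 0, 0)),
                     cylinder_pose(center = c(0, 0, H + 1.2)),
                     geom, patches)
  expect_identical(pair_energy(far), Inf)
  # overlapping cylinders: hard violation
  olap <- dimer_state(cylinder_pose(center = c(0, 0, 0)),
                      cylinder_pose(center = c(0, 0, H / 2)),
                      geom, patches)
  expect_identical(pair_energy(olap), Inf)
})

test_that("pair energy is invariant under rigid-body transformations", {
  set.seed(77)
  geom <- cylinder_geometry()
  patches <- patch_spec()
  base_cases <- list(
    c(0, 0, geom$height + 1e-4),   # stacked
    c(0, 0, geom$height + 0.6),    # unstacked, feasible
    c(0.4, 0.3, geom$height + 0.2) # offset
  )
  for (cb in base_cases) {
    d0 <- dimer_state(cylinder_pose(), cylinder_pose(center = cb),
                      geom, patches)
    e0 <- pair_energy(d0)
    for (i in 1:15) {
      Q <- rand_rotation()
      tr <- rnorm(3, 0, 20)
      move <- function(p) {
        ax <- as.numeric(Q %*% p$axis)
        # transform the rim direction through the azimuth-frame roundtrip
        fr0 <- g4dimer:::perp_frame(p$axis)
        w0 <- cos(p$azimuth) * fr0$e1 + sin(p$azimuth) * fr0$e2
        w1 <- as.numeric(Q %*% w0)
        fr1 <- g4dimer:::perp_frame(ax)
        cylinder_pose(center = as.numeric(Q %*% p$center) + tr, axis = ax,
                      azimuth = atan2(sum(w1 * fr1$e2), sum(w1 * fr1$e1)))
      }
      d1 <- dimer_state(move(d0$pose_a), move(d0$pose_b), geom, patches)
      expect_equal(pair_energy(d1), e0)
    }
  }
})

test_that("stacking implies energy -1 and feasible non-stacked means 0", {
  set.seed(31)
  geom <- cylinder_geometry()
  patches <- patch_spec()
  h <- geom$height / 2
  link_a <- c(geom$radius, 0, h)  # cylinder A linker patch (+axis base rim)
  n_checked <- 0
  n_stacked <- 0
  for (i in 1:300) {
    # propose B with its linker patch inside A's linker well, as in the
    # constrained configuration space the model samples
    ub <- rand_unit_vec()
    az <- runif(1, 0, 2 * pi)
    dirb <- rand_unit_vec()
    link_b <- link_a + dirb * 2 * patches$linker_radius * runif(1)^(1 / 3)
    # B's rim direction at this azimuth in the world frame
    frb <- g4dimer:::perp_frame(ub)
    wb <- cos(az) * frb$e1 + sin(az) * frb$e2
    cb <- link_b + h * ub - geom$radius * wb
    d <- dimer_state(cylinder_pose(),
                     cylinder_pose(center = cb, axis = ub, azimuth = az),
                     geom, patches)
    e <- pair_energy(d)
    if (!is.finite(e)) next
    n_checked <- n_checked + 1
    if (is_stacked(d)) {
      n_stacked <- n_stacked + 1
      expect_equal(e, -1)
    } else {
      expect_equal(e, 0)
    }
  }
  expect_gt(n_checked, 50)
})
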