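# Morphometrics: density, inter-capillary distance, distance maps, scaling
# parameters, perfusion classes, histograms, radial profiles.

test_that("vascular density sums surface area over volume and normalises", {
  m <- smallCube(6, 6L)
  # hand network: 3 segments with known radii and lengths
  pos <- rbind(c(0, 3, 3), c(2, 3, 3), c(4, 3, 3), c(6, 3, 3))
  net <- handNetwork(pos, m, radius = 0.03)
  net$R[] <- c(0.02, 0.04, 0.04, 0.02)
  manual <- sum(2 * pi * c(0.03, 0.04, 0.03) * 2)  # mean endpoint radii x L
  expect_equal(vascularDensity(net, 216), manual / 216, tolerance = 1e-12)
  expect_equal(vascularDensity(net, 216, day0 = manual / 216), 1)
  net2 <- net; net2$R <- net$R * 2
  expect_equal(vascularDensity(net2, 216), 2 * vascularDensity(net, 216))
  # collapsed segments are excluded
  net3 <- net; net3$state[2] <- 2L
  expect_lt(vascularDensity(net3, 216), vascularDensity(net, 216))
})

test_that("inter-capillary distance: parallel lines, degenerate and brute force", {
  m <- smallCube(6, 6L)
  two <- handNetwork(rbind(c(0, 2.7, 3), c(6, 2.7, 3)), m, outlet = 2L)
  two <- angiomech:::appendNodes(two, rbind(c(0, 3.3, 3), c(6, 3.3, 3)), tg = 0,
                                 tip = FALSE, dir = matrix(c(1, 0, 0), 2, 3),
                                 vessel = 2L,
                                 elem = locateHostElement(rbind(c(0, 3.3, 3), c(6, 3.3, 3)), m)$elem,
                                 lc = locateHostElement(rbind(c(0, 3.3, 3), c(6, 3.3, 3)), m)$lc,
                                 R = 0.03, h = 5e-3, rp = 5e-5)
  two <- angiomech:::addSegment(two, 3L, 4L)
  expect_equal(intercapillaryDistance(two, spacing = 0.05), 0.6, tolerance = 1e-9)
  one <- handNetwork(rbind(c(0, 3, 3), c(6, 3, 3)), m, outlet = 2L)
  expect_true(is.na(intercapillaryDistance(one)))
  # random 5-vessel set against a brute-force all-pairs computation
  set.seed(21)
  net5 <- NULL
  for (v in 1:5) {
    a <- c(0, runif(2, 1, 5)); b <- c(6, runif(2, 1, 5))
    seg <- handNetwork(rbind(a, b), m, outlet = 2L)
    if (is.null(net5)) {
      net5 <- seg
    } else {
      k0 <- angiomech:::nNodes(net5)
      net5 <- angiomech:::appendNodes(net5, rbind(a, b), tg = 0, tip = FALSE,
                                      dir = matrix(c(1, 0, 0), 2, 3), vessel = v,
                                      elem = locateHostElement(rbind(a, b), m)$elem,
                                      lc = locateHostElement(rbind(a, b), m)$lc,
                                      R = 0.03, h = 5e-3, rp = 5e-5)
      net5 <- angiomech:::addSegment(net5, k0 + 1L, k0 + 2L)
    }
  }
  got <- intercapillaryDistance(net5, spacing = 0.05)
  s <- angiomech:::sampleVessels(net5, 0.05)
  brute <- mean(vapply(seq_len(nrow(s$pos)), function(i) {
    other <- s$vessel != s$vessel[i]
    sqrt(min(rowSums(sweep(s$pos[other, , drop = FALSE], 2, s$pos[i, ])^2)))
  }, 0))
  expect_equal(got, brute, tolerance = 1e-9)
})

test_that("distance maps are exact for simple geometries", {
  m <- smallCube(6, 6L)
  net <- handNetwork(rbind(c(0, 3, 3), c(6, 3, 3)), m, outlet = 2L)
  dm <- distanceMap(net, centre = c(3, 3, 3), radius = 1.5, voxel = 0.1)
  expect_true(dm$valid)
  expect_lt(min(dm$delta), 0.1)               # voxels on the vessel
  # analytic distance to the line y=3,z=3 within a voxel diagonal
  lo <- c(3, 3, 3) - 1.5
  n <- dm$dims[1]
  ax <- lo[1] + (seq_len(n) - 0.5) * 0.1
  cc <- expand.grid(x = ax, y = lo[2] + (seq_len(n) - 0.5) * 0.1,
                    z = lo[3] + (seq_len(n) - 0.5) * 0.1)
  insph <- (cc$x - 3)^2 + (cc$y - 3)^2 + (cc$z - 3)^2 <= 1.5^2
  ref <- sqrt((cc$y[insph] - 3)^2 + (cc$z[insph] - 3)^2)
  expect_lt(max(abs(dm$delta - ref)), 0.1 * sqrt(3) + 1e-9)
  # empty network is flagged invalid
  empty <- net; empty$state[] <- 2L
  dme <- distanceMap(empty, c(3, 3, 3), 1.5, 0.1)
  expect_false(dme$valid)
})

test_that("scaling parameters recover a known exponential decay length", {
  for (seed in 1:3) {
    set.seed(seed)
    delta <- stats::rexp(2e5, rate = 1 / 0.3)
    sp <- scalingParameters(delta, binwidth = 0.03)
    expect_lt(abs(sp$lambda_v - 0.3) / 0.3, 0.1)
    expect_equal(sp$delta_v_max, max(delta))
  }
  # max distance grows when an avascular pocket is added
  set.seed(4)
  base <- stats::rexp(5e4, 1 / 0.2)
  sp1 <- scalingParameters(base)
  sp2 <- scalingParameters(c(base, 3.5))
  expect_gt(sp2$delta_v_max, sp1$delta_v_max)
  expect_true(is.na(scalingParameters(numeric(0))$lambda_v))
})

test_that("lattice distance map is resolution-stable", {
  m <- generateCubeMesh(12, 8L, 1, grading = 2.5)
  net <- buildInitialNetwork(m, spacing = 0.6, radius = 0.03)
  sp1 <- scalingParameters(distanceMap(net, c(6, 6, 6), 1.6, voxel = 0.06)$delta,
                           binwidth = 0.06)
  sp2 <- scalingParameters(distanceMap(net, c(6, 6, 6), 1.6, voxel = 0.03)$delta,
                           binwidth = 0.03)
  expect_lt(abs(sp1$lambda_v - sp2$lambda_v) / sp2$lambda_v, 0.05)
  # the farthest point of a uniform lattice is near half the lattice diagonal
  expect_lt(abs(sp2$delta_v_max - 0.6 / sqrt(2)) / (0.6 / sqrt(2)), 0.45)
})

test_that("perfusion classes use the printed velocity bins", {
  m <- smallCube(6, 6L)
  pos <- rbind(c(0, 3, 3), c(2, 3, 3), c(4, 3, 3), c(6, 3, 3))
  net <- handNetwork(pos, m)
  pc <- perfusionClassification(net, seg_v = c(0.05, 0.1, 0.7))
  expect_equal(unname(pc$by_count),
               c(1, 1, 1, 0) / 3)
  expect_equal(sum(pc$by_count), 1, tolerance = 1e-12)
  # v = 0.1 exactly is 'perfused' (closed lower edge), 0.3 likewise
  pc2 <- perfusionClassification(net, seg_v = c(0.1, 0.3, 0.5))
  expect_equal(unname(pc2$by_count[["perfused"]]), 1)
  # all-collapsed network
  netc <- net; netc$state[] <- 2L
  pcc <- perfusionClassification(netc, seg_v = rep(0, 3))
  expect_equal(unname(pcc$by_count[["collapsed"]]), 1)
  # length-weighted fractions are invariant to segment subdivision
  net_sub <- handNetwork(rbind(c(0, 3, 3), c(1, 3, 3), c(2, 3, 3),
                               c(4, 3, 3), c(6, 3, 3)), m)
  pc_sub <- perfusionClassification(net_sub, seg_v = c(0.05, 0.05, 0.1, 0.7))
  expect_equal(pc$by_length, pc_sub$by_length, tolerance = 1e-12)
})

test_that("histograms normalise functional length per diameter bin", {
  m <- smallCube(6, 6L)
  pos <- rbind(c(0, 3, 3), c(2, 3, 3), c(4, 3, 3), c(6, 3, 3))
  net <- handNetwork(pos, m)
  net$R[] <- c(0.003, 0.003, 0.008, 0.008)   # diameters 6, 11, 16 um (means)
  h <- vesselHistograms(net, seg_v = c(0.1, 0.2, 0.3))
  expect_equal(sum(h$norm_length), 1, tolerance = 1e-12)
  expect_equal(h$norm_length[h$dia_lo_um == 4], 1 / 3)  # one of three segments
  expect_equal(h$norm_length[h$dia_lo_um == 10], 2 / 3)
  # single-bin degenerate case
  net1 <- net; net1$R[] <- 0.004
  h1 <- vesselHistograms(net1, seg_v = rep(0.1, 3))
  expect_equal(max(h1$norm_length), 1)
  # collapsed-length ratio
  net2 <- net; net2$state[4] <- 2L
  h2 <- vesselHistograms(net2, seg_v = rep(0.1, 3))
  expect_equal(attr(h2, "collapsed_ratio"), 0.5)
})

test_that("radial profiles recover analytic fields", {
  m <- smallCube(6, 8L)
  const <- rep(2.5, nrow(m$nodes))
  pr <- radialProfiles(const, m, dr = 0.3)
  expect_lt(max(abs(pr$mean - 2.5)), 1e-10)
  expect_lt(max(pr$sd, na.rm = TRUE), 1e-10)
  m12 <- smallCube(6, 12L)
  r_field <- sqrt(rowSums(sweep(m12$nodes, 2, c(3, 3, 3))^2))
  pr2 <- radialProfiles(r_field, m12, dr = 0.3)
  # trilinear interpolation error, dominated by the |r| kink at the origin
  expect_lt(max(abs(pr2$mean - pr2$r)), 0.12)
  # spherically symmetric smooth field has near-zero azimuthal scatter
  f <- exp(-r_field)
  pr3 <- radialProfiles(f, m12, dr = 0.3)
  expect_lt(max(pr3$sd / pmax(pr3$mean, 1e-12), na.rm = TRUE), 0.1)
})
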