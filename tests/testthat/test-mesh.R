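# Mesh generation, Gmsh I/O, point location, densities.

test_that("generated cube meshes have exact volume and sane labelling", {
  m <- smallCube(6, 6L, 2)
  expect_equal(sum(m$volumes), 216, tolerance = 1e-12)
  expect_gt(sum(m$label == 2L), 0)
  expect_gt(sum(m$label == 1L), 0)
  # graded mesh: volume still exact, min edge at the centre
  mg <- generateCubeMesh(12, 8L, 1, grading = 3)
  expect_equal(sum(mg$volumes), 12^3, tolerance = 1e-6 * 12^3)
  expect_lt(mg$min_edge, 12 / 8)
  # empty-sphere case
  m0 <- smallCube(6, 4L, 0)
  expect_identical(sum(m0$label == 2L), 0L)
  expect_error(generateCubeMesh(6, 6L, 3.5), "tumour_diameter")
  expect_error(generateCubeMesh(6, 3L), "n_per_side")
})

test_that("point location matches an exhaustive generic scan", {
  m <- generateCubeMesh(6, 5L, 1.5, grading = 1.5)
  set.seed(11)
  p <- matrix(runif(3000, 0, 6), 1000, 3)
  fast <- locateHostElement(p, m)
  m2 <- m
  attr(m2, "axis_coords") <- NULL   # force the generic bbox+Newton path
  slow <- locateHostElement(p, m2)
  expect_identical(fast$elem, slow$elem)
  expect_lt(max(abs(fast$lc - slow$lc)), 1e-7)
  # centroid maps to its own element at local (0,0,0)
  e <- 17L
  cc <- locateHostElement(m$centroids[e, ], m)
  expect_identical(cc$elem[1], e)
  expect_lt(max(abs(cc$lc)), 1e-10)
  # shared-face points resolve to the lowest adjacent element id
  ax <- attr(m, "axis_coords")
  face_pt <- c(ax[3], mean(ax[2:3]), mean(ax[2:3]))  # on the x-face of elems 2/3
  lf <- locateHostElement(face_pt, m)
  expect_identical(lf$elem[1], locateHostElement(face_pt - c(1e-9, 0, 0), m)$elem[1])
  # outside the domain
  expect_true(is.na(locateHostElement(c(-1, 1, 1), m)$elem[1]))
})

test_that("Gmsh meshes round-trip in both dialects and agree across them", {
  m <- smallCube(6, 5L, 2)
  for (ver in c("2.2", "4.1")) {
    f <- tempfile(fileext = ".msh")
    writeGmshMesh(m, f, ver)
    m2 <- loadMesh(f)
    expect_identical(unname(m2$elems), unname(m$elems))
    expect_equal(unname(m2$nodes), unname(m$nodes))
    expect_identical(m2$label, m$label)
    expect_identical(m2$inlet_nodes, m$inlet_nodes)
    expect_identical(m2$outlet_nodes, m$outlet_nodes)
  }
  f22 <- tempfile(fileext = ".msh"); f41 <- tempfile(fileext = ".msh")
  writeGmshMesh(m, f22, "2.2"); writeGmshMesh(m, f41, "4.1")
  a <- loadMesh(f22); b <- loadMesh(f41)
  expect_identical(unname(a$elems), unname(b$elems))
  expect_equal(unname(a$nodes), unname(b$nodes))
  expect_identical(a$label, b$label)
  # malformed inputs fail loudly
  empty <- tempfile(); file.create(empty)
  expect_error(loadMesh(empty), "empty|MeshFormat")
  bad <- tempfile(); writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), bad)
  expect_error(loadMesh(bad), "Nodes")
})

test_that("initial network spans the tagged faces and avoids the tumour", {
  m <- generateCubeMesh(12, 8L, 1, grading = 2.5)
  net <- buildInitialNetwork(m, spacing = 0.6, radius = 0.03)
  ctr <- attr(m, "centre")
  din <- sqrt(rowSums(sweep(net$pos, 2, ctr)^2))
  expect_true(all(din > 0.5))                # no node inside the tumour sphere
  expect_true(all(net$pos[net$inlet, 1] == 0))
  expect_true(all(net$pos[net$outlet, 1] == 12))
  expect_true(all(net$tg == 0))
  # all interior nodes have degree 2 (no branches initially)
  deg <- angiomech:::nodeDegree(net)
  interior <- !(net$inlet | net$outlet)
  expect_true(all(deg[interior] == 2))
  expect_true(all(deg[net$inlet | net$outlet] == 1))
  # mean nearest-neighbour distance between distinct vessels ~ spacing
  ys <- unique(net$pos[, 2:3])
  d <- as.matrix(dist(ys)); diag(d) <- Inf
  expect_lt(abs(mean(apply(d, 1, min)) - 0.6) / 0.6, 0.2)
  # all segment lengths positive and no longer than needed for embedding
  expect_true(all(net$segs$L0 > 0))
  expect_error(buildInitialNetwork(m, spacing = 20), "spacing")
})

test_that("element densities count tips and well-perfused nodes", {
  m <- smallCube(6, 6L, 0)
  net <- buildInitialNetwork(m, spacing = 1, radius = 0.03)
  # empty element: none of these nodes is a tip, mark none perfused
  d0 <- updateDensities(net, m, well_perfused = rep(FALSE, nrow(net$pos)))
  expect_true(all(d0$rho_v == 0))
  expect_true(all(d0$rho_t == 0))
  # flag some tips and perfusion
  net$tip[5] <- TRUE; net$tip[6] <- TRUE
  wp <- rep(FALSE, nrow(net$pos)); wp[5] <- TRUE
  d1 <- updateDensities(net, m, well_perfused = wp)
  e5 <- net$elem[5]
  expect_identical(d1$rho_v[e5], 1)
  expect_identical(sum(d1$N_t), 2L)        # global tip-count conservation
  expect_identical(sum(d1$rho_t), 2)
  # collapsed nodes never count
  net$state[5] <- 2L
  d2 <- updateDensities(net, m, well_perfused = wp)
  expect_identical(d2$rho_v[e5], 0)
})

test_that("state writers are bit-stable and CSV round-trips", {
  m <- smallCube(6, 4L, 0)
  net <- buildInitialNetwork(m, spacing = 2, radius = 0.03)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeNetworkCSV(net, f1)
  net2 <- readNetworkCSV(f1)
  writeNetworkCSV(net2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(nrow(net2$segs), nrow(net$segs))
  # VTK outputs written, field lengths enforced
  fields <- list(tau = rep(0.5, nrow(m$nodes)))
  tv <- tempfile(fileext = ".vtk")
  writeTissueVTK(m, fields, tv)
  expect_true(any(grepl("UNSTRUCTURED_GRID", readLines(tv, n = 10))))
  expect_error(writeTissueVTK(m, list(bad = 1:3), tv), "length")
  nv <- tempfile(fileext = ".vtk")
  writeNetworkVTK(net, nv)
  expect_true(any(grepl("POLYDATA", readLines(nv, n = 10))))
  # bit-stability of the tissue writer
  tv2 <- tempfile(fileext = ".vtk")
  writeTissueVTK(m, fields, tv2)
  expect_identical(readLines(tv), readLines(tv2))
})
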