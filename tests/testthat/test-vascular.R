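# Sprouting, branching, anastomosis, wall remodelling, compression/collapse.

test_that("sprout direction combines taxis cues with unit norm", {
  p <- list(k_tau = 1, k_eps = 0, k_m = 0)
  expect_equal(sproutDirection(c(2, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), p),
               c(1, 0, 0))
  p2 <- list(k_tau = 0, k_eps = 0, k_m = 1)
  expect_equal(sproutDirection(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), p2),
               c(0, 0, -1))                      # minus sign on mechanotaxis
  # zero cue falls back to the previous direction
  expect_equal(sproutDirection(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0), c(0, 1, 0),
                               list(k_tau = 1, k_eps = 1, k_m = 1)), c(0, 1, 0))
  set.seed(2)
  p3 <- list(k_tau = 1, k_eps = 0.4, k_m = 0.3)
  for (k in 1:20) {
    e <- sproutDirection(rnorm(3), rnorm(3), rnorm(3), c(1, 0, 0), p3)
    expect_equal(sum(e^2), 1, tolerance = 1e-12)
  }
})

test_that("tip speed follows the exponential law with the small-radius clamp", {
  p <- vascParams()
  expect_equal(tipSpeed(1e3, p), p$v_v0, tolerance = 1e-6)       # R -> infinity
  expect_equal(tipSpeed(p$R_tilde, p), p$v_v0 + p$v_v1 / exp(1))
  expect_equal(tipSpeed(0.001, p), p$v_vmax)                     # R = 1 um
  expect_true(all(tipSpeed(seq(0.001, 0.1, by = 0.001), p) <= p$v_vmax))
})

test_that("tip extension obeys threshold, step length and freeze rules", {
  m <- smallCube(6, 6L)
  p <- vascParams()
  pos <- rbind(c(0, 3.5, 3.5), c(3, 3.5, 3.5))
  net <- handNetwork(pos, m, inlet = 1L, outlet = integer(0), tip = 2L)
  net$frozen[2] <- FALSE
  # below threshold: no-op
  n1 <- extendTip(net, 2L, c(1, 0, 0), tau_local = 0.5 * p$tau_star, m, p, 0.25, 1)
  expect_false(attr(n1, "extended"))
  # successful extension: new node at distance v*dt, nascent wall state
  net$R[2] <- 0.001                                # clamp regime: v = v_vmax
  n2 <- extendTip(net, 2L, c(1, 0, 0), tau_local = 1, m, p, 0.25, 1)
  expect_true(attr(n2, "extended"))
  newid <- angiomech:::nNodes(n2)
  d <- sqrt(sum((n2$pos[newid, ] - pos[2, ])^2))
  expect_equal(d, p$v_vmax * 0.25, tolerance = 1e-12)   # = 0.0625 mm
  expect_true(n2$tip[newid]); expect_false(n2$tip[2])
  expect_equal(n2$R[newid], p$R_min)
  expect_equal(n2$h[newid], p$h_min)
  expect_equal(n2$rp[newid], p$r_p_max)
  expect_equal(n2$tg[newid], 1)
  # collapsed tips never extend
  net$state[2] <- 2L
  n3 <- extendTip(net, 2L, c(1, 0, 0), 1, m, p, 0.25, 1)
  expect_false(attr(n3, "extended"))
  net$state[2] <- 0L
  # leaving the domain clamps to the boundary and freezes
  net$pos[2, ] <- c(5.99, 3.5, 3.5)
  net$R[2] <- 0.001
  n4 <- extendTip(net, 2L, c(1, 0, 0), 1, m, p, 0.25, 1)
  expect_true(attr(n4, "extended"))
  newid <- angiomech:::nNodes(n4)
  expect_equal(n4$pos[newid, 1], 6)
  expect_true(n4$frozen[newid])
})

test_that("branching probability peaks at the modes and favours hypo-perfusion", {
  b <- vascParams()$branching
  pk <- branchingProbability(b$hypo$m_A, b$hypo$m_D, "hypo", b)
  expect_equal(pk, b$hypo$w_A + b$hypo$w_D)
  far <- branchingProbability(b$hypo$m_A + 5 * b$hypo$s_A,
                              b$hypo$m_D + 5 * b$hypo$s_D, "hypo", b)
  expect_lt(far, 1e-4 * pk)
  grid_ <- expand.grid(a = seq(0, 8, by = 0.5), d = seq(0, 0.5, by = 0.05))
  Ph <- branchingProbability(grid_$a, grid_$d, "hypo", b)
  Pw <- branchingProbability(grid_$a, grid_$d, "well", b)
  expect_true(all(Ph >= Pw - 1e-12))
  # no branching node: distance component takes its modal value
  expect_equal(branchingProbability(b$hypo$m_A, NA, "hypo", b),
               b$hypo$w_A + b$hypo$w_D)
  expect_true(all(branchingProbability(runif(50, 0, 20), runif(50, 0, 2),
                                       "hypo", b) <= 1))
})

test_that("branch spawning is deterministic in the draw and respects P limits", {
  m <- smallCube(6, 6L)
  p <- vascParams()
  pos <- rbind(c(0, 3.5, 3.5), c(2, 3.5, 3.5), c(4, 3.5, 3.5), c(6, 3.5, 3.5))
  net <- handNetwork(pos, m)
  # P = 0: never branches
  n0 <- maybeBranch(net, 2L, rn = 0.5, P = 0, direction = c(0, 1, 0), m, p, 0.25, 1)
  expect_false(attr(n0, "branched"))
  # P = 1: always branches; new tip 30 degrees or more off the parent
  n1 <- maybeBranch(net, 2L, rn = 0.999, P = 1, direction = c(1, 0, 0), m, p, 0.25, 1)
  expect_true(attr(n1, "branched"))
  newid <- angiomech:::nNodes(n1)
  dirb <- (n1$pos[newid, ] - n1$pos[2, ]) /
    sqrt(sum((n1$pos[newid, ] - n1$pos[2, ])^2))
  cosang <- sum(dirb * c(1, 0, 0))
  expect_lte(cosang, cos(pi / 6) + 1e-9)
  expect_true(n1$tip[newid])
  # identical draws give identical outcomes
  n2 <- maybeBranch(net, 2L, rn = 0.999, P = 1, direction = c(1, 0, 0), m, p, 0.25, 1)
  expect_identical(n1$pos, n2$pos)
})

test_that("anastomosis respects the capture distance and adjacency", {
  m <- smallCube(6, 6L)
  pos <- rbind(c(0, 3.5, 3.5), c(2, 3.5, 3.5), c(2.039, 3.5, 3.5))
  net <- handNetwork(pos[1:2, ], m, inlet = 1L, outlet = integer(0))
  net <- angiomech:::appendNodes(net, pos = pos[3, , drop = FALSE], tg = 1,
                                 tip = TRUE, dir = matrix(c(1, 0, 0), 1),
                                 vessel = 2L,
                                 elem = locateHostElement(pos[3, ], m)$elem,
                                 lc = locateHostElement(pos[3, ], m)$lc,
                                 R = 0.005, h = 5e-4, rp = 4e-4)
  # nearest foreign node at 39 um -> segment created
  n1 <- tryAnastomose(net, 3L, capture = 0.04)
  expect_true(attr(n1, "anastomosed"))
  expect_identical(nrow(n1$segs), 2L)
  expect_false(n1$tip[3])
  # at 41 um -> no-op
  net41 <- net; net41$pos[3, 1] <- 2.041
  n2 <- tryAnastomose(net41, 3L, capture = 0.04)
  expect_false(attr(n2, "anastomosed"))
  # the tip's own neighbour is excluded
  netadj <- handNetwork(rbind(c(0, 3.5, 3.5), c(0.02, 3.5, 3.5)), m,
                        inlet = 1L, outlet = integer(0), tip = 2L)
  n3 <- tryAnastomose(netadj, 2L, capture = 0.04)
  expect_false(attr(n3, "anastomosed"))
})

test_that("remodelling time interpolates between its endpoints", {
  p <- vascParams()
  tb <- wssThreshold(0.06)                      # R = 60 um
  expect_equal(tb, 4e-4)
  expect_equal(remodellingTime(0, tb, p), 100)
  expect_equal(remodellingTime(tb, tb, p), 10)
  expect_equal(remodellingTime(2 * tb, tb, p), 10)
  # tau = tau_bar/sqrt(2): (1 - 1/2)^-1 = 2 -> t_mT + dt/e
  expect_equal(remodellingTime(tb / sqrt(2), tb, p), 10 + 90 / exp(1),
               tolerance = 1e-12)
  # continuity approaching the threshold from below
  expect_lt(abs(remodellingTime(tb * (1 - 1e-8), tb, p) - 10), 1e-3)
})

test_that("wall geometry laws: radius, thickness, pore size", {
  p <- vascParams()
  A_R <- p$R_max - p$R_min
  expect_equal(lumenRadius(5, TRUE, p), p$R_min)            # tips stay minimal
  expect_equal(lumenRadius(0, FALSE, p), p$R_min + A_R * exp(-11))
  expect_equal(lumenRadius(1, FALSE, p),
               p$R_min + A_R * exp(-11 * exp(-4.4)), tolerance = 1e-12)
  expect_equal(lumenRadius(1, FALSE, p) - p$R_min, 0.8734 * A_R, tolerance = 1e-3)
  tb <- seq(0, 3, by = 0.01)
  r <- lumenRadius(tb, FALSE, p)
  expect_true(all(diff(r) >= 0) && all(r <= p$R_max + 1e-12))
  expect_equal(wallThickness(0, p), p$h_min)
  expect_equal(wallThickness(1.7, p), p$h_max)
  expect_equal(wallThickness(0.5, p), (p$h_min + p$h_max) / 2)
  expect_equal(poreRadius(0, p), p$r_p_max)
  expect_equal(poreRadius(1, p), p$r_p_min)                 # continuous junction
  expect_equal(poreRadius(1 - 1e-9, p), p$r_p_min, tolerance = 1e-6)
  rp <- poreRadius(seq(0, 1, by = 0.01), p)
  expect_true(all(diff(rp) <= 1e-15))
})

test_that("pressure ratio and the quadratic wall-strain inversion", {
  expect_equal(pressureRatio(3, 2, 5), 1)
  expect_equal(pressureRatio(0, 0, 5), 0)
  expect_gte(pressureRatio(1, 1, 0), 1e6)       # degenerate guard
  expect_equal(pressureRatio(-1, 0, 0), 0)
  expect_equal(wallStrain(1, 3.4, 0.92), 0)
  expect_equal(wallStrain(3.4, 3.4, 0.92), 0.92)
  # root-finding oracle for the mid-range case
  pc <- 3.4; ec <- 0.92; pbar <- 2.2
  f <- function(x) 1 + (2 * pc - 2) * x - (pc - 1) * x^2 - pbar
  x_or <- stats::uniroot(f, c(0, 1), tol = 1e-14)$root
  expect_equal(wallStrain(pbar, pc, ec), x_or * ec, tolerance = 1e-10)
  expect_equal(wallStrain(pbar, pc, ec), 0.26947, tolerance = 1e-4)
})

test_that("wall stiffness maps to collapse pressure in both directions", {
  expect_equal(signif(stiffnessFromPc(1.6, 0.92), 3), 1.30)
  expect_equal(signif(stiffnessFromPc(3.4, 0.92), 3), 5.22)
  expect_equal(signif(pcFromStiffness(1.3, 0.92), 3), 1.60)
  expect_equal(signif(pcFromStiffness(5.22, 0.92), 3), 3.40)
  for (pc in seq(1.2, 5, by = 0.2))
    expect_equal(pcFromStiffness(stiffnessFromPc(pc)), pc, tolerance = 1e-12)
})

test_that("compression is reversible, collapse permanent and propagating", {
  m <- smallCube(6, 6L)
  p <- vascParams()
  # inlet - A - B - C - D(tip): nascent nodes (tbar 0 -> p_c = 1.6)
  pos <- rbind(c(0, 3.5, 3.5), c(1, 3.5, 3.5), c(2, 3.5, 3.5),
               c(3, 3.5, 3.5), c(4, 3.5, 3.5))
  net <- handNetwork(pos, m, inlet = 1L, outlet = integer(0), tip = 5L, tg = 1)
  net$tbar[] <- 0
  pv <- rep(10, 5)
  # moderate load on node 3: compressed, radius reduced reversibly
  load <- c(5, 5, 14, 5, 5)                     # pbar = 1.4 at node 3
  n1 <- applyCompressionAndCollapse(net, load, rep(0, 5), pv, p)
  expect_identical(n1$state[3], 1L)
  expect_lt(n1$R[3], n1$R0[3])
  n1b <- applyCompressionAndCollapse(n1, rep(5, 5), rep(0, 5), pv, p)
  expect_identical(n1b$state[3], 0L)
  expect_equal(n1b$R[3], n1b$R0[3])             # elastic recovery
  # collapse node 3: distal run (4, 5) has no route and collapses too
  load2 <- c(5, 5, 20, 5, 5)                    # pbar = 2 >= 1.6
  n2 <- applyCompressionAndCollapse(net, load2, rep(0, 5), pv, p)
  expect_identical(n2$state[3], 2L)
  expect_identical(n2$state[4], 2L)
  expect_identical(n2$state[5], 2L)
  expect_identical(n2$state[2], 0L)             # proximal side keeps its route
  expect_identical(attr(n2, "n_collapsed"), 3L)
  expect_equal(n2$R[3], n2$R0[3] / p$lambda_r)
  # an anastomosis back to node 2 gives the distal run a second route
  net3 <- angiomech:::addSegment(net, 5L, 2L)
  n3 <- applyCompressionAndCollapse(net3, load2, rep(0, 5), pv, p)
  expect_identical(n3$state[3], 2L)
  expect_identical(n3$state[4], 0L)
  expect_identical(n3$state[5], 0L)
})

test_that("no load leaves the network untouched", {
  m <- smallCube(6, 6L)
  net <- handNetwork(rbind(c(0, 3.5, 3.5), c(3, 3.5, 3.5), c(6, 3.5, 3.5)), m)
  p <- vascParams()
  n <- applyCompressionAndCollapse(net, rep(2, 3), rep(0, 3), rep(10, 3), p)
  expect_true(all(n$state == 0L))
  expect_equal(n$R, net$R)
})

test_that("tip bookkeeping: tips are exactly the live degree-1 sprout ends", {
  m <- smallCube(6, 6L)
  p <- vascParams()
  net <- buildInitialNetwork(m, spacing = 1.5, radius = 0.03)
  # grow a few tips and branches deterministically
  net <- angiomech:::appendNodes(net, matrix(c(3, 2.2, 2.2), 1), tg = 1, tip = TRUE,
                                 dir = matrix(c(0, 1, 0), 1), vessel = 99L,
                                 elem = locateHostElement(c(3, 2.2, 2.2), m)$elem,
                                 lc = locateHostElement(c(3, 2.2, 2.2), m)$lc,
                                 R = p$R_min, h = p$h_min, rp = p$r_p_max)
  base <- which(abs(net$pos[, 1] - 3) < 0.4 & net$vessel == 1L)[1]
  net <- angiomech:::addSegment(net, base, angiomech:::nNodes(net))
  for (k in 1:4)
    net <- extendTip(net, which(net$tip)[1], c(0, 1, 0), 1, m, p, 0.25, 1 + k / 4)
  deg <- angiomech:::nodeDegree(net)
  live_deg1 <- which(deg == 1 & !net$inlet & !net$outlet & !net$frozen &
                     net$state != 2L)
  expect_setequal(which(net$tip), live_deg1)
  expect_true(all(segmentLengths(net) > 0))
})

test_that("chemotaxis-only guidance points tips towards a radial attractant", {
  # synthetic radially-decaying attractant around a centre
  set.seed(31)
  ctr <- c(3, 3, 3)
  p <- list(k_tau = 1, k_eps = 0, k_m = 0)
  dots <- replicate(100, {
    x <- ctr + runif(3, -2, 2)
    g <- (ctr - x) / sqrt(sum((ctr - x)^2))  # gradient points inwards
    e <- sproutDirection(g * runif(1, 0.1, 2), c(0, 0, 0), c(0, 0, 0),
                         prev = c(1, 0, 0), p)
    sum(e * g)
  })
  expect_gt(mean(dots), 0.9)
})
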