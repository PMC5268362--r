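# Coupled multiscale driver: biochemical sub-cycling (seconds), hourly solid
# equilibrium solves, six-hourly vascular network updates with a coupled
# flow solve and a post-flow collapse re-assessment.

#' Initialise the full simulation state
#'
#' Builds (or loads) the mesh and the initial parallel capillary network,
#' sets the initial conditions (tau = mu = 0 everywhere, xi = 1 in the host
#' and 0 in the tumour, eps = 1, zero deformation), solves the initial flow,
#' and stores the day-0 vascular density as normalisation denominator.
#'
#' @param config an \code{angio_config}.
#' @return an \code{angio_state}.
#' @export
initialiseSimulation <- function(config) {
  set.seed(config$seed)
  dm <- config$domain
  mesh <- if (!is.null(dm$mesh_file)) loadMesh(dm$mesh_file) else
    generateCubeMesh(dm$edge_length, dm$n_per_side, dm$tumour_diameter, dm$grading)
  val <- validateConfig(config, mesh)
  if (!val$ok) stopf("invalid configuration:\n%s", paste(val$errors, collapse = "\n"))
  nw <- config$network
  net <- buildInitialNetwork(mesh, nw$spacing, nw$radius, nw$thickness, nw$pore_radius)
  N <- nrow(mesh$nodes); E <- nrow(mesh$elems)
  tumour_node <- rep(FALSE, N)
  tumour_node[unique(as.vector(mesh$elems[mesh$label == 2L, ]))] <- TRUE
  fields <- list(tau = numeric(N), xi = as.numeric(!tumour_node),
                 mu = numeric(N), eps = rep(1, N), tumour_node = tumour_node)
  ops <- biochemOperators(mesh)
  # node <- element incidence (mean / volume-weighted projections)
  ii <- as.vector(mesh$elems)
  jj <- rep(seq_len(E), times = 8)
  Ainc <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(N, E))
  Aw <- Matrix::sparseMatrix(i = ii, j = jj, x = mesh$volumes[jj], dims = c(N, E))
  incid <- list(mean_div = as.numeric(Ainc %*% rep(1, E)),
                Ainc = Ainc, Aw = Aw,
                vol_div = as.numeric(Aw %*% rep(1, E)))
  matpars <- rbind(config$solid$host, config$solid$tumour)
  solid <- list(
    u = matrix(0, N, 3),
    th_g = numeric(E * 8), th_gx = numeric(E * 8), th_ge = numeric(E * 8),
    Fg = rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), E * 8),
    zeta_q = rep(1, E * 8),
    matpars = matpars,
    solver = solidSolver(mesh, c(mesh$inlet_nodes, mesh$outlet_nodes)),
    S_elem = matrix(0, E, 6), thp_elem = numeric(E), detF = rep(1, E),
    thp_node = numeric(N)
  )
  flow <- solveCoupledPressures(net, mesh, config$fluid)
  net$wss <- flow$node_tauf
  net$vel <- flow$node_v
  dens <- updateDensities(net, mesh, v_thresh = config$vascular$v_well)
  day0 <- vascularDensity(net, sum(mesh$volumes))
  state <- structure(list(
    config = config, mesh = mesh, net = net, fields = fields, ops = ops,
    incid = incid, solid = solid, flow = flow, dens = dens,
    time = 0, day0_density = day0,
    counters = c(sprouts = 0, branches = 0, anastomoses = 0, collapses = 0),
    metrics = NULL
  ), class = "angio_state")
  state$metrics <- computeMetricsRow(state, full = TRUE)
  state
}

#' @method print angio_state
#' @export
print.angio_state <- function(x, ...) {
  cat(sprintf("angio_state: day %.2f\n", x$time))
  print(x$mesh)
  print(x$net)
  cat(sprintf("  events: %s\n",
              paste(names(x$counters), x$counters, sep = "=", collapse = ", ")))
  invisible(x)
}

# element-mean of a nodal field at quadrature points: returns nq x E matrix
nodalToQuad <- function(field, mesh) {
  fcon <- matrix(field[t(mesh$elems)], 8, nrow(mesh$elems))
  mesh$quad$Nq %*% fcon
}

# update growth ratchets and rebuild the growth tensor field (flattened).
# Growth is irreversible (running maximum) and rate-limited: the volumetric
# strain may not advance faster than d(ln J_g)/dt = g_max (tissue cannot
# double its volume faster than ~daily), i.e. dtheta <= (2 theta+1) g_max dt/3.
updateGrowthField <- function(state, dt = state$config$time$dt_solid) {
  mesh <- state$mesh; cfg <- state$config$solid
  E <- nrow(mesh$elems)
  tum <- which(mesh$label == 2L)
  sol <- state$solid
  g_max <- cfg$g_max %||% 0.7
  ratchet <- function(prev, target) {
    cap <- prev + (2 * prev + 1) * g_max * dt / 3
    pmin(pmax(prev, target), cap)
  }
  if (length(tum)) {
    xiq <- nodalToQuad(state$fields$xi, mesh)       # 8 x E
    gx <- computeGradients(state$fields$xi, mesh)   # 3 x 8 x E
    ge <- computeGradients(state$fields$eps, mesh)
    for (e in tum) {
      for (q in 1:8) {
        iq <- (e - 1) * 8 + q
        xi <- xiq[q, e]
        sol$th_g[iq] <- ratchet(sol$th_g[iq],
                                growthVolumeStrain(xi, cfg$alpha_g, cfg$beta_g, cfg$gamma_g))
        sol$th_gx[iq] <- ratchet(sol$th_gx[iq],
                                 growthVolumeStrain(xi, cfg$growth_xi[["alpha"]],
                                                    cfg$growth_xi[["beta"]],
                                                    cfg$growth_xi[["gamma"]]))
        sol$th_ge[iq] <- ratchet(sol$th_ge[iq],
                                 growthVolumeStrain(xi, cfg$growth_eps[["alpha"]],
                                                    cfg$growth_eps[["beta"]],
                                                    cfg$growth_eps[["gamma"]]))
        Fgq <- growthTensor(sol$th_g[iq], sol$th_gx[iq], sol$th_ge[iq],
                            gx[, q, e], ge[, q, e])
        sol$Fg[(iq - 1) * 9 + 1:9] <- as.vector(t(Fgq))
      }
    }
  }
  # ECM integrity at quadrature points: eps in the host, 1 in the tumour
  zq <- nodalToQuad(state$fields$eps, mesh)
  zq[, mesh$label == 2L] <- 1
  sol$zeta_q <- clamp(as.numeric(zq), 1e-3, 1)
  state$solid <- sol
  state
}

solidStep <- function(state) {
  state <- updateGrowthField(state)
  sol <- state$solid
  res <- solveEquilibrium(state$mesh, Fg = sol$Fg, zeta_q = sol$zeta_q,
                          matpars = sol$matpars, u0 = sol$u,
                          Fg_prev = sol$Fg_prev %||% NULL,
                          solver = sol$solver)
  sol$u <- res$u
  # the converged growth state (equal to the target unless an increment was
  # carried over; the remainder is re-attempted at the next hourly solve)
  sol$Fg_prev <- res$Fg_applied
  if (res$growth_fraction < 1 - 1e-9)
    sol$carryover <- (sol$carryover %||% 0L) + 1L
  sf <- solidStressField(state$mesh, sol$u, res$Fg_applied, sol$zeta_q, sol$matpars)
  sol$S_elem <- sf$S
  sol$thp_elem <- if (identical(state$config$solid$thp_measure, "reference"))
    sf$thp_ref else sf$thp_cauchy
  sol$detF <- sf$detF
  # volume-weighted nodal projection of the element hydrostatic pressure
  sol$thp_node <- as.numeric(state$incid$Aw %*% sol$thp_elem) / state$incid$vol_div
  state$solid <- sol
  state
}

biochemHour <- function(state) {
  cfg <- state$config$biochem
  mesh <- state$mesh; ops <- state$ops
  f <- state$fields
  dtb <- stableTimestep(mesh, cfg, state$config$time$dt_solid)
  nsub <- max(1L, ceiling((1 / 24) / as.numeric(dtb)))
  dt <- (1 / 24) / nsub
  # element densities -> nodal (mean over incident elements)
  rho_v_node <- as.numeric(state$incid$Ainc %*% state$dens$rho_v) / state$incid$mean_div
  rho_t_node <- as.numeric(state$incid$Ainc %*% state$dens$rho_t) / state$incid$mean_div
  src_xi <- cfg$lambda_xi * rho_v_node
  src_mu <- mmpProduction(rho_t_node, f$tumour_node, cfg)
  host <- !f$tumour_node
  for (s in seq_len(nsub)) {
    src_tau <- tafProduction(f$xi, f$tumour_node, cfg)
    f$tau <- stepReactionDiffusion(f$tau, cfg$D_tau, src_tau, cfg$delta_tau, dt, ops)
    f$xi <- stepReactionDiffusion(f$xi, cfg$D_xi, src_xi, cfg$delta_xi, dt, ops)
    f$mu <- stepReactionDiffusion(f$mu, cfg$D_mu, src_mu, cfg$delta_mu, dt, ops)
    f$eps <- stepECM(f$eps, f$mu, dt, cfg$delta_eps, host, cfg$eps_floor)
  }
  state$fields <- f
  state
}

# taxis weights for the current mode
taxisWeights <- function(config) {
  v <- config$vascular
  if (identical(config$taxis_mode, "chemo_only"))
    list(k_tau = v$k_tau, k_eps = 0, k_m = 0)
  else list(k_tau = v$k_tau, k_eps = v$k_eps, k_m = v$k_m)
}

# direction cue for one vascular node (gradients + traction at its location)
nodeTaxisDirection <- function(state, i, kw) {
  mesh <- state$mesh; net <- state$net
  e <- net$elem[i]
  prev <- net$dir[i, ]
  if (is.na(e)) return(prev)
  gt <- gradientAtLocal(state$fields$tau, mesh, e, net$lc[i, ])
  ge <- gradientAtLocal(state$fields$eps, mesh, e, net$lc[i, ])
  tr <- c(0, 0, 1)
  if (kw$k_m > 0) {
    Sv <- state$solid$S_elem[e, ]
    S <- matrix(c(Sv[1], Sv[4], Sv[5],
                  Sv[4], Sv[2], Sv[6],
                  Sv[5], Sv[6], Sv[3]), 3, 3)
    tr <- tractionDirection(S, prev = prev)
  }
  sproutDirection(gt, ge, tr, prev, kw)
}

vascularUpdate <- function(state) {
  cfg <- state$config
  vs <- cfg$vascular
  mesh <- state$mesh
  net <- state$net
  now <- state$time + cfg$time$dt_v
  kw <- taxisWeights(cfg)
  n0 <- nNodes(net)
  tau_at <- fieldAtLocal(state$fields$tau, mesh, net$elem, net$lc)
  thp_at <- fieldAtLocal(state$solid$thp_node, mesh, net$elem, net$lc) * KPA_TO_MMHG
  pint_at <- fieldAtLocal(state$flow$p_int, mesh, net$elem, net$lc)
  pbar <- pressureRatio(ifelse(is.na(pint_at), 0, pint_at),
                        ifelse(is.na(thp_at), 0, thp_at), state$flow$p_vsc)
  Ew <- vs$E_w_min + clamp(net$tbar, 0, 1) * (vs$E_w_max - vs$E_w_min)
  p_c <- pcFromStiffness(Ew, vs$e_c)
  ok_mech <- pbar < p_c
  # --- tip extension
  tips <- which(net$tip & !net$frozen & net$state != STATE_COLLAPSED)
  n_sprout <- 0
  for (i in tips) {
    if (is.na(tau_at[i]) || tau_at[i] < vs$tau_star || !ok_mech[i]) next
    dir_ <- nodeTaxisDirection(state2net(state, net), i, kw)
    net <- extendTip(net, i, dir_, tau_at[i], mesh, vs, cfg$time$dt_v, now)
    if (isTRUE(attr(net, "extended"))) n_sprout <- n_sprout + 1
  }
  # --- stochastic branching (draws consumed in node-id order over the nodes
  # present at step start; inhibition distances evaluated at step start)
  draws <- stats::runif(n0)
  bdist <- branchDistances(state$net)
  eligible <- which(!net$tip[seq_len(n0)] & !net$frozen[seq_len(n0)] &
                    net$state[seq_len(n0)] != STATE_COLLAPSED &
                    !net$inlet[seq_len(n0)] & !net$outlet[seq_len(n0)] &
                    !is.na(tau_at[seq_len(n0)]) & tau_at[seq_len(n0)] >= vs$tau_star &
                    ok_mech[seq_len(n0)])
  n_branch <- 0
  for (i in eligible) {
    cls <- if (net$vel[i] < vs$v_well) "hypo" else "well"
    P <- branchingProbability(now - net$tg[i], bdist[i] %||% NA, cls, vs$branching)
    if (draws[i] >= P) next
    dir_ <- nodeTaxisDirection(state2net(state, net), i, kw)
    net <- maybeBranch(net, i, draws[i], P, dir_, mesh, vs, cfg$time$dt_v, now)
    if (isTRUE(attr(net, "branched"))) n_branch <- n_branch + 1
  }
  # --- anastomosis
  n_ana <- 0
  for (i in which(net$tip)) {
    net <- tryAnastomose(net, i, vs$anastomosis_dist)
    if (isTRUE(attr(net, "anastomosed"))) n_ana <- n_ana + 1
  }
  # --- wall remodelling (pre-existing vessels t_g = 0 are exempt)
  rem <- which(net$tg > 0 & net$state != STATE_COLLAPSED)
  if (length(rem)) {
    tau_bar <- wssThreshold(net$R[rem], vs$tauf_coef)
    tm <- remodellingTime(net$wss[rem], tau_bar, vs)
    net$tbar[rem] <- (now - net$tg[rem]) / tm
    net$R0[rem] <- lumenRadius(net$tbar[rem], net$tip[rem], vs)
    net$h[rem] <- wallThickness(net$tbar[rem], vs)
    net$rp[rem] <- poreRadius(net$tbar[rem], vs)
    net$R[rem] <- net$R0[rem]   # compression reapplied after the flow solve
  }
  state$net <- net
  state$counters["sprouts"] <- state$counters["sprouts"] + n_sprout
  state$counters["branches"] <- state$counters["branches"] + n_branch
  state$counters["anastomoses"] <- state$counters["anastomoses"] + n_ana
  state
}

# helper: a shallow state whose $net is replaced (for direction queries while
# the network is being grown)
state2net <- function(state, net) {
  state$net <- net
  state
}

# deformed vascular node positions
deformedPositions <- function(state, net = state$net) {
  u_at <- vectorFieldAtLocal(state$solid$u, state$mesh, net$elem, net$lc)
  u_at[is.na(u_at)] <- 0
  net$pos + u_at
}

collapsePass <- function(state) {
  net <- state$net
  thp_at <- fieldAtLocal(state$solid$thp_node, state$mesh, net$elem, net$lc) * KPA_TO_MMHG
  pint_at <- fieldAtLocal(state$flow$p_int, state$mesh, net$elem, net$lc)
  net <- applyCompressionAndCollapse(net, ifelse(is.na(pint_at), 0, pint_at),
                                     ifelse(is.na(thp_at), 0, thp_at),
                                     state$flow$p_vsc, state$config$vascular)
  state$counters["collapses"] <- state$counters["collapses"] + attr(net, "n_collapsed")
  state$net <- net
  attr(state, "n_collapsed") <- attr(net, "n_collapsed")
  state
}

#' Advance the simulation by one vascular step
#'
#' Runs the multi-timescale cycle: biochemical sub-steps and hourly solid
#' solves across one vascular increment, then the vascular network update
#' (extension, branching, anastomosis, remodelling), the coupled flow solve,
#' and the post-flow collapse re-assessment (with a flow re-solve if the
#' topology changed).
#'
#' @param state an \code{angio_state}.
#' @return the advanced state.
#' @export
vascularStep <- function(state) {
  cfg <- state$config
  n_hours <- round(cfg$time$dt_v / cfg$time$dt_solid)
  for (h in seq_len(n_hours)) {
    state <- biochemHour(state)
    state <- solidStep(state)
  }
  state <- vascularUpdate(state)
  state$dens <- updateDensities(state$net, state$mesh,
                                v_thresh = cfg$vascular$v_well)
  pos_cur <- deformedPositions(state)
  state$flow <- solveCoupledPressures(state$net, state$mesh, cfg$fluid,
                                      pos_cur = pos_cur, u = state$solid$u)
  state <- collapsePass(state)
  if (attr(state, "n_collapsed") > 0) {
    state$flow <- solveCoupledPressures(state$net, state$mesh, cfg$fluid,
                                        pos_cur = deformedPositions(state),
                                        u = state$solid$u)
  }
  state$net$wss <- state$flow$node_tauf
  state$net$vel <- state$flow$node_v
  state$dens <- updateDensities(state$net, state$mesh,
                                v_thresh = cfg$vascular$v_well)
  state$time <- state$time + cfg$time$dt_v
  state
}

computeMetricsRow <- function(state, full = FALSE) {
  mesh <- state$mesh
  cfg <- state$config
  tum <- mesh$label == 2L
  tum_vol <- sum(mesh$volumes[tum] * state$solid$detF[tum])
  tot_vol <- sum(mesh$volumes * state$solid$detF)
  pos_cur <- deformedPositions(state)
  nvd <- vascularDensity(state$net, tot_vol, pos_cur, day0 = state$day0_density)
  tnode <- state$fields$tumour_node
  plateau <- if (any(tnode)) mean(state$flow$p_int[tnode]) else NA_real_
  max_ifv <- max(abs(state$flow$edges$v_int)) * 1000  # um/s
  pc <- perfusionClassification(state$net, state$flow$seg_v, pos_cur)
  icd <- lam <- dvm <- NA_real_
  if (full) {
    icd <- intercapillaryDistance(state$net, cfg$output$icd_spacing, pos_cur)
    centre <- attr(mesh, "centre") %||% colMeans(rbind(mesh$bbox[1, ], mesh$bbox[2, ]))
    r_t <- (3 * tum_vol / (4 * pi))^(1 / 3)
    dm <- distanceMap(state$net, centre, r_t + 1, cfg$output$voxel, pos_cur)
    if (dm$valid) {
      sp <- scalingParameters(dm$delta, cfg$output$voxel)
      lam <- sp$lambda_v; dvm <- sp$delta_v_max
    }
  }
  data.frame(day = state$time, tumour_volume_mm3 = tum_vol,
             norm_vasc_density = nvd, mean_icd_mm = icd,
             plateau_ifp_mmhg = plateau, max_ifv_um_s = max_ifv,
             frac_hypo = pc$by_count[["hypo"]],
             frac_perfused = pc$by_count[["perfused"]],
             frac_well = pc$by_count[["well"]],
             frac_collapsed = pc$by_count[["collapsed"]],
             n_segments = nrow(state$net$segs),
             n_collapsed_segments = sum(!functionalSegs(state$net)),
             lambda_v = lam, delta_v_max = dvm)
}

#' Run the coupled simulation
#'
#' @param config an \code{angio_config} (ignored when \code{state} resumes a
#'   run).
#' @param state optional state to resume from (e.g. a checkpoint).
#' @param days simulated horizon in days (default from the config).
#' @param checkpoint_path optional RDS path written every
#'   \code{checkpoint_every} days.
#' @param checkpoint_every checkpoint cadence (days).
#' @param quiet suppress progress output.
#' @return the final \code{angio_state}; \code{$metrics} holds the
#'   time-series (one row per vascular step at the metrics cadence).
#' @export
runSimulation <- function(config = defaultConfig(), state = NULL, days = NULL,
                          checkpoint_path = NULL, checkpoint_every = NULL,
                          quiet = TRUE) {
  if (is.null(state)) {
    state <- initialiseSimulation(config)
  } else {
    if (!is.null(state$rng)) assign(".Random.seed", state$rng, envir = globalenv())
  }
  cfg <- state$config
  target <- days %||% cfg$time$days
  last_cp <- state$time
  while (state$time < target - 1e-9) {
    state <- vascularStep(state)
    me <- cfg$output$morphometrics_every
    full <- abs(state$time / me - round(state$time / me)) < 1e-9
    state$metrics <- rbind(state$metrics, computeMetricsRow(state, full = full))
    if (!quiet)
      message(sprintf("day %.2f: %d nodes, %d segs, nvd %.3f",
                      state$time, nNodes(state$net), nrow(state$net$segs),
                      utils::tail(state$metrics$norm_vasc_density, 1)))
    if (!is.null(checkpoint_path) && !is.null(checkpoint_every) &&
        state$time - last_cp >= checkpoint_every - 1e-9) {
      writeCheckpoint(state, checkpoint_path)
      last_cp <- state$time
    }
  }
  # snapshot the stream so resuming this state (in memory or from disk)
  # reproduces an uninterrupted run
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

#' Write / read a bit-exact simulation checkpoint
#'
#' The checkpoint carries the full state including the random-number stream,
#' so a resumed run reproduces an uninterrupted one exactly.
#'
#' @param state an \code{angio_state}.
#' @param path RDS file.
#' @export
writeCheckpoint <- function(state, path) {
  # force the promise before reading the RNG: complex assignment evaluates
  # its value first, which would otherwise snapshot the pre-run stream when
  # called as writeCheckpoint(runSimulation(...))
  force(state)
  state$rng <- get(".Random.seed", envir = globalenv())
  saveRDS(state, path)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) readRDS(path)
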