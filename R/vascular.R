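# Capillary sprouting, branching, anastomosis, wall remodelling and
# stress-induced compression/collapse of the discrete vascular network.

#' Sprout elongation direction
#'
#' Linear superposition of chemotaxis (TAF gradient), haptotaxis (ECM
#' gradient) and mechanotaxis (minus the traction direction), normalised to a
#' unit vector; falls back to the previous direction when the combined cue
#' vanishes.
#'
#' @param grad_tau,grad_eps gradient vectors (1/mm).
#' @param traction traction direction (unit vector) from
#'   \code{\link{tractionDirection}}.
#' @param prev previous unit direction.
#' @param params list with weights \code{k_tau}, \code{k_eps}, \code{k_m}.
#' @return unit vector.
#' @export
sproutDirection <- function(grad_tau, grad_eps, traction, prev, params) {
  l <- params$k_tau * grad_tau + params$k_eps * grad_eps - params$k_m * traction
  u <- unitVector(l)
  if (is.null(u)) return(prev)
  u
}

#' Tip extension speed
#'
#' Exponential decay of the elongation speed with lumen radius,
#' \code{v = v_v0 + v_v1 exp(-R / R_tilde)}, clamped at \code{v_vmax}; below
#' the small-radius cutoff the maximum speed is enforced.
#'
#' @param R lumen radius (mm), vectorised.
#' @param params list with \code{v_v0}, \code{v_v1} (mm/day), \code{R_tilde}
#'   (mm), \code{v_vmax} (mm/day), \code{R_cutoff} (mm).
#' @return speed (mm/day).
#' @export
tipSpeed <- function(R, params) {
  v <- params$v_v0 + params$v_v1 * exp(-R / params$R_tilde)
  ifelse(R < params$R_cutoff, params$v_vmax, pmin(v, params$v_vmax))
}

#' Stochastic branching probability
#'
#' Superposition of two Gaussian components - one in the node age, one in the
#' distance (along the network) to the nearest branching node - each scaled
#' by its mode so the combination lies in [0, 1]. Hypo-perfused vessels carry
#' a more permissive parameter set than well-perfused ones.
#'
#' @param age node age (days).
#' @param dist distance to the nearest branch (mm); NA when no branching node
#'   exists, in which case the distance component takes its modal value.
#' @param perfusion_class "hypo" or "well".
#' @param params branching parameter list (per class: \code{m_A}, \code{s_A},
#'   \code{w_A}, \code{m_D}, \code{s_D}, \code{w_D}).
#' @return probability in [0, 1].
#' @export
branchingProbability <- function(age, dist, perfusion_class = c("hypo", "well"),
                                 params) {
  perfusion_class <- match.arg(perfusion_class)
  p <- params[[perfusion_class]]
  PA <- p$w_A * exp(-(age - p$m_A)^2 / (2 * p$s_A^2))
  PD <- ifelse(is.na(dist), p$w_D,
               p$w_D * exp(-(dist - p$m_D)^2 / (2 * p$s_D^2)))
  clamp(PA + PD, 0, 1)
}

#' Wall-shear-stress remodelling time
#'
#' \code{t_m = t_mT} above the shear threshold; below it the remodelling time
#' rises smoothly to \code{t_m0} at zero shear:
#' \code{t_mT + (t_m0 - t_mT) exp(1 - (1 - tau_f^2/tau_bar^2)^-1)}.
#'
#' @param tau_f wall shear stress (mm-Hg), vectorised.
#' @param tau_bar shear threshold (mm-Hg), vectorised (radius-dependent).
#' @param params list with \code{t_m0}, \code{t_mT} (days).
#' @return remodelling time (days).
#' @export
remodellingTime <- function(tau_f, tau_bar, params) {
  dt <- params$t_m0 - params$t_mT
  x2 <- (tau_f / tau_bar)^2
  slow <- params$t_mT + dt * exp(1 - 1 / pmax(1 - x2, 1e-300))
  ifelse(tau_f >= tau_bar, params$t_mT, slow)
}

#' Radius-dependent wall-shear-stress threshold
#'
#' \code{tau_bar = 2.4e-8 / R} mm-Hg with the radius in metres; equivalently
#' \code{8 mu_B v_thresh / R} at the 0.1 mm/s hypo/well perfusion velocity
#' threshold.
#'
#' @param R lumen radius in mm.
#' @param coef threshold coefficient in mm-Hg m.
#' @return threshold in mm-Hg.
#' @export
wssThreshold <- function(R, coef = 2.4e-8) coef / (R * 1e-3)

#' Lumen radius remodelling law
#'
#' Tip nodes keep the minimum radius; other remodelling nodes follow the
#' Gompertz curve \code{R_min + A_R exp(-B_R exp(-C_R t_bar))} with
#' \code{A_R = R_max - R_min}, \code{B_R = 11}, \code{C_R = 4.4}.
#'
#' @param tbar normalised remodelling age (t - t_g)/t_m, vectorised.
#' @param is_tip logical, vectorised.
#' @param params list with \code{R_min}, \code{R_max} (mm), \code{B_R},
#'   \code{C_R}.
#' @return lumen radius (mm).
#' @export
lumenRadius <- function(tbar, is_tip, params) {
  A_R <- params$R_max - params$R_min
  r <- params$R_min + A_R * exp(-params$B_R * exp(-params$C_R * pmax(tbar, 0)))
  ifelse(is_tip, params$R_min, r)
}

#' Wall thickness remodelling law (linear, h_min to h_max)
#' @param tbar normalised remodelling age.
#' @param params list with \code{h_min}, \code{h_max} (mm).
#' @export
wallThickness <- function(tbar, params) {
  params$h_min + clamp(tbar, 0, 1) * (params$h_max - params$h_min)
}

#' Pore radius remodelling law
#'
#' Cubic decay \code{A_r t^3 + B_r t^2 + C_r} from \code{r_p_max} at birth to
#' \code{r_p_min} at full remodelling, with \code{C_r = r_p_max},
#' \code{B_r = 3 (r_p_min - r_p_max)}, \code{A_r = 2 (r_p_max - r_p_min)}.
#'
#' @param tbar normalised remodelling age.
#' @param params list with \code{r_p_min}, \code{r_p_max} (mm).
#' @export
poreRadius <- function(tbar, params) {
  Cr <- params$r_p_max
  Br <- 3 * (params$r_p_min - params$r_p_max)
  Ar <- 2 * (params$r_p_max - params$r_p_min)
  t_ <- pmax(tbar, 0)
  ifelse(t_ >= 1, params$r_p_min, Ar * t_^3 + Br * t_^2 + Cr)
}

#' Wall pressure ratio
#'
#' \code{pbar = (p_int + p_h) / p_vsc}: external (interstitial + solid) over
#' internal (blood) pressure. Non-positive blood pressure with a positive
#' numerator returns a large sentinel (treated as above any collapse
#' threshold).
#'
#' @param p_int interstitial fluid pressure (mm-Hg).
#' @param p_h tissue hydrostatic (solid) pressure (mm-Hg).
#' @param p_vsc blood pressure (mm-Hg).
#' @param sentinel value returned for the degenerate case.
#' @export
pressureRatio <- function(p_int, p_h, p_vsc, sentinel = 1e6) {
  num <- p_int + p_h
  ifelse(p_vsc > 1e-12, num / p_vsc, ifelse(num > 0, sentinel, 0))
}

#' Radial wall strain from the quadratic collapse law
#'
#' Inverts \code{pbar = 1 + (2 p_c - 2)(e_r/e_c) - (p_c - 1)(e_r/e_c)^2}
#' (smaller root) for \code{1 < pbar < p_c}; zero below physiological load,
#' the critical strain \code{e_c} at or beyond the collapse pressure.
#'
#' @param pbar wall pressure ratio, vectorised.
#' @param p_c critical collapse pressure ratio, vectorised.
#' @param e_c critical radial strain.
#' @return radial strain \code{e_r}.
#' @export
wallStrain <- function(pbar, p_c, e_c) {
  b <- 2 * p_c - 2
  a <- p_c - 1
  disc <- pmax(b^2 - 4 * a * (pbar - 1), 0)
  x <- (b - sqrt(disc)) / (2 * a)
  ifelse(pbar <= 1, 0, ifelse(pbar >= p_c, e_c, x * e_c))
}

#' Wall stiffness / collapse pressure conversions
#'
#' The maximum wall rigidity modulus of the quadratic collapse law is
#' \code{E_w_max = 2 (p_c - 1)/e_c}; these helpers convert in both
#' directions.
#'
#' @param p_c critical collapse pressure ratio.
#' @param E wall stiffness modulus (dimensionless).
#' @param e_c critical radial strain.
#' @export
stiffnessFromPc <- function(p_c, e_c = 0.92) 2 * (p_c - 1) / e_c

#' @rdname stiffnessFromPc
#' @export
pcFromStiffness <- function(E, e_c = 0.92) 1 + E * e_c / 2

#' Extend a vascular tip
#'
#' Moves the tip by \code{d = v_v dt_v e_hat}: a new node is appended at the
#' advanced position with birth time \code{now}, nascent wall properties
#' (R_min, h_min, r_p_max) and tip status; the old node loses tip status.
#' Requires local TAF at or above the sprouting threshold; collapsed or
#' boundary-frozen tips are no-ops. A step leaving the domain is clamped to
#' the boundary and the new node permanently frozen.
#'
#' @param net an \code{angio_network}.
#' @param tip node index of the tip.
#' @param direction unit extension direction.
#' @param tau_local normalised TAF concentration at the tip.
#' @param mesh the tissue mesh.
#' @param params vascular parameter list (tip kinetics + \code{tau_star}).
#' @param dt_v vascular time step (days).
#' @param now current time (days).
#' @return the updated network (unchanged for a no-op); attribute
#'   \code{"extended"} is TRUE/FALSE.
#' @export
extendTip <- function(net, tip, direction, tau_local, mesh, params, dt_v, now) {
  noop <- function(net) { attr(net, "extended") <- FALSE; net }
  if (!net$tip[tip] || net$frozen[tip] || net$state[tip] == STATE_COLLAPSED)
    return(noop(net))
  if (is.na(tau_local) || tau_local < params$tau_star) return(noop(net))
  v <- tipSpeed(net$R[tip], params)
  d <- v * dt_v * direction
  newpos <- net$pos[tip, ] + d
  bb <- mesh$bbox
  frozen <- FALSE
  # clamp against the domain bounding box (cube domain): largest step fraction
  s <- 1
  for (k in 1:3) {
    if (d[k] > 0) s <- min(s, (bb[2, k] - net$pos[tip, k]) / d[k])
    if (d[k] < 0) s <- min(s, (bb[1, k] - net$pos[tip, k]) / d[k])
  }
  if (s < 1) {
    newpos <- net$pos[tip, ] + max(s, 0) * d
    frozen <- TRUE
  }
  loc <- locateHostElement(newpos, mesh)
  if (is.na(loc$elem[1])) {
    # outside a non-box domain: freeze in place at the last valid position
    newpos <- net$pos[tip, ]
    loc <- list(elem = net$elem[tip], lc = net$lc[tip, , drop = FALSE])
    frozen <- TRUE
  }
  if (sqrt(sum((newpos - net$pos[tip, ])^2)) < 1e-12) {
    net$frozen[tip] <- TRUE
    return(noop(net))
  }
  net <- appendNodes(net, pos = matrix(newpos, 1), tg = now, tip = TRUE,
                     dir = matrix(direction, 1), vessel = net$vessel[tip],
                     elem = loc$elem[1], lc = loc$lc[1, , drop = FALSE],
                     R = params$R_min, h = params$h_min, rp = params$r_p_max,
                     frozen = frozen)
  newid <- nNodes(net)
  net$tip[tip] <- FALSE
  net <- addSegment(net, tip, newid)
  attr(net, "extended") <- TRUE
  net
}

#' Stochastic branch formation at a vascular node
#'
#' With probability \code{P} (from \code{\link{branchingProbability}},
#' compared against the supplied uniform draw) a new tip is spawned from the
#' node; its first extension direction is the taxis direction, rotated in the
#' plane spanned with the parent direction to at least 30 degrees away from
#' it. The branch is initialised like an extended tip (nascent wall state).
#'
#' @param net an \code{angio_network}.
#' @param node node index.
#' @param rn uniform random draw in [0, 1].
#' @param P branching probability.
#' @param direction taxis direction for the new branch (unit vector).
#' @param mesh tissue mesh.
#' @param params vascular parameter list.
#' @param dt_v vascular time step (days).
#' @param now current time (days).
#' @return updated network; attribute \code{"branched"}.
#' @export
maybeBranch <- function(net, node, rn, P, direction, mesh, params, dt_v, now) {
  noop <- function(net) { attr(net, "branched") <- FALSE; net }
  if (rn >= P) return(noop(net))
  if (net$frozen[node] || net$state[node] == STATE_COLLAPSED) return(noop(net))
  parent <- net$dir[node, ]
  dirb <- branchDirection(direction, parent)
  # avoid spawning on top of an existing neighbour (duplicate branch cue)
  adj <- c(net$segs$b[net$segs$a == node], net$segs$a[net$segs$b == node])
  v0 <- tipSpeed(params$R_min, params)
  prop <- net$pos[node, ] + v0 * dt_v * dirb
  if (length(adj)) {
    dmin <- min(sqrt(rowSums(sweep(net$pos[adj, , drop = FALSE], 2, prop)^2)))
    if (dmin < 1e-6) return(noop(net))
  }
  net2 <- net
  net2$tip[node] <- TRUE        # reuse the tip-extension machinery
  oldR <- net2$R[node]
  net2$R[node] <- params$R_min  # a nascent branch extends at the nascent speed
  net2 <- extendTip(net2, node, dirb, tau_local = params$tau_star, mesh = mesh,
                    params = params, dt_v = dt_v, now = now)
  ext <- attr(net2, "extended")
  net2$tip[node] <- FALSE
  net2$R[node] <- oldR
  attr(net2, "branched") <- isTRUE(ext)
  if (!isTRUE(ext)) return(noop(net))
  net2
}

# rotate `d` away from the parent direction to at least 30 degrees, in the
# plane spanned by both
branchDirection <- function(d, parent, min_angle = pi / 6) {
  p <- unitVector(parent)
  if (is.null(p)) return(d)
  cosang <- sum(d * p)
  if (acos(clamp(cosang, -1, 1)) >= min_angle) return(d)
  w <- d - cosang * p
  uw <- unitVector(w)
  if (is.null(uw)) {
    # parallel: pick a deterministic perpendicular
    ax <- diag(3)[, which.min(abs(p))]
    uw <- unitVector(ax - sum(ax * p) * p)
  }
  cos(min_angle) * p + sin(min_angle) * uw
}

#' Attempt anastomosis of a tip with a nearby vessel
#'
#' If a non-adjacent functional vascular node lies within the capture
#' distance (40 um), a new segment connects the two and both endpoints lose
#' tip status.
#'
#' @param net an \code{angio_network}.
#' @param tip tip node index.
#' @param capture capture distance (mm), default 0.04.
#' @return updated network; attribute \code{"anastomosed"}.
#' @export
tryAnastomose <- function(net, tip, capture = 0.04) {
  noop <- function(net) { attr(net, "anastomosed") <- FALSE; net }
  if (!net$tip[tip] || net$state[tip] == STATE_COLLAPSED) return(noop(net))
  adj <- c(net$segs$b[net$segs$a == tip], net$segs$a[net$segs$b == tip])
  d2 <- (net$pos[, 1] - net$pos[tip, 1])^2 + (net$pos[, 2] - net$pos[tip, 2])^2 +
        (net$pos[, 3] - net$pos[tip, 3])^2
  cand <- which(d2 <= capture^2 & d2 > 1e-18)
  cand <- cand[!(cand %in% c(tip, adj)) & net$state[cand] != STATE_COLLAPSED]
  if (!length(cand)) return(noop(net))
  other <- cand[which.min(d2[cand])]
  net <- addSegment(net, tip, other)
  net$tip[tip] <- FALSE
  net$tip[other] <- FALSE
  attr(net, "anastomosed") <- TRUE
  net
}

#' Apply wall compression and pressure-induced collapse
#'
#' Per functional node the wall pressure ratio is evaluated; in the
#' compressed regime the effective radius is reduced by the radial wall
#' strain (reversibly, by default), at or beyond the node's critical pressure
#' the vessel collapses permanently (radius divided by \code{lambda_r},
#' excluded from flow and sprouting). Nodes left without any functional path
#' to an inlet or outlet (dead ends distal to a collapse, unless an
#' anastomosis provides a second route) collapse too.
#'
#' @param net an \code{angio_network}.
#' @param p_int interstitial pressure at the nodes (mm-Hg).
#' @param p_h tissue solid pressure at the nodes (mm-Hg).
#' @param p_vsc blood pressure at the nodes (mm-Hg).
#' @param params collapse parameter list (\code{e_c}, \code{E_w_min},
#'   \code{E_w_max}, \code{lambda_r}).
#' @return updated network; attribute \code{"n_collapsed"} counts new
#'   collapses.
#' @export
applyCompressionAndCollapse <- function(net, p_int, p_h, p_vsc, params) {
  n <- nNodes(net)
  pbar <- pressureRatio(p_int, p_h, p_vsc)
  already <- net$state == STATE_COLLAPSED
  pbar[already] <- net$pbar[already]
  net$pbar <- pbar
  # per-node stiffness interpolates with remodelling level; parents (tbar=1)
  # carry the maximum stiffness
  Ew <- params$E_w_min + clamp(net$tbar, 0, 1) * (params$E_w_max - params$E_w_min)
  p_c <- pcFromStiffness(Ew, params$e_c)
  collapse_now <- !already & pbar >= p_c
  er <- wallStrain(pbar, p_c, params$e_c)
  compressed <- !already & !collapse_now & pbar > 1
  net$R <- ifelse(already, net$R,
           ifelse(collapse_now, net$R0 / params$lambda_r,
           ifelse(compressed, net$R0 / (1 + er), net$R0)))
  net$state[compressed] <- STATE_COMPRESSED
  net$state[!already & !collapse_now & !compressed] <- STATE_NORMAL
  net$state[collapse_now] <- STATE_COLLAPSED
  # prune functional nodes with no route to an inlet/outlet
  fun <- net$state != STATE_COLLAPSED
  keep <- fun[net$segs$a] & fun[net$segs$b]
  term <- which((net$inlet | net$outlet) & fun)
  if (length(term)) {
    dist <- .cppGraphDist(n, net$segs$a[keep] - 1L, net$segs$b[keep] - 1L,
                          rep(1, sum(keep)), term - 1L)
    orphan <- fun & !is.finite(dist)
  } else orphan <- fun
  if (any(orphan)) {
    net$state[orphan] <- STATE_COLLAPSED
    net$R[orphan] <- net$R0[orphan] / params$lambda_r
  }
  attr(net, "n_collapsed") <- sum(collapse_now) + sum(orphan)
  net
}

# network-geodesic distance (mm) to the nearest branching (degree >= 3) node;
# NA where unreachable / none exists
branchDistances <- function(net) {
  deg <- nodeDegree(net)
  br <- which(deg >= 3)
  n <- nNodes(net)
  if (!length(br)) return(rep(NA_real_, n))
  d <- .cppGraphDist(n, net$segs$a - 1L, net$segs$b - 1L, net$segs$L0, br - 1L)
  d[!is.finite(d)] <- NA_real_
  d
}
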