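# Quasi-steady coupled vascular / interstitial / transvascular flow.
#
# One symmetric sparse linear system over all tissue-node and vascular-node
# pressures: Poiseuille conductances on vessel segments, Darcy conductances
# on the element-edge graph of the hexahedral mesh, and Starling exchange
# coupling each functional vascular node to the vertices of its host element
# through trilinear weights. Pressures in mm-Hg, lengths mm, time seconds.

#' Poiseuille conductance of a vessel segment
#'
#' \code{G = pi R^4 / (8 mu_B L)}; flow is \code{Q = -G dp}.
#'
#' @param R lumen radius (mm).
#' @param L segment length (mm).
#' @param mu_B blood viscosity (mm-Hg s).
#' @return conductance (mm^3 / (mm-Hg s)).
#' @export
segmentConductance <- function(R, L, mu_B) pi * R^4 / (8 * mu_B * L)

#' Hydraulic conductivity of the capillary wall
#'
#' \code{K_vsc = gamma_p r_p^2 / (8 mu_B h)}.
#'
#' @param r_p pore radius (mm).
#' @param gamma_p wall-surface pore fraction.
#' @param mu_B blood viscosity (mm-Hg s).
#' @param h wall thickness (mm).
#' @return conductivity (mm / (mm-Hg s)).
#' @export
wallConductivity <- function(r_p, gamma_p, mu_B, h) gamma_p * r_p^2 / (8 * mu_B * h)

#' Effective filtration pressure (Starling)
#'
#' \code{p_eff = p_vsc - sigma_o (pi_vsc - pi_int)}.
#'
#' @param p_vsc blood pressure (mm-Hg).
#' @param pi_vsc,pi_int plasma and interstitial osmotic pressures (mm-Hg).
#' @param sigma_o osmotic reflection coefficient.
#' @export
effectivePressure <- function(p_vsc, pi_vsc, pi_int, sigma_o) {
  p_vsc - (pi_vsc - pi_int) * sigma_o
}

#' Wall shear stress of a vessel segment
#'
#' \code{tau_f = R |dp| / L} (kept in this form; the remodelling threshold
#' coefficient is calibrated to it).
#'
#' @param R lumen radius (mm).
#' @param dp pressure drop along the segment (mm-Hg).
#' @param L segment length (mm).
#' @return shear stress (mm-Hg).
#' @export
wallShearStress <- function(R, dp, L) R * abs(dp) / L

#' Solve the coupled pressure system
#'
#' Dirichlet anchors: inlet vascular nodes at \code{p_inlet}, outlets at
#' \code{p_outlet}, collapsed vascular nodes at 0, and tissue nodes on the
#' tagged boundary faces at \code{p_boundary}. Vessel-free elements fall back
#' to the configured vascular surface density and mean radius for the Darcy
#' cross-section.
#'
#' @param net an \code{angio_network}.
#' @param mesh an \code{angio_mesh}.
#' @param params fluid parameter list (see \code{\link{defaultConfig}},
#'   block \code{fluid}).
#' @param pos_cur current (deformed) vascular node positions; reference by
#'   default.
#' @param u nodal tissue displacements (N x 3) for deformed edge lengths,
#'   zeros by default.
#' @return list: \code{p_int} (tissue nodes), \code{p_vsc} (vascular nodes,
#'   0 at collapsed), per-segment \code{seg_Q} (mm^3/s), \code{seg_v} (mm/s),
#'   \code{seg_tauf} (mm-Hg), per-node \code{node_v}, \code{node_tauf},
#'   \code{Q_trv}, tissue-edge table \code{edges} with \code{v_int} (mm/s),
#'   and the global balance summary \code{balance}.
#' @export
solveCoupledPressures <- function(net, mesh, params, pos_cur = net$pos, u = NULL) {
  Nt <- nrow(mesh$nodes)
  nv <- nNodes(net)
  ntot <- Nt + nv
  fun_node <- net$state != STATE_COLLAPSED
  fun_seg <- functionalSegs(net)
  if (!any(net$inlet & fun_node) || !any(net$outlet & fun_node)) {
    if (any(fun_seg))
      stopf("network needs at least one functional inlet and outlet")
    # fully collapsed/absent vasculature: pure-Dirichlet interstitium
    fun_node[] <- FALSE
  }
  Lcur <- segmentLengths(net, pos_cur)
  segR <- (net$R[net$segs$a] + net$R[net$segs$b]) / 2

  # --- element-wise vascular surface density for the Darcy cross-section
  E <- nrow(mesh$elems)
  mid <- (pos_cur[net$segs$a, , drop = FALSE] + pos_cur[net$segs$b, , drop = FALSE]) / 2
  mide <- net$elem[net$segs$a]  # host element of segment: via endpoint a
  sa <- 2 * pi * segR * Lcur
  Svsc <- rep(params$S_vsc_default, E)
  Rbar <- rep(params$R_bar_default, E)
  wseg <- which(fun_seg & !is.na(mide))
  if (length(wseg)) {
    acc <- rowsum(sa[wseg], mide[wseg])
    el <- as.integer(rownames(acc))
    Svsc[el] <- pmax(acc[, 1] / mesh$volumes[el], 1e-9)
    accR <- rowsum(segR[wseg], mide[wseg])
    cnt <- rowsum(rep(1, length(wseg)), mide[wseg])
    Rbar[el] <- accR[, 1] / cnt[, 1]
  }
  A_int <- 2 * pi * Rbar / Svsc

  # --- tissue edge graph (unique element edges, averaged coefficients)
  ee <- do.call(rbind, lapply(seq_len(nrow(HEX_EDGES)), function(k)
    cbind(mesh$elems[, HEX_EDGES[k, 1]], mesh$elems[, HEX_EDGES[k, 2]],
          seq_len(E))))
  a0 <- pmin(ee[, 1], ee[, 2]); b0 <- pmax(ee[, 1], ee[, 2])
  K_int_e <- ifelse(mesh$label == 2L, params$K_int_tumour, params$K_int_host)
  gcontrib <- K_int_e[ee[, 3]] * A_int[ee[, 3]]
  key <- a0 + (b0 - 1) * Nt
  o <- order(key)
  key_s <- key[o]
  grp <- cumsum(c(TRUE, diff(key_s) != 0))
  ea <- a0[o][!duplicated(grp)]
  eb <- b0[o][!duplicated(grp)]
  gsum <- rowsum(gcontrib[o], grp)[, 1]
  gcnt <- rowsum(rep(1, length(grp)), grp)[, 1]
  gmean <- gsum / gcnt
  posT <- mesh$nodes + if (is.null(u)) 0 else u
  eL <- sqrt(rowSums((posT[ea, , drop = FALSE] - posT[eb, , drop = FALSE])^2))
  g_edge <- gmean / eL

  ti <- c(ea, eb, ea, eb)
  tj <- c(ea, eb, eb, ea)
  tx <- c(g_edge, g_edge, -g_edge, -g_edge)

  # --- vascular segments (functional only)
  wa <- net$segs$a[fun_seg] + Nt
  wb <- net$segs$b[fun_seg] + Nt
  G <- segmentConductance(segR[fun_seg], Lcur[fun_seg], params$mu_B)
  ti <- c(ti, wa, wb, wa, wb)
  tj <- c(tj, wa, wb, wb, wa)
  tx <- c(tx, G, G, -G, -G)

  # --- transvascular exchange (functional nodes with a host element)
  rhs <- numeric(ntot)
  exch <- which(fun_node & !is.na(net$elem))
  A_vsc <- numeric(nv)
  wk_seg <- which(fun_seg)
  if (length(wk_seg)) {
    half <- pi * segR[wk_seg] * Lcur[wk_seg]  # 2*pi*R*L/2
    for (endp in list(net$segs$a[wk_seg], net$segs$b[wk_seg])) {
      acc <- rowsum(half, endp)
      id <- as.integer(rownames(acc))
      A_vsc[id] <- A_vsc[id] + acc[, 1]
    }
  }
  Kv <- wallConductivity(net$rp, params$gamma_p, params$mu_B, net$h)
  Cex <- Kv * A_vsc
  osm <- params$sigma_o * (params$pi_vsc - params$pi_int)
  TI <- list(ti); TJ <- list(tj); TX <- list(tx)
  if (length(exch)) {
    a <- HEX_LC
    lcw <- net$lc[exch, , drop = FALSE]
    Nw <- sapply(1:8, function(kk)
      (1 + a[kk, 1] * lcw[, 1]) * (1 + a[kk, 2] * lcw[, 2]) * (1 + a[kk, 3] * lcw[, 3]) / 8)
    if (is.null(dim(Nw))) Nw <- matrix(Nw, 1)
    verts <- mesh$elems[net$elem[exch], , drop = FALSE]
    C <- Cex[exch]
    vid <- exch + Nt
    TI[[length(TI) + 1]] <- vid; TJ[[length(TJ) + 1]] <- vid
    TX[[length(TX) + 1]] <- C
    rhs[vid] <- rhs[vid] + C * osm
    for (kk in 1:8) {
      vk <- verts[, kk]
      wk <- Nw[, kk]
      TI[[length(TI) + 1]] <- c(vid, vk)
      TJ[[length(TJ) + 1]] <- c(vk, vid)
      TX[[length(TX) + 1]] <- c(-C * wk, -C * wk)
      racc <- rowsum(wk * C * osm, vk)
      rid <- as.integer(rownames(racc))
      rhs[rid] <- rhs[rid] - racc[, 1]
      for (mm in 1:8) {
        TI[[length(TI) + 1]] <- vk
        TJ[[length(TJ) + 1]] <- verts[, mm]
        TX[[length(TX) + 1]] <- C * wk * Nw[, mm]
      }
    }
  }
  ti <- unlist(TI, use.names = FALSE)
  tj <- unlist(TJ, use.names = FALSE)
  tx <- unlist(TX, use.names = FALSE)

  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(ntot, ntot))

  # --- Dirichlet rows
  dir_idx <- c(mesh$inlet_nodes, mesh$outlet_nodes,
               Nt + which(net$inlet & fun_node), Nt + which(net$outlet & fun_node),
               Nt + which(!fun_node))
  dir_val <- c(rep(params$p_boundary, length(mesh$inlet_nodes) + length(mesh$outlet_nodes)),
               rep(params$p_inlet, sum(net$inlet & fun_node)),
               rep(params$p_outlet, sum(net$outlet & fun_node)),
               rep(0, sum(!fun_node)))
  keep <- !duplicated(dir_idx)
  dir_idx <- dir_idx[keep]; dir_val <- dir_val[keep]
  free <- setdiff(seq_len(ntot), dir_idx)
  rhs_f <- rhs[free] - as.numeric(A[free, dir_idx, drop = FALSE] %*% dir_val)
  Aff <- A[free, free, drop = FALSE]
  p <- numeric(ntot)
  p[dir_idx] <- dir_val
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::forceSymmetric((Aff + Matrix::t(Aff)) / 2), rhs_f)),
    error = function(e) as.numeric(Matrix::solve(Aff, rhs_f)))
  if (any(!is.finite(sol))) stopf("flow solve failed (singular system)")
  p[free] <- sol
  p_int <- p[seq_len(Nt)]
  p_vsc <- p[Nt + seq_len(nv)]
  p_vsc[!fun_node] <- 0

  # --- derived quantities
  dp <- p_vsc[net$segs$a] - p_vsc[net$segs$b]
  Gall <- segmentConductance(segR, Lcur, params$mu_B)
  seg_Q <- ifelse(fun_seg, -Gall * (p_vsc[net$segs$b] - p_vsc[net$segs$a]), 0)
  seg_v <- ifelse(fun_seg, seg_Q / (pi * segR^2), 0)
  seg_tauf <- ifelse(fun_seg, wallShearStress(segR, dp, Lcur), 0)
  node_v <- numeric(nv); node_tauf <- numeric(nv); inc <- numeric(nv)
  ends <- c(net$segs$a[wk_seg], net$segs$b[wk_seg])
  if (length(ends)) {
    vacc <- rowsum(rep(abs(seg_v[wk_seg]), 2), ends)
    tacc <- rowsum(rep(seg_tauf[wk_seg], 2), ends)
    cacc <- rowsum(rep(1, length(ends)), ends)
    id <- as.integer(rownames(vacc))
    node_v[id] <- vacc[, 1] / cacc[, 1]
    node_tauf[id] <- tacc[, 1] / cacc[, 1]
  }
  peff <- effectivePressure(p_vsc, params$pi_vsc, params$pi_int, params$sigma_o)
  pint_at <- fieldAtLocal(p_int, mesh, net$elem, net$lc)
  Q_trv <- ifelse(fun_node & !is.na(net$elem), Cex * (peff - pint_at), 0)
  # interstitial velocity per unique tissue edge: v = -K dp / L with the
  # edge-averaged conductivity
  Kmean <- rowsum((K_int_e[ee[, 3]])[o], grp)[, 1] / gcnt
  v_edge <- -Kmean * (p_int[eb] - p_int[ea]) / eL
  inflow <- sum(seg_Q[fun_seg & net$inlet[net$segs$a]]) -
            sum(seg_Q[fun_seg & net$inlet[net$segs$b]])
  outflow <- sum(seg_Q[fun_seg & net$outlet[net$segs$b]]) -
             sum(seg_Q[fun_seg & net$outlet[net$segs$a]])
  # interior filtration only: pressure-anchored (inlet/outlet) nodes exchange
  # directly with the boundary condition, not with the balance identity
  interior <- !(net$inlet | net$outlet)
  list(p_int = p_int, p_vsc = p_vsc, seg_Q = seg_Q, seg_v = seg_v,
       seg_tauf = seg_tauf, node_v = node_v, node_tauf = node_tauf,
       Q_trv = Q_trv,
       edges = data.frame(a = ea, b = eb, v_int = v_edge),
       balance = c(inflow = inflow, outflow = outflow,
                   filtration = sum(Q_trv[interior])))
}

#' Velocities from a flow solution
#'
#' \code{v_vsc = Q / (pi R^2)} per vessel segment and
#' \code{v_int = -K_int dp / L} per tissue edge (both already computed during
#' the solve; this accessor returns them together).
#'
#' @param flow result of \code{\link{solveCoupledPressures}}.
#' @return list with \code{v_vsc} (mm/s) and \code{v_int} (mm/s per tissue
#'   edge).
#' @export
flowVelocities <- function(flow) {
  list(v_vsc = flow$seg_v, v_int = flow$edges$v_int)
}
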