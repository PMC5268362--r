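# Discrete 1D vascular network embedded (non-conformingly) in the tissue mesh.
#
# Node state codes: 0 = normal, 1 = compressed, 2 = collapsed. Radii, wall
# thickness and pore radius are stored in mm. R is the current effective
# lumen radius (after any compression); R0 the remodelling-law radius.

STATE_NORMAL <- 0L
STATE_COMPRESSED <- 1L
STATE_COLLAPSED <- 2L

newNetwork <- function(pos, tg, tip, inlet, outlet, frozen, R, h, rp,
                       state, elem, lc, dir, vessel) {
  n <- nrow(pos)
  structure(list(
    pos = pos, tg = tg, tip = tip, inlet = inlet, outlet = outlet,
    frozen = frozen, R = R, R0 = R, h = h, rp = rp,
    state = as.integer(state), elem = as.integer(elem), lc = lc,
    dir = dir, vessel = as.integer(vessel),
    tbar = ifelse(tg == 0, 1, 0),       # remodelling level; parents fully mature
    pbar = rep(0, n),                    # last wall pressure ratio
    wss = rep(0, n), vel = rep(0, n),    # last flow-derived node quantities
    segs = data.frame(a = integer(0), b = integer(0), L0 = numeric(0))
  ), class = "angio_network")
}

nNodes <- function(net) nrow(net$pos)

#' @method print angio_network
#' @export
print.angio_network <- function(x, ...) {
  deg <- nodeDegree(x)
  cat(sprintf(paste0("angio_network: %d nodes, %d segments, %d vessels\n",
                     "  tips %d, inlets %d, outlets %d, collapsed %d, frozen %d\n"),
              nNodes(x), nrow(x$segs), length(unique(x$vessel)), sum(x$tip),
              sum(x$inlet), sum(x$outlet), sum(x$state == STATE_COLLAPSED),
              sum(x$frozen)))
  invisible(x)
}

nodeDegree <- function(net) {
  tabulate(c(net$segs$a, net$segs$b), nbins = nNodes(net))
}

# current segment lengths given node positions (reference or deformed)
segmentLengths <- function(net, pos = net$pos) {
  a <- net$segs$a; b <- net$segs$b
  sqrt((pos[a, 1] - pos[b, 1])^2 + (pos[a, 2] - pos[b, 2])^2 +
       (pos[a, 3] - pos[b, 3])^2)
}

# functional = neither endpoint collapsed
functionalSegs <- function(net) {
  net$state[net$segs$a] != STATE_COLLAPSED & net$state[net$segs$b] != STATE_COLLAPSED
}

appendNodes <- function(net, pos, tg, tip, dir, vessel, elem, lc,
                        R, h, rp, frozen = FALSE) {
  k <- nrow(pos)
  net$pos <- rbind(net$pos, pos)
  net$tg <- c(net$tg, rep(tg, k))
  net$tip <- c(net$tip, rep(tip, k))
  net$inlet <- c(net$inlet, rep(FALSE, k))
  net$outlet <- c(net$outlet, rep(FALSE, k))
  net$frozen <- c(net$frozen, rep(frozen, k))
  net$R <- c(net$R, rep(R, k))
  net$R0 <- c(net$R0, rep(R, k))
  net$h <- c(net$h, rep(h, k))
  net$rp <- c(net$rp, rep(rp, k))
  net$state <- c(net$state, rep(STATE_NORMAL, k))
  net$elem <- c(net$elem, elem)
  net$lc <- rbind(net$lc, lc)
  net$dir <- rbind(net$dir, dir)
  net$vessel <- c(net$vessel, rep(vessel, k))
  net$tbar <- c(net$tbar, rep(0, k))
  net$pbar <- c(net$pbar, rep(0, k))
  net$wss <- c(net$wss, rep(0, k))
  net$vel <- c(net$vel, rep(0, k))
  net
}

addSegment <- function(net, a, b) {
  L <- sqrt(sum((net$pos[a, ] - net$pos[b, ])^2))
  if (L <= 0) stopf("zero-length vascular segment %d-%d", a, b)
  net$segs <- rbind(net$segs, data.frame(a = a, b = b, L0 = L))
  net
}

#' Build the initial capillary network
#'
#' Straight, parallel, unbranched vessels spanning the domain between the two
#' tagged faces on a square lattice at the given spacing; the tumour region is
#' kept avascular by rerouting lines whose axis passes within the tumour
#' radius of the domain centre radially to just outside it. Each line is
#' discretised adaptively so no segment is longer than the local element edge
#' (so segments pass through, not across, tissue elements). All nodes carry
#' birth time t_g = 0 and are exempt from wall remodelling.
#'
#' @param mesh an \code{angio_mesh} with tagged inlet/outlet faces (generated
#'   cube meshes tag x = 0 and x = edge).
#' @param spacing lattice spacing between vessels (mm).
#' @param radius initial lumen radius (mm).
#' @param thickness initial wall thickness (mm).
#' @param pore_radius initial wall pore radius (mm).
#' @return an \code{angio_network}.
#' @export
buildInitialNetwork <- function(mesh, spacing = 0.6, radius = 0.03,
                                thickness = 5e-3, pore_radius = 5e-5) {
  bb <- mesh$bbox
  L <- bb[2, 1] - bb[1, 1]
  Ly <- bb[2, 2] - bb[1, 2]
  if (spacing <= 0) stopf("spacing must be positive")
  if (spacing > min(L, Ly)) stopf("spacing %g larger than domain", spacing)
  centre <- attr(mesh, "centre") %||% colMeans(rbind(bb[1, ], bb[2, ]))
  rT <- (attr(mesh, "tumour_diameter") %||% 0) / 2
  # exclusion radius in the (y,z) plane: no line may cross a tumour-labelled
  # element, so the avascular region is the tumour elements' footprint (which
  # converges to the tumour sphere as the mesh resolves it)
  tum <- which(mesh$label == 2L)
  r_excl <- rT
  if (length(tum)) {
    dy2 <- pmax(abs(mesh$el_lo[tum, 2] - centre[2]), abs(mesh$el_hi[tum, 2] - centre[2]))
    dz2 <- pmax(abs(mesh$el_lo[tum, 3] - centre[3]), abs(mesh$el_hi[tum, 3] - centre[3]))
    r_excl <- max(rT, max(sqrt(dy2^2 + dz2^2)))
  }
  latt <- seq(bb[1, 2] + spacing / 2, bb[2, 2] - spacing / 2 + 1e-9, by = spacing)
  lines <- expand.grid(y = latt, z = latt)
  # reroute lines whose axis passes through the avascular footprint
  dy <- lines$y - centre[2]; dz <- lines$z - centre[3]
  d <- sqrt(dy^2 + dz^2)
  close_ <- which(r_excl > 0 & d < r_excl)
  for (i in close_) {
    if (d[i] < 1e-12) { dy[i] <- 1; dz[i] <- 0; d[i] <- 1 }
    f <- (r_excl * 1.02) / d[i]
    lines$y[i] <- centre[2] + dy[i] * f
    lines$z[i] <- centre[3] + dz[i] * f
  }
  # adaptive subdivision of [x0, x1] against the local element min edge
  subdivide <- function(y, z) {
    xs <- c(bb[1, 1], bb[2, 1])
    repeat {
      mids <- (xs[-1] + xs[-length(xs)]) / 2
      loc <- locateHostElement(cbind(mids, y, z), mesh)
      hmax <- ifelse(is.na(loc$elem), Inf, mesh$elem_min_edge[loc$elem])
      too_long <- diff(xs) > hmax + 1e-12
      if (!any(too_long)) return(xs)
      xs <- sort(c(xs, mids[too_long]))
    }
  }
  pos <- NULL; seg_a <- integer(0); seg_b <- integer(0); vessel <- integer(0)
  inlet <- logical(0); outlet <- logical(0)
  for (v in seq_len(nrow(lines))) {
    xs <- subdivide(lines$y[v], lines$z[v])
    k0 <- if (is.null(pos)) 0L else nrow(pos)
    m <- length(xs)
    pos <- rbind(pos, cbind(xs, lines$y[v], lines$z[v]))
    vessel <- c(vessel, rep(v, m))
    inlet <- c(inlet, c(TRUE, rep(FALSE, m - 1)))
    outlet <- c(outlet, c(rep(FALSE, m - 1), TRUE))
    seg_a <- c(seg_a, k0 + seq_len(m - 1))
    seg_b <- c(seg_b, k0 + seq_len(m - 1) + 1L)
  }
  dimnames(pos) <- NULL
  n <- nrow(pos)
  loc <- locateHostElement(pos, mesh)
  net <- newNetwork(pos = pos, tg = rep(0, n), tip = rep(FALSE, n),
                    inlet = inlet, outlet = outlet,
                    frozen = inlet | outlet,
                    R = rep(radius, n), h = rep(thickness, n),
                    rp = rep(pore_radius, n), state = rep(STATE_NORMAL, n),
                    elem = loc$elem, lc = loc$lc,
                    dir = matrix(rep(c(1, 0, 0), each = n), n, 3),
                    vessel = vessel)
  net$segs <- data.frame(a = seg_a, b = seg_b, L0 = 0)
  net$segs$L0 <- segmentLengths(net)
  if (rT > 0) {
    din <- sqrt(rowSums(sweep(net$pos, 2, centre)^2))
    if (any(din < rT)) stopf("initial network node inside the tumour sphere")
  }
  net
}

#' Per-element tip and functional vascular-node densities
#'
#' \code{rho_t} counts the tip nodes contained in each tissue element;
#' \code{rho_v} is 1 where an element contains at least one well-perfused,
#' functional vascular node and 0 otherwise (hypo-perfused, collapsed or
#' vessel-free elements).
#'
#' @param net an \code{angio_network}.
#' @param mesh an \code{angio_mesh}.
#' @param well_perfused logical per node; defaults to the stored node mean
#'   blood velocity exceeding \code{v_thresh} on functional nodes.
#' @param v_thresh perfusion velocity threshold (mm/s), default 0.1.
#' @return list with \code{rho_v}, \code{rho_t}, \code{N_t}, \code{N_v}
#'   (per element).
#' @export
updateDensities <- function(net, mesh, well_perfused = NULL, v_thresh = 0.1) {
  E <- nrow(mesh$elems)
  if (is.null(well_perfused))
    well_perfused <- net$vel >= v_thresh & net$state != STATE_COLLAPSED
  ok <- !is.na(net$elem)
  tipn <- ok & net$tip & net$state != STATE_COLLAPSED
  N_t <- tabulate(net$elem[tipn], nbins = E)
  wp <- ok & well_perfused & net$state != STATE_COLLAPSED
  N_v <- tabulate(net$elem[wp], nbins = E)
  list(rho_v = as.numeric(N_v > 0), rho_t = as.numeric(N_t),
       N_t = N_t, N_v = N_v)
}

stateLabels <- c("normal", "compressed", "collapsed")

#' Write the network segment table as CSV
#'
#' Schema: \code{node_a,node_b,xa,ya,za,xb,yb,zb,radius_um,state}; segment
#' radius is the mean of its endpoint lumen radii, state the worse of the two
#' endpoint states. Full precision so repeated writes are bit-stable.
#'
#' @param net an \code{angio_network}.
#' @param path output file.
#' @param pos optional deformed node positions.
#' @export
writeNetworkCSV <- function(net, path, pos = net$pos) {
  a <- net$segs$a; b <- net$segs$b
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  # networks reconstructed from CSV carry exact per-segment radius/state
  st <- if (!is.null(net$segs$state)) net$segs$state else
    stateLabels[pmax(net$state[a], net$state[b]) + 1L]
  rad <- if (!is.null(net$segs$radius_um)) net$segs$radius_um else
    (net$R[a] + net$R[b]) / 2 * 1000
  df <- data.frame(node_a = a, node_b = b,
                   xa = fmt(pos[a, 1]), ya = fmt(pos[a, 2]), za = fmt(pos[a, 3]),
                   xb = fmt(pos[b, 1]), yb = fmt(pos[b, 2]), zb = fmt(pos[b, 3]),
                   radius_um = fmt(rad), state = st)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a network segment table written by \code{writeNetworkCSV}
#'
#' Reconstructs node positions, connectivity, per-node radius (mean of the
#' incident segment radii) and state. Node attributes not present in the
#' table (birth times, wall thickness, pore size) are not recovered.
#'
#' @param path CSV file.
#' @return an \code{angio_network} with geometric/state information only.
#' @export
readNetworkCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_a", "node_b", "xa", "ya", "za", "xb", "yb", "zb",
            "radius_um", "state")
  if (!all(need %in% names(df))) stopf("malformed network CSV: %s", path)
  n <- max(df$node_a, df$node_b)
  pos <- matrix(NA_real_, n, 3)
  pos[df$node_a, ] <- cbind(df$xa, df$ya, df$za)
  pos[df$node_b, ] <- cbind(df$xb, df$yb, df$zb)
  stnum <- match(df$state, stateLabels) - 1L
  state <- rep(STATE_NORMAL, n)
  # endpoint state is the max over incident segments (consistent with writer)
  for (k in seq_len(nrow(df))) {
    state[df$node_a[k]] <- max(state[df$node_a[k]], stnum[k])
    state[df$node_b[k]] <- max(state[df$node_b[k]], stnum[k])
  }
  Rsum <- rep(0, n); cnt <- rep(0, n)
  for (k in seq_len(nrow(df))) {
    Rsum[df$node_a[k]] <- Rsum[df$node_a[k]] + df$radius_um[k]
    Rsum[df$node_b[k]] <- Rsum[df$node_b[k]] + df$radius_um[k]
    cnt[df$node_a[k]] <- cnt[df$node_a[k]] + 1
    cnt[df$node_b[k]] <- cnt[df$node_b[k]] + 1
  }
  R <- ifelse(cnt > 0, Rsum / cnt, 0) / 1000
  net <- newNetwork(pos = pos, tg = rep(0, n), tip = rep(FALSE, n),
                    inlet = rep(FALSE, n), outlet = rep(FALSE, n),
                    frozen = rep(FALSE, n), R = R, h = rep(0, n),
                    rp = rep(0, n), state = state, elem = rep(NA_integer_, n),
                    lc = matrix(NA_real_, n, 3),
                    dir = matrix(0, n, 3), vessel = rep(1L, n))
  net$segs <- data.frame(a = df$node_a, b = df$node_b, L0 = 0)
  net$segs$L0 <- segmentLengths(net)
  net$segs$radius_um <- df$radius_um
  net$segs$state <- df$state
  net
}
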