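# Morphometric and functional summaries of the simulated vasculature:
# vascular density, inter-capillary distance, distance-map scaling
# parameters, perfusion classes, histograms, radial profiles.

#' Vascular surface density
#'
#' Ratio of functional vessel wall surface area (sum of 2 pi R L over
#' non-collapsed segments) to tissue volume, optionally normalised against a
#' reference (day-0) value.
#'
#' @param net an \code{angio_network}.
#' @param volume tissue volume (mm^3).
#' @param pos_cur current node positions (reference by default).
#' @param day0 un-normalised day-0 density for normalisation, or NULL.
#' @return density (1/mm), or the dimensionless normalised value when
#'   \code{day0} is given.
#' @export
vascularDensity <- function(net, volume, pos_cur = net$pos, day0 = NULL) {
  fun <- functionalSegs(net)
  L <- segmentLengths(net, pos_cur)
  segR <- (net$R[net$segs$a] + net$R[net$segs$b]) / 2
  dens <- sum(2 * pi * segR[fun] * L[fun]) / volume
  if (is.null(day0)) dens else dens / day0
}

# sample points along functional segments at a given spacing; returns
# positions and the vessel id of each sample
sampleVessels <- function(net, spacing, pos_cur = net$pos, functional_only = TRUE) {
  keep <- if (functional_only) functionalSegs(net) else rep(TRUE, nrow(net$segs))
  P <- list(); V <- list()
  for (k in which(keep)) {
    a <- net$segs$a[k]; b <- net$segs$b[k]
    L <- sqrt(sum((pos_cur[a, ] - pos_cur[b, ])^2))
    m <- max(2L, ceiling(L / spacing) + 1L)
    t_ <- seq(0, 1, length.out = m)
    P[[length(P) + 1]] <- cbind(pos_cur[a, 1] + t_ * (pos_cur[b, 1] - pos_cur[a, 1]),
                                pos_cur[a, 2] + t_ * (pos_cur[b, 2] - pos_cur[a, 2]),
                                pos_cur[a, 3] + t_ * (pos_cur[b, 3] - pos_cur[a, 3]))
    V[[length(V) + 1]] <- rep(net$vessel[a], m)
  }
  if (!length(P)) return(list(pos = matrix(0, 0, 3), vessel = integer(0)))
  list(pos = do.call(rbind, P), vessel = unlist(V))
}

#' Mean inter-capillary distance
#'
#' Mean, over sample points on each functional vessel centreline, of the
#' distance to the nearest point on any other vessel.
#'
#' @param net an \code{angio_network}.
#' @param spacing sampling density along vessels (mm).
#' @param pos_cur current node positions.
#' @return distance (mm); NA for fewer than two vessels.
#' @export
intercapillaryDistance <- function(net, spacing = 0.05, pos_cur = net$pos) {
  s <- sampleVessels(net, spacing, pos_cur)
  if (length(unique(s$vessel)) < 2) return(NA_real_)
  d <- .cppForeignNN(s$pos, as.integer(s$vessel), cell = 0.7)
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

#' Distance map of the vascular network
#'
#' Voxelises the functional vessels on a regular grid over the analysis
#' region (by default the tumour plus a 1 mm shell) and returns the exact
#' Euclidean distance to the nearest vessel per voxel.
#'
#' @param net an \code{angio_network}.
#' @param centre region centre (mm).
#' @param radius region radius (mm).
#' @param voxel voxel size (mm), default 0.03.
#' @param pos_cur current node positions.
#' @return list with \code{delta} (distances at the valid, in-sphere voxels),
#'   \code{dims}, \code{voxel}, \code{valid} (any vessel present).
#' @export
distanceMap <- function(net, centre, radius, voxel = 0.03, pos_cur = net$pos) {
  lo <- centre - radius
  n <- rep(max(2L, ceiling(2 * radius / voxel)), 3)
  s <- sampleVessels(net, voxel / 2, pos_cur)
  occ <- array(FALSE, dim = n)
  valid <- nrow(s$pos) > 0
  if (valid) {
    ijk <- floor(sweep(s$pos, 2, lo) / voxel) + 1
    keep <- ijk[, 1] >= 1 & ijk[, 1] <= n[1] & ijk[, 2] >= 1 & ijk[, 2] <= n[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= n[3]
    ijk <- ijk[keep, , drop = FALSE]
    occ[cbind(ijk[, 1], ijk[, 2], ijk[, 3])] <- TRUE
    valid <- any(occ)
  }
  if (!valid)
    return(list(delta = numeric(0), dims = n, voxel = voxel, valid = FALSE))
  d <- .cppEDT3(as.logical(occ), n[1], n[2], n[3]) * voxel
  # restrict to the spherical analysis region
  ax <- lo[1] + (seq_len(n[1]) - 0.5) * voxel
  ay <- lo[2] + (seq_len(n[2]) - 0.5) * voxel
  az <- lo[3] + (seq_len(n[3]) - 0.5) * voxel
  cc <- expand.grid(x = ax, y = ay, z = az)
  insph <- (cc$x - centre[1])^2 + (cc$y - centre[2])^2 + (cc$z - centre[3])^2 <= radius^2
  list(delta = d[insph], dims = n, voxel = voxel, valid = TRUE)
}

#' Distance-map scaling parameters
#'
#' \code{delta_v_max} is the largest distance to the nearest vessel;
#' \code{lambda_v} the decay length of the distance-frequency histogram,
#' obtained by linear regression of log(frequency) on distance over the
#' decaying tail (bins beyond the mode with at least 5 counts).
#'
#' @param delta vector of voxel distances (mm) from \code{\link{distanceMap}}.
#' @param binwidth histogram bin width (mm).
#' @param log_tail fit in log-frequency (default); FALSE fits the raw
#'   frequencies.
#' @return list with \code{lambda_v} (mm; NA if under 3 usable bins) and
#'   \code{delta_v_max} (mm).
#' @export
scalingParameters <- function(delta, binwidth = 0.03, log_tail = TRUE) {
  if (!length(delta)) return(list(lambda_v = NA_real_, delta_v_max = NA_real_))
  dmax <- max(delta)
  br <- seq(0, dmax + binwidth, by = binwidth)
  h <- graphics::hist(delta, breaks = br, plot = FALSE)
  cnt <- h$counts
  mids <- h$mids
  mode_i <- which.max(cnt)
  use <- seq_along(cnt) > mode_i & cnt >= 5
  if (sum(use) < 3) return(list(lambda_v = NA_real_, delta_v_max = dmax))
  if (log_tail) {
    fit <- stats::lm(log(cnt[use]) ~ mids[use])
    lam <- -1 / unname(stats::coef(fit)[2])
  } else {
    fit <- stats::lm(cnt[use] ~ mids[use])
    lam <- -1 / unname(stats::coef(fit)[2])
  }
  if (!is.finite(lam) || lam <= 0) lam <- NA_real_
  list(lambda_v = lam, delta_v_max = dmax)
}

#' Perfusion-state classification of the network
#'
#' Functional segments are classed by mean blood velocity: hypo-perfused
#' below 0.1 mm/s, perfused in [0.1, 0.5] mm/s, well-perfused above
#' 0.5 mm/s; collapsed segments form their own class. Fractions are reported
#' both by segment count and by length.
#'
#' @param net an \code{angio_network}.
#' @param seg_v per-segment mean velocity (mm/s), e.g. from the flow solve.
#' @param pos_cur current node positions.
#' @return list with \code{by_count}, \code{by_length} (named fractions
#'   summing to 1) and \code{counts}.
#' @export
perfusionClassification <- function(net, seg_v, pos_cur = net$pos) {
  fun <- functionalSegs(net)
  L <- segmentLengths(net, pos_cur)
  v <- abs(seg_v)
  cls <- ifelse(!fun, "collapsed",
         ifelse(v < 0.1, "hypo", ifelse(v <= 0.5, "perfused", "well")))
  lev <- c("hypo", "perfused", "well", "collapsed")
  cnt <- vapply(lev, function(k) sum(cls == k), 0)
  len <- vapply(lev, function(k) sum(L[cls == k]), 0)
  tot <- sum(cnt)
  list(by_count = if (tot > 0) cnt / tot else cnt,
       by_length = if (sum(len) > 0) len / sum(len) else len,
       counts = cnt)
}

#' Diameter-length and velocity-diameter histograms
#'
#' Functional vessel length per lumen-diameter bin (4-10, 10-20, 20-30, ...
#' um) normalised by the total functional length, the mean velocity per bin,
#' and the collapsed-to-functional length ratio.
#'
#' @param net an \code{angio_network}.
#' @param seg_v per-segment velocities (mm/s).
#' @param pos_cur current node positions.
#' @return data.frame with bin limits, \code{norm_length} and
#'   \code{mean_velocity}; attribute \code{"collapsed_ratio"}.
#' @export
vesselHistograms <- function(net, seg_v, pos_cur = net$pos) {
  fun <- functionalSegs(net)
  L <- segmentLengths(net, pos_cur)
  dia_um <- (net$R[net$segs$a] + net$R[net$segs$b]) * 1000  # 2*R_mean in um
  lims <- c(4, seq(10, max(20, ceiling(max(dia_um) / 10) * 10), by = 10))
  lo <- lims[-length(lims)]; hi <- lims[-1]
  totL <- sum(L[fun])
  norm_length <- mean_velocity <- numeric(length(lo))
  for (k in seq_along(lo)) {
    inb <- fun & dia_um >= lo[k] & dia_um < hi[k]
    norm_length[k] <- if (totL > 0) sum(L[inb]) / totL else 0
    mean_velocity[k] <- if (any(inb)) mean(abs(seg_v[inb])) else NA_real_
  }
  out <- data.frame(dia_lo_um = lo, dia_hi_um = hi,
                    norm_length = norm_length, mean_velocity = mean_velocity)
  attr(out, "collapsed_ratio") <- if (totL > 0) sum(L[!fun]) / totL else NA_real_
  out
}

# 14 ray directions distributed over the sphere (Fibonacci lattice)
rayDirections <- function(n_rays = 14) {
  i <- seq_len(n_rays) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_rays
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Radial profiles of a nodal tissue field
#'
#' Samples the field along rays from the tumour centre in 14 azimuthal
#' directions and returns mean and standard deviation per radial bin.
#'
#' @param field nodal vector.
#' @param mesh an \code{angio_mesh}.
#' @param centre ray origin (domain centre by default).
#' @param r_max maximum radius (mm).
#' @param dr radial bin width (mm).
#' @param n_rays number of rays.
#' @return data.frame with \code{r}, \code{mean}, \code{sd}, \code{n}.
#' @export
radialProfiles <- function(field, mesh, centre = NULL, r_max = NULL,
                           dr = 0.25, n_rays = 14) {
  bb <- mesh$bbox
  centre <- centre %||% (attr(mesh, "centre") %||% colMeans(rbind(bb[1, ], bb[2, ])))
  r_max <- r_max %||% (min(bb[2, ] - centre, centre - bb[1, ]) * 0.98)
  dirs <- rayDirections(n_rays)
  radii <- seq(dr / 2, r_max, by = dr)
  pts <- do.call(rbind, lapply(seq_len(n_rays), function(k)
    cbind(centre[1] + radii * dirs[k, 1], centre[2] + radii * dirs[k, 2],
          centre[3] + radii * dirs[k, 3])))
  loc <- locateHostElement(pts, mesh)
  vals <- fieldAtLocal(field, mesh, loc$elem, loc$lc)
  rad <- rep(radii, n_rays)
  ok <- !is.na(vals)
  agg_m <- tapply(vals[ok], rad[ok], mean)
  agg_s <- tapply(vals[ok], rad[ok], stats::sd)
  agg_n <- tapply(vals[ok], rad[ok], length)
  r_out <- as.numeric(names(agg_m))
  data.frame(r = r_out, mean = as.numeric(agg_m),
             sd = as.numeric(agg_s), n = as.numeric(agg_n))
}
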