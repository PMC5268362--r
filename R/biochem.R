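# Explicit (forward-Euler, mass-lumped) finite-element solver for the
# reaction-diffusion species: angiogenic factor tau, oxygen xi, matrix
# metalloproteinase mu, and the local ODE for ECM density eps.
#
# All concentrations are normalised (dimensionless); diffusion coefficients
# in mm^2/day, rates in 1/day; the Laplacian acts in reference coordinates
# and zero-flux conditions hold naturally on the outer boundary.

#' Assemble the lumped mass vector and unit-diffusivity stiffness matrix
#'
#' @param mesh an \code{angio_mesh}.
#' @return list with \code{M} (lumped, length N) and sparse \code{K} such
#'   that the semi-discrete system is \code{M df/dt = -D K f + M (q - d f)}.
#' @export
biochemOperators <- function(mesh) {
  E <- nrow(mesh$elems); N <- nrow(mesh$nodes); nq <- 8L
  G <- array(mesh$quad$gradN, dim = c(3, 8, nq, E))   # [d, a, q, e]
  dV <- matrix(mesh$quad$dV, nq, E)
  Nq <- mesh$quad$Nq                                   # nq x 8
  conn <- mesh$elems
  M <- numeric(N)
  for (a in 1:8) {
    w <- colSums(Nq[, a] * dV)
    acc <- rowsum(w, conn[, a])
    M[as.integer(rownames(acc))] <- M[as.integer(rownames(acc))] + acc[, 1]
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (a in 1:8) for (b in a:8) {
    # K_ab per element = sum_q sum_d G[d,a,q,e] G[d,b,q,e] dV[q,e]
    prod_ <- G[1, a, , ] * G[1, b, , ] + G[2, a, , ] * G[2, b, , ] +
             G[3, a, , ] * G[3, b, , ]
    kab <- colSums(prod_ * dV)
    ii <- c(ii, conn[, a]); jj <- c(jj, conn[, b]); xx <- c(xx, kab)
    if (b > a) { ii <- c(ii, conn[, b]); jj <- c(jj, conn[, a]); xx <- c(xx, kab) }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  list(M = M, K = K)
}

#' TAF production rate
#'
#' Hypoxic tumour cells secrete the angiogenic factor at a rate that decays
#' exponentially with the local oxygen level; there is no production in the
#' host tissue.
#'
#' @param xi normalised oxygen concentration (vector).
#' @param in_tumour logical (vector).
#' @param params list with \code{lambda_tau} (1/day) and \code{xi_bar}.
#' @return production rate (1/day).
#' @export
tafProduction <- function(xi, in_tumour, params) {
  ifelse(in_tumour, params$lambda_tau * exp(-2 * xi / params$xi_bar), 0)
}

#' MMP production rate
#'
#' Proliferating tumour cells contribute a constant rate inside the tumour;
#' tip endothelial cells contribute proportionally to the local tip density
#' everywhere.
#'
#' @param rho_t tip-node density (count, vector).
#' @param in_tumour logical (vector).
#' @param params list with \code{lambda_mu_c}, \code{lambda_mu_v} (1/day).
#' @return production rate (1/day).
#' @export
mmpProduction <- function(rho_t, in_tumour, params) {
  ifelse(in_tumour, params$lambda_mu_c + params$lambda_mu_v * rho_t,
         params$lambda_mu_v * rho_t)
}

#' Forward-Euler step of the ECM degradation ODE
#'
#' \code{eps <- eps * (1 - delta_eps * mu * dt)} on host nodes, clipped below
#' at a positive floor; tumour nodes are untouched.
#'
#' @param eps,mu nodal vectors.
#' @param dt time step (days).
#' @param delta_eps degradation rate (1/day).
#' @param host logical nodal mask (TRUE on the host domain).
#' @param floor_ lower clip for eps.
#' @export
stepECM <- function(eps, mu, dt, delta_eps, host = rep(TRUE, length(eps)),
                    floor_ = 0.05) {
  if (any(eps < 0) || any(mu < 0)) stopf("negative field passed to stepECM")
  out <- eps
  out[host] <- pmax(eps[host] * (1 - delta_eps * mu[host] * dt), floor_)
  out
}

#' Stable explicit time step for the biochemical solver
#'
#' CFL-type bound \code{dt = safety * h_min^2 / (2 * dim * D_max)} with
#' safety 0.5 and dim 3, capped at the solid-solver step when diffusion is
#' absent.
#'
#' @param mesh an \code{angio_mesh}.
#' @param params list with the diffusion coefficients \code{D_tau},
#'   \code{D_xi}, \code{D_mu} (mm^2/day).
#' @param dt_solid cap (days), default one hour.
#' @return time step in days; attribute \code{"seconds"} carries the value
#'   in seconds.
#' @export
stableTimestep <- function(mesh, params, dt_solid = 1 / 24) {
  Dmax <- max(params$D_tau, params$D_xi, params$D_mu)
  dt <- if (Dmax <= 0) dt_solid else
    min(0.5 * mesh$min_edge^2 / (2 * 3 * Dmax), dt_solid)
  attr(dt, "seconds") <- dt * 86400
  dt
}

#' One explicit reaction-diffusion step
#'
#' Mass-lumped forward-Euler update of a nodal field with constant isotropic
#' diffusivity, nodal source and linear decay; zero-flux boundary conditions
#' are natural. Small negative undershoots are clipped to zero; the run
#' aborts if the clipped mass exceeds \code{clip_tol} of the total or if
#' non-finite values appear.
#'
#' @param field nodal vector.
#' @param D diffusivity (mm^2/day).
#' @param source nodal production rate (1/day).
#' @param decay linear decay rate (1/day), scalar or nodal.
#' @param dt time step (days).
#' @param ops operators from \code{\link{biochemOperators}}.
#' @param clip_tol abort when the clipped (negative) mass exceeds this
#'   fraction of the total mass in one step.
#' @return updated nodal vector (attribute \code{"clipped"}: count).
#' @export
stepReactionDiffusion <- function(field, D, source, decay, dt, ops,
                                  clip_tol = 1e-3) {
  f <- field + dt * (-(D * as.numeric(ops$K %*% field)) / ops$M +
                     source - decay * field)
  if (any(!is.finite(f))) stopf("non-finite value in reaction-diffusion step")
  neg <- f < 0
  if (any(neg)) {
    clipped_mass <- -sum(ops$M[neg] * f[neg])
    total <- sum(ops$M * pmax(f, 0))
    if (total > 0 && clipped_mass > clip_tol * total)
      stopf("excessive negative undershoot in explicit step (%.3g of mass)",
            clipped_mass / total)
    f[neg] <- 0
  }
  attr(f, "clipped") <- sum(neg)
  f
}

#' Field gradients at element quadrature points
#'
#' @param field nodal vector.
#' @param mesh an \code{angio_mesh}.
#' @return array \code{[3, 8, E]}: gradient components at the 8 quadrature
#'   points of each element.
#' @export
computeGradients <- function(field, mesh) {
  E <- nrow(mesh$elems); nq <- 8L
  G <- array(mesh$quad$gradN, dim = c(3, 8, nq, E))
  fcon <- matrix(field[t(mesh$elems)], 8, E)   # [a, e]
  out <- array(0, dim = c(3, nq, E))
  for (q in seq_len(nq)) for (d in 1:3)
    out[d, q, ] <- colSums(G[d, , q, ] * fcon)
  out
}
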