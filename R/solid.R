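# Quasi-static nonlinear tissue mechanics with oxygen-driven multiplicative
# growth (F = F_e F_g) and an ECM-integrity-scaled generalised polynomial
# hyperelastic energy. Stresses in kPa; converted to mm-Hg only at the
# vascular coupling boundary.

#' Oxygen-driven Gompertz growth volume strain
#'
#' \code{theta_g = alpha_g exp(-beta_g exp(-gamma_g xi)) - alpha_g
#' exp(-beta_g)}: zero without oxygen, saturating at
#' \code{alpha_g (1 - exp(-beta_g))} under full oxygenation. Applied on
#' tumour material only.
#'
#' @param xi normalised oxygen concentration (vector).
#' @param alpha_g,beta_g,gamma_g dimensionless growth parameters.
#' @return Green-Lagrange growth volume strain.
#' @export
growthVolumeStrain <- function(xi, alpha_g, beta_g, gamma_g) {
  alpha_g * exp(-beta_g * exp(-gamma_g * xi)) - alpha_g * exp(-beta_g)
}

#' Assemble the growth deformation gradient
#'
#' \code{F_g = lambda_g I + (lambda_g_xi - lambda_g) n_xi (x) n_xi +
#' (lambda_g_eps - lambda_g) n_eps (x) n_eps}, with each stretch recovered
#' from its Green-Lagrange strain via \code{lambda = sqrt(2 theta + 1)}.
#' Gradient directions are normalised to unit vectors before forming the
#' dyads (zero gradients drop the corresponding term).
#'
#' @param theta_g isotropic growth strain.
#' @param theta_g_xi,theta_g_eps directional growth strains along the oxygen
#'   and ECM gradients.
#' @param grad_xi,grad_eps gradient vectors (any magnitude; orientation only).
#' @return 3 x 3 growth deformation gradient.
#' @export
growthTensor <- function(theta_g, theta_g_xi = 0, theta_g_eps = 0,
                         grad_xi = c(0, 0, 0), grad_eps = c(0, 0, 0)) {
  lam <- function(th) {
    if (2 * th + 1 <= 0) stopf("growth strain %.3g below the -1/2 limit", th)
    sqrt(2 * th + 1)
  }
  lg <- lam(theta_g)
  Fg <- diag(lg, 3)
  nx <- unitVector(grad_xi)
  if (!is.null(nx)) Fg <- Fg + (lam(theta_g_xi) - lg) * tcrossprod(nx)
  ne <- unitVector(grad_eps)
  if (!is.null(ne)) Fg <- Fg + (lam(theta_g_eps) - lg) * tcrossprod(ne)
  Fg
}

#' Stored-energy function of the elastic deformation
#'
#' Generalised polynomial form on the isochoric invariants of the elastic
#' right Cauchy-Green tensor plus a quadratic volumetric term; the isochoric
#' part is scaled by the ECM integrity factor zeta, the volumetric part is
#' not.
#'
#' @param Ce elastic right Cauchy-Green tensor (3 x 3).
#' @param zeta integrity factor in (0, 1].
#' @param pars named list/vector with c10, c20, c01, c02, c11, kappa (kPa).
#' @return energy density (kPa).
#' @export
storedEnergy <- function(Ce, zeta, pars) {
  p <- as.list(pars)
  I1 <- sum(diag(Ce))
  I2 <- (I1^2 - sum(Ce * Ce)) / 2
  J <- sqrt(det(Ce))
  I1b <- J^(-2 / 3) * I1
  I2b <- J^(-4 / 3) * I2
  zeta * (p$c10 * (I1b - 3) + p$c20 * (I1b - 3)^2 + p$c01 * (I2b - 3) +
          p$c02 * (I2b - 3)^2 + p$c11 * (I1b - 3) * (I2b - 3)) +
    p$kappa * (J - 1)^2 / 2
}

#' Second Piola-Kirchhoff stress of the growth-hyperelastic law
#'
#' Analytic derivative of the stored energy. With
#' \code{measure = "intermediate"} returns \code{S_e = dW/dE_e} (conjugate to
#' the elastic Green-Lagrange strain, as used in the constitutive checks);
#' with \code{measure = "reference"} returns the pull-back
#' \code{J_g F_g^-1 S_e F_g^-T} that enters the equilibrium equations.
#'
#' @param F total deformation gradient (3 x 3).
#' @param Fg growth deformation gradient (3 x 3).
#' @param zeta ECM integrity factor.
#' @param pars material constants (c10, c20, c01, c02, c11, kappa).
#' @param measure stress measure, see above.
#' @return 3 x 3 symmetric stress (kPa).
#' @export
elasticStress <- function(F, Fg = diag(3), zeta = 1, pars,
                          measure = c("intermediate", "reference")) {
  measure <- match.arg(measure)
  p <- as.list(pars)
  Fgi <- solve(Fg)
  Fe <- F %*% Fgi
  if (det(Fe) <= 0) stopf("non-positive elastic volume ratio")
  Ce <- t(Fe) %*% Fe
  I1 <- sum(diag(Ce))
  I2 <- (I1^2 - sum(Ce * Ce)) / 2
  J <- sqrt(det(Ce))
  Jm23 <- J^(-2 / 3); Jm43 <- Jm23^2
  I1b <- Jm23 * I1; I2b <- Jm43 * I2
  Ci <- solve(Ce)
  W1 <- zeta * (p$c10 + 2 * p$c20 * (I1b - 3) + p$c11 * (I2b - 3))
  W2 <- zeta * (p$c01 + 2 * p$c02 * (I2b - 3) + p$c11 * (I1b - 3))
  I3 <- diag(3)
  Se <- 2 * W1 * Jm23 * (I3 - (I1 / 3) * Ci) +
        2 * W2 * (Jm43 * (I1 * I3 - Ce) - (2 / 3) * I2b * Ci) +
        p$kappa * (J - 1) * J * Ci
  if (measure == "intermediate") return(Se)
  det(Fg) * Fgi %*% Se %*% t(Fgi)
}

#' Hydrostatic pressure of a stress tensor
#'
#' Returns \code{-tr(S)/3} so compression is positive.
#'
#' @param S 3 x 3 stress tensor.
#' @export
hydrostaticPressure <- function(S) -sum(diag(S)) / 3

#' Mechanotaxis traction direction
#'
#' Unit eigenvector of the algebraically smallest eigenvalue of the symmetric
#' stress tensor (the direction of strongest compression). The sign is chosen
#' so that the mechanotactic term \code{-k_m t} has a non-negative projection
#' on the previous tip direction; for (near-)isotropic stress the previous
#' direction is returned with reversed sign, so \code{-k_m t} reproduces it.
#'
#' @param S 3 x 3 symmetric stress tensor.
#' @param prev previous unit tip direction (tie-breaking), optional.
#' @param tol relative degeneracy tolerance.
#' @return unit vector.
#' @export
tractionDirection <- function(S, prev = NULL, tol = 1e-8) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  vals <- ev$values  # decreasing
  scale_ <- max(abs(vals), 1e-300)
  if ((vals[2] - vals[3]) < tol * scale_) {
    if (!is.null(prev) && sqrt(sum(prev^2)) > 0) return(-prev / sqrt(sum(prev^2)))
    return(c(0, 0, 1))
  }
  t_ <- ev$vectors[, 3]
  t_ <- t_ / sqrt(sum(t_^2))
  if (!is.null(prev)) {
    # -k_m t should not oppose the previous direction
    if (sum(-t_ * prev) < 0) t_ <- -t_
  } else if (t_[which.max(abs(t_))] < 0) t_ <- -t_
  t_
}

# ---------------------------------------------------------------------------
# Equilibrium solver

# reusable solver context: dof maps and (lazily) the sparsity pattern.
# fixed_nodes: node indices (all three dofs pinned) or an N x 3 logical
# matrix of pinned dofs (e.g. symmetry planes).
solidSolver <- function(mesh, fixed_nodes) {
  N <- nrow(mesh$nodes)
  fixed <- matrix(FALSE, N, 3)
  if (is.matrix(fixed_nodes)) fixed <- fixed_nodes else fixed[fixed_nodes, ] <- TRUE
  dofmap <- matrix(-1L, N, 3)
  nf <- 0L
  for (i in seq_len(N)) for (d in 1:3) if (!fixed[i, d]) {
    dofmap[i, d] <- nf
    nf <- nf + 1L
  }
  # linear index (column-major into an N x 3 matrix) of each free dof
  posU <- integer(nf)
  for (i in seq_len(N)) for (d in 1:3) if (!fixed[i, d])
    posU[dofmap[i, d] + 1L] <- i + N * (d - 1L)
  env <- new.env(parent = emptyenv())
  env$pattern <- NULL
  list(mesh = mesh, dofmap = dofmap, nf = nf, posU = posU, cache = env)
}

buildPattern <- function(solver, ti, tj, tx) {
  nf <- solver$nf
  keys <- as.numeric(tj) * nf + as.numeric(ti)
  o <- order(keys)
  uk <- unique(keys[o])
  map <- match(keys, uk)
  K <- Matrix::sparseMatrix(i = ti + 1L, j = tj + 1L, x = tx, dims = c(nf, nf))
  solver$cache$pattern <- list(map = map, nx = length(uk), K = K)
  invisible(NULL)
}

assembleSolid <- function(solver, u, Fg, zeta_q, matid, matpars, tangent = TRUE) {
  mesh <- solver$mesh
  out <- .cppSolidAssemble(mesh$elems - 1L, u, mesh$quad$gradN, mesh$quad$dV,
                           Fg, zeta_q, matid, matpars, solver$dofmap, tangent)
  if (!isTRUE(out$ok)) return(NULL)
  res <- list(res = out$res)
  if (tangent) {
    if (is.null(solver$cache$pattern)) buildPattern(solver, out$i, out$j, out$x)
    pat <- solver$cache$pattern
    K <- pat$K
    K@x <- .cppAccumulate(pat$map, out$x, pat$nx)
    res$K <- K
  }
  res
}

solveLinear <- function(K, r) {
  Ks <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  du <- tryCatch(as.numeric(Matrix::solve(Ks, r)), error = function(e) NULL)
  if (is.null(du) || any(!is.finite(du)))
    du <- as.numeric(Matrix::solve(K, r))
  du
}

newtonSolve <- function(solver, u, Fg, zeta_q, matid, matpars,
                        rtol = 1e-8, utol = 1e-10, maxit = 30) {
  posU <- solver$posU
  r0 <- NULL
  for (it in seq_len(maxit)) {
    asm <- assembleSolid(solver, u, Fg, zeta_q, matid, matpars, tangent = TRUE)
    if (is.null(asm)) return(list(ok = FALSE, reason = "element inversion", u = u))
    r <- asm$res[posU]
    nr <- sqrt(sum(r^2))
    if (is.null(r0)) r0 <- max(nr, 1e-12)
    if (nr < rtol * r0 || nr < 1e-12)
      return(list(ok = TRUE, u = u, iters = it - 1L, resid = nr))
    du <- solveLinear(asm$K, r)
    if (any(!is.finite(du))) return(list(ok = FALSE, reason = "singular tangent", u = u))
    # simple backtracking on the residual norm
    step <- 1
    repeat {
      u2 <- u
      u2[posU] <- u2[posU] - step * du
      asm2 <- assembleSolid(solver, u2, Fg, zeta_q, matid, matpars, tangent = FALSE)
      if (!is.null(asm2)) {
        nr2 <- sqrt(sum(asm2$res[posU]^2))
        if (nr2 < nr || step < 0.26) break
      }
      step <- step / 2
      if (step < 1 / 32) {
        if (is.null(asm2)) return(list(ok = FALSE, reason = "line search failed", u = u))
        break
      }
    }
    if (sqrt(sum((step * du)^2)) < utol * (1 + sqrt(sum(u2[posU]^2))))
      return(list(ok = TRUE, u = u2, iters = it, resid = nr))
    u <- u2
  }
  list(ok = FALSE, reason = "no convergence", u = u)
}

#' Solve quasi-static equilibrium under a prescribed growth field
#'
#' Full Newton iteration (numerically consistent tangent, backtracking line
#' search, growth-increment sub-stepping on failure) for the displacement
#' field balancing the grown hyperelastic body. Boundary conditions: zero
#' displacement on the given node set, traction-free elsewhere.
#'
#' @param mesh an \code{angio_mesh}.
#' @param Fg growth deformation gradients, numeric vector of length
#'   \code{E*8*9} ([e][q][3x3 row-major]) or NULL for identity.
#' @param zeta_q integrity factor per quadrature point (length \code{E*8})
#'   or scalar.
#' @param fixed_nodes node indices pinned to zero displacement (default: the
#'   inlet/outlet faces).
#' @param matpars 2 x 6 matrix of material constants (rows: host, tumour;
#'   columns c10, c20, c01, c02, c11, kappa in kPa).
#' @param u0 initial guess (N x 3), zeros by default.
#' @param Fg_prev previously converged growth field for sub-stepping, NULL
#'   for identity.
#' @param rtol relative residual tolerance.
#' @param max_cutbacks growth sub-stepping bisection levels before aborting.
#' @return list with \code{u} (N x 3), \code{iters}, \code{resid}.
#' @export
solveEquilibrium <- function(mesh, Fg = NULL, zeta_q = 1,
                             fixed_nodes = c(mesh$inlet_nodes, mesh$outlet_nodes),
                             matpars, u0 = NULL, Fg_prev = NULL,
                             rtol = 1e-8, max_cutbacks = 5,
                             solver = NULL) {
  E <- nrow(mesh$elems)
  idq <- rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), E * 8)
  if (is.null(Fg)) Fg <- idq
  if (length(zeta_q) == 1) zeta_q <- rep(zeta_q, E * 8)
  if (is.null(Fg_prev)) Fg_prev <- idq
  matid <- mesh$label - 1L  # 0 host, 1 tumour
  if (is.null(solver)) solver <- solidSolver(mesh, fixed_nodes)
  u <- u0 %||% matrix(0, nrow(mesh$nodes), 3)
  # adaptive growth-increment continuation: advance the blend fraction from
  # the previously converged growth field towards the target, halving the
  # increment on failure. An unconvergeable remainder is carried over (the
  # caller re-applies it at the next solve) rather than aborting the run.
  s_min <- 2^(-max_cutbacks - 1)
  s_done <- 0; s_try <- 1
  iters <- 0L; resid <- NA_real_
  first_fail <- NULL
  while (s_done < 1 - 1e-12) {
    s1 <- min(s_done + s_try, 1)
    Fg_s <- Fg_prev + s1 * (Fg - Fg_prev)
    out <- newtonSolve(solver, u, Fg_s, zeta_q, matid, matpars, rtol = rtol)
    if (out$ok) {
      u <- out$u
      s_done <- s1
      iters <- iters + (out$iters %||% 0L)
      resid <- out$resid
      s_try <- min(2 * s_try, 1)
    } else {
      first_fail <- first_fail %||% out$reason
      s_try <- s_try / 2
      if (s_try < s_min) break
    }
  }
  if (s_done == 0)
    stopf("solid solver failed (%s) with no convergent growth increment",
          first_fail %||% "unknown")
  list(u = u, iters = iters, resid = resid, solver = solver,
       growth_fraction = s_done,
       Fg_applied = Fg_prev + s_done * (Fg - Fg_prev))
}

#' Per-element stress measures for a converged state
#'
#' Quadrature-averaged reference second Piola-Kirchhoff stress, tissue
#' hydrostatic pressure (reference and Cauchy-equivalent, positive in
#' compression, kPa) and mean volume ratio per element.
#'
#' @inheritParams solveEquilibrium
#' @param u converged displacements (N x 3).
#' @return list with \code{S} (E x 6: xx yy zz xy xz yz), \code{thp_ref},
#'   \code{thp_cauchy}, \code{detF}.
#' @export
solidStressField <- function(mesh, u, Fg = NULL, zeta_q = 1, matpars) {
  E <- nrow(mesh$elems)
  if (is.null(Fg)) Fg <- rep(c(1, 0, 0, 0, 1, 0, 0, 0, 1), E * 8)
  if (length(zeta_q) == 1) zeta_q <- rep(zeta_q, E * 8)
  .cppSolidStressField(mesh$elems - 1L, u, mesh$quad$gradN, mesh$quad$dV,
                       Fg, zeta_q, mesh$label - 1L, matpars)
}
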