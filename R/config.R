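# Simulation configuration: defaults, YAML I/O, validation.
#
# Values anchored in published experimental or modelling literature are
# marked [lit]; the remaining defaults are the package's own
# physiologically-motivated choices, marked [assumed] and discussed in the
# methods vignette.

#' Default simulation configuration
#'
#' Nested parameter list covering the domain, time discretisation,
#' biochemical, solid, vascular and fluid models. Units: mm, days (mm-Hg s
#' inside the flow solver), kPa for solid moduli, normalised concentrations.
#'
#' @return a list of class \code{angio_config}.
#' @export
defaultConfig <- function() {
  cfg <- list(
    seed = 1L,
    taxis_mode = "combined",          # "combined" or "chemo_only" [lit]
    domain = list(
      edge_length = 12,               # mm [lit]
      n_per_side = 16L,               # [assumed] graded, min edge ~0.07 mm
      grading = 4.6,                  # [assumed] centre refinement
      tumour_diameter = 1,            # mm [lit]
      mesh_file = NULL
    ),
    time = list(
      days = 40,                      # [lit]
      dt_v = 0.25,                    # vascular step, 6 h [lit]
      dt_solid = 1 / 24               # solid step, ~1 h [lit]
    ),
    network = list(
      spacing = 0.6,                  # mm inter-capillary [lit]
      radius = 0.03,                  # mm parent lumen radius [assumed]
      thickness = 5e-3,               # mm parent wall thickness [assumed]
      pore_radius = 5e-5              # mm parent (tight) pore radius [assumed]
    ),
    biochem = list(
      D_tau = 10, D_xi = 2, D_mu = 1,           # mm^2/day [assumed]
      delta_tau = 1, delta_xi = 50, delta_mu = 2, delta_eps = 0.15,  # 1/day [assumed]
      lambda_tau = 100, lambda_xi = 50,         # 1/day [assumed]
      lambda_mu_c = 2, lambda_mu_v = 0.2,       # 1/day [assumed]
      xi_bar = 0.5,                             # [assumed]
      eps_floor = 0.05
    ),
    solid = list(
      host = c(c10 = 1, c20 = 0.5, c01 = 0.25, c02 = 0, c11 = 0, kappa = 50),
      tumour = c(c10 = 2, c20 = 1, c01 = 0.5, c02 = 0, c11 = 0, kappa = 100),
      alpha_g = 22, beta_g = 40, gamma_g = 6,   # [assumed]
      growth_xi = c(alpha = 1.5, beta = 40, gamma = 6),   # [assumed]
      growth_eps = c(alpha = 1.5, beta = 40, gamma = 6),  # [assumed]
      g_max = 0.7,                    # 1/day max volumetric growth rate [assumed]
      thp_measure = "cauchy"          # or "reference" (literal tr(S)/3)
    ),
    vascular = list(
      k_tau = 1, k_eps = 0.35, k_m = 0.35,      # taxis weights [assumed]
      tau_star = 0.02,                           # TAF threshold [lit]
      anastomosis_dist = 0.04,                   # mm [lit]
      R_min = 0.005, R_max = 0.05,               # mm [lit]
      B_R = 11, C_R = 4.4,                       # [lit]
      h_min = 5e-4, h_max = 5e-3,                # mm [assumed]
      r_p_min = 5e-5, r_p_max = 4e-4,            # mm [assumed]
      v_v0 = 0.05, v_v1 = 0.25,                  # mm/day [assumed]
      R_tilde = 0.01,                            # mm [assumed]
      v_vmax = 0.25,                             # mm/day [lit: 0.0625 mm / 6 h]
      R_cutoff = 0.002,                          # mm [lit]
      t_m0 = 100, t_mT = 10,                     # days [lit]
      tauf_coef = 2.4e-8,                        # mm-Hg m [lit]
      v_well = 0.1,                              # mm/s [lit]
      branching = list(
        hypo = list(m_A = 2, s_A = 1, w_A = 0.03, m_D = 0.12, s_D = 0.06, w_D = 0.03),
        well = list(m_A = 2, s_A = 1, w_A = 0.015, m_D = 0.12, s_D = 0.06, w_D = 0.015)
      ),
      e_c = 0.92,                                # [lit]
      E_w_min = 1.3, E_w_max = 5.22,             # [lit]
      lambda_r = 1e3                             # [lit]
    ),
    fluid = list(
      mu_B = 3e-5,                 # mm-Hg s (4 cP) [paper via tau_f_bar]
      K_int_host = 1e-5, K_int_tumour = 3e-5,  # mm^2/(mm-Hg s) [assumed]
      gamma_p = 1e-5,              # [assumed]
      sigma_o = 0.91,              # [assumed]
      pi_vsc = 20, pi_int = 15,    # mm-Hg [assumed]
      p_inlet = 25, p_outlet = 10, # mm-Hg [lit]
      p_boundary = 0.1,            # mm-Hg [lit]
      S_vsc_default = 0.52,        # 1/mm, matches the initial lattice [assumed]
      R_bar_default = 0.03         # mm [assumed]
    ),
    output = list(
      metrics_every = 0.25,        # days
      morphometrics_every = 1,     # days (ICD, distance map)
      icd_spacing = 0.1,           # mm sampling for inter-capillary distance
      voxel = 0.03                 # mm distance-map voxel
    )
  )
  class(cfg) <- c("angio_config", "list")
  cfg
}

#' Read / write a configuration as YAML
#' @param path YAML file.
#' @export
readConfig <- function(path) {
  cfg <- utils::modifyList(defaultConfig(), yaml::read_yaml(path))
  class(cfg) <- c("angio_config", "list")
  cfg
}

#' @rdname readConfig
#' @param config an \code{angio_config}.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a configuration (and optionally its mesh)
#'
#' Checks parameter sanity, the branching-probability ordering (hypo-perfused
#' vessels must branch at least as easily as well-perfused ones), and the
#' mesh/elongation compatibility rule: the minimum element edge must be at
#' least the maximum tip elongation per vascular step
#' (\code{v_vmax * dt_v}).
#'
#' @param config an \code{angio_config}.
#' @param mesh optional \code{angio_mesh} for the mesh-dependent checks.
#' @return list of class \code{angio_validation} with \code{ok},
#'   \code{errors}, \code{info}.
#' @export
validateConfig <- function(config, mesh = NULL) {
  errs <- character(0)
  info <- character(0)
  bad <- function(cond, msg) if (isTRUE(cond)) errs <<- c(errs, msg)
  bc <- config$biochem
  for (nm in c("D_tau", "D_xi", "D_mu", "delta_tau", "delta_xi", "delta_mu",
               "delta_eps", "lambda_tau", "lambda_xi", "lambda_mu_c",
               "lambda_mu_v", "xi_bar"))
    bad(bc[[nm]] < 0, sprintf("biochem$%s must be non-negative", nm))
  vs <- config$vascular
  bad(vs$R_min >= vs$R_max, "vascular$R_min must be below R_max")
  bad(vs$h_min > vs$h_max, "vascular$h_min must not exceed h_max")
  bad(vs$r_p_min >= vs$r_p_max, "vascular$r_p_min must be below r_p_max")
  bad(vs$t_mT >= vs$t_m0, "vascular$t_mT must be below t_m0")
  bad(vs$e_c <= 0 || vs$e_c >= 1, "vascular$e_c must lie in (0,1)")
  bad(vs$E_w_min <= 0 || vs$E_w_max < vs$E_w_min,
      "vascular wall stiffness range invalid")
  bad(any(c(vs$k_tau, vs$k_eps, vs$k_m) < 0), "taxis weights must be >= 0")
  for (cl in c("hypo", "well")) {
    p <- vs$branching[[cl]]
    bad(p$s_A <= 0 || p$s_D <= 0, sprintf("branching$%s: sd must be > 0", cl))
    bad(p$w_A + p$w_D > 1, sprintf("branching$%s: weights must sum to <= 1", cl))
  }
  ages <- seq(0, 10, by = 0.5); dists <- seq(0, 0.6, by = 0.03)
  grid_ <- expand.grid(a = ages, d = dists)
  Ph <- branchingProbability(grid_$a, grid_$d, "hypo", vs$branching)
  Pw <- branchingProbability(grid_$a, grid_$d, "well", vs$branching)
  bad(any(Ph < Pw - 1e-12),
      "hypo-perfused branching probability must dominate the well-perfused one")
  fl <- config$fluid
  bad(fl$mu_B <= 0 || fl$K_int_host <= 0 || fl$K_int_tumour <= 0,
      "fluid conductivities/viscosity must be positive")
  bad(fl$sigma_o < 0 || fl$sigma_o > 1, "fluid$sigma_o must lie in [0,1]")
  elong <- vs$v_vmax * config$time$dt_v
  info <- c(info, sprintf("maximum tip elongation per vascular step: %.4g mm", elong))
  if (!is.null(mesh)) {
    info <- c(info, sprintf("mesh minimum edge length: %.4g mm", mesh$min_edge))
    bad(mesh$min_edge < elong,
        sprintf("mesh min edge %.4g mm below the maximum elongation %.4g mm",
                mesh$min_edge, elong))
    dtb <- stableTimestep(mesh, bc, config$time$dt_solid)
    info <- c(info, sprintf("stable biochemical step: %.3g s", attr(dtb, "seconds")))
  }
  structure(list(ok = length(errs) == 0, errors = errs, info = info),
            class = "angio_validation")
}

#' @method print angio_validation
#' @export
print.angio_validation <- function(x, ...) {
  cat(if (x$ok) "configuration OK\n" else "configuration INVALID\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (i in x$info) cat("  info:", i, "\n")
  invisible(x)
}
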