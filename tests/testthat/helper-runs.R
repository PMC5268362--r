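# Memoised scenario runs shared by the emergent-behaviour and quantitative
# acceptance checks. Problem sizes are the package's desk-scale reference
# scenario (12 mm cube on a centre-graded 10^3 mesh resolving the 1 mm
# tumour; 16 simulated days for the taxis contrast, 12 for the wall-stiffness
# scenario) - see the methods vignette.

.run_cache <- new.env(parent = emptyenv())

scaledConfig <- function(taxis = "combined", stiff_mult = 1, seed = 1L) {
  cfg <- defaultConfig()
  cfg$seed <- seed
  cfg$taxis_mode <- taxis
  cfg$domain$n_per_side <- 10L
  cfg$domain$grading <- 3
  cfg$domain$tumour_diameter <- 1
  cfg$vascular$E_w_min <- cfg$vascular$E_w_min * stiff_mult
  cfg$vascular$E_w_max <- cfg$vascular$E_w_max * stiff_mult
  cfg$output$morphometrics_every <- 4   # ICD / distance map cadence (days)
  cfg
}

memoRun <- function(key, cfg, days) {
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- runSimulation(cfg, days = days)
  .run_cache[[key]]
}

combinedRun <- function() memoRun("combined", scaledConfig("combined"), 16)
chemoRun <- function() memoRun("chemo", scaledConfig("chemo_only"), 16)
stiffRun <- function() memoRun("stiff", scaledConfig("combined", stiff_mult = 10), 10)

# mean |e_hat . r_hat| of post-natal vessel directions in the peritumoural
# shell (tumour interface to interface + 1 mm)
shellOrientation <- function(st) {
  ctr <- attr(st$mesh, "centre")
  m <- utils::tail(st$metrics, 1)
  rT <- (3 * m$tumour_volume_mm3 / (4 * pi))^(1 / 3)
  net <- st$net
  sel <- which(net$tg > 0 & net$state != 2L)
  r <- sweep(net$pos[sel, , drop = FALSE], 2, ctr)
  rad <- sqrt(rowSums(r^2))
  band <- rad > rT & rad < rT + 1
  rhat <- r[band, , drop = FALSE] / rad[band]
  d <- net$dir[sel, , drop = FALSE][band, , drop = FALSE]
  mean(abs(rowSums(rhat * d)))
}
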