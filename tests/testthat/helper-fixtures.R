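# Small fixtures built in code: meshes, hand-made networks, parameter sets.

testMatpars <- function() {
  rbind(c(1, 0.5, 0.25, 0, 0, 50),     # host
        c(2, 1, 0.5, 0, 0, 100))       # tumour
}

# a uniform small cube mesh (host-only unless tumour_diameter > 0)
smallCube <- function(edge = 6, n = 6L, tumour = 0, grading = 0) {
  generateCubeMesh(edge, n, tumour, grading)
}

# hand-built vascular path: nodes at given positions, consecutive segments;
# first node inlet, last outlet unless open_end
handNetwork <- function(pos, mesh, inlet = 1L, outlet = nrow(pos),
                        radius = 0.03, tg = 0, tip = integer(0)) {
  n <- nrow(pos)
  loc <- locateHostElement(pos, mesh)
  inl <- rep(FALSE, n); inl[inlet] <- TRUE
  out <- rep(FALSE, n); out[outlet] <- TRUE
  net <- angiomech:::newNetwork(
    pos = pos, tg = rep(tg, n), tip = seq_len(n) %in% tip,
    inlet = inl, outlet = out, frozen = inl | out,
    R = rep(radius, n), h = rep(5e-3, n), rp = rep(5e-5, n),
    state = rep(0L, n), elem = loc$elem, lc = loc$lc,
    dir = matrix(rep(c(1, 0, 0), each = n), n, 3), vessel = rep(1L, n))
  for (k in seq_len(n - 1))
    net <- angiomech:::addSegment(net, k, k + 1L)
  net
}

vascParams <- function() defaultConfig()$vascular

fluidParams <- function() defaultConfig()$fluid

expect_close <- function(x, y, tol) testthat::expect_lt(max(abs(x - y)), tol)
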