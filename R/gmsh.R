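# Gmsh ASCII mesh I/O (v2.2 and v4.1 dialects).
#
# Physical group convention: volume groups 1 = host, 2 = tumour; surface
# groups 11 = inlet face, 12 = outlet face. Only 8-node hexahedra are accepted
# as volume cells; boundary quadrilaterals carry the face tags.

GMSH_HEX <- 5L
GMSH_QUAD <- 3L

#' Write a mesh in Gmsh ASCII format
#'
#' @param mesh an \code{angio_mesh}.
#' @param path output file.
#' @param version \code{"2.2"} or \code{"4.1"}.
#' @export
writeGmshMesh <- function(mesh, path, version = c("2.2", "4.1")) {
  version <- match.arg(version)
  N <- nrow(mesh$nodes); E <- nrow(mesh$elems)
  # tagged boundary faces (quads) on the inlet/outlet node sets
  inlet <- facesOnNodeSet(mesh, mesh$inlet_nodes)
  outlet <- facesOnNodeSet(mesh, mesh$outlet_nodes)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  if (version == "2.2") {
    w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
    w("$Nodes"); w("%d", N)
    writeLines(paste(seq_len(N), fmt(mesh$nodes[, 1]), fmt(mesh$nodes[, 2]),
                     fmt(mesh$nodes[, 3])), con)
    w("$EndNodes")
    nel <- E + nrow(inlet) + nrow(outlet)
    w("$Elements"); w("%d", nel)
    id <- 1L
    for (set in list(list(inlet, 11L), list(outlet, 12L))) {
      f <- set[[1]]
      if (nrow(f))
        writeLines(paste(id:(id + nrow(f) - 1L), GMSH_QUAD, 2, set[[2]], set[[2]],
                         f[, 1], f[, 2], f[, 3], f[, 4]), con)
      id <- id + nrow(f)
    }
    writeLines(paste(id:(id + E - 1L), GMSH_HEX, 2, mesh$label, mesh$label,
                     mesh$elems[, 1], mesh$elems[, 2], mesh$elems[, 3],
                     mesh$elems[, 4], mesh$elems[, 5], mesh$elems[, 6],
                     mesh$elems[, 7], mesh$elems[, 8]), con)
    w("$EndElements")
  } else {
    # v4.1: one discrete entity per physical group
    w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
    w("$Entities")
    w("0 0 2 2")  # no points/curves, 2 surfaces, 2 volumes
    bb <- mesh$bbox
    for (s in c(11L, 12L))
      w("%d %s %s %s %s %s %s 1 %d 0", s, fmt(bb[1, 1]), fmt(bb[1, 2]), fmt(bb[1, 3]),
        fmt(bb[2, 1]), fmt(bb[2, 2]), fmt(bb[2, 3]), s)
    for (v in c(1L, 2L))
      w("%d %s %s %s %s %s %s 1 %d 0", v, fmt(bb[1, 1]), fmt(bb[1, 2]), fmt(bb[1, 3]),
        fmt(bb[2, 1]), fmt(bb[2, 2]), fmt(bb[2, 3]), v)
    w("$EndEntities")
    w("$Nodes")
    w("1 %d 1 %d", N, N)  # one block on volume entity 1
    w("3 1 0 %d", N)
    writeLines(as.character(seq_len(N)), con)
    writeLines(paste(fmt(mesh$nodes[, 1]), fmt(mesh$nodes[, 2]), fmt(mesh$nodes[, 3])), con)
    w("$EndNodes")
    blocks <- list(list(2L, 11L, GMSH_QUAD, inlet),
                   list(2L, 12L, GMSH_QUAD, outlet))
    # hexahedra in original order, split into runs of constant label so the
    # element ordering survives a round trip
    runs <- rle(mesh$label)
    pos <- 1L
    for (r in seq_along(runs$lengths)) {
      idx <- pos:(pos + runs$lengths[r] - 1L)
      blocks[[length(blocks) + 1]] <-
        list(3L, runs$values[r], GMSH_HEX, mesh$elems[idx, , drop = FALSE])
      pos <- pos + runs$lengths[r]
    }
    blocks <- Filter(function(b) nrow(b[[4]]) > 0, blocks)
    ntot <- sum(vapply(blocks, function(b) nrow(b[[4]]), 0L))
    w("$Elements")
    w("%d %d 1 %d", length(blocks), ntot, ntot)
    id <- 1L
    for (b in blocks) {
      m <- b[[4]]
      w("%d %d %d %d", b[[1]], b[[2]], b[[3]], nrow(m))
      writeLines(paste(id:(id + nrow(m) - 1L),
                       apply(m, 1, paste, collapse = " ")), con)
      id <- id + nrow(m)
    }
    w("$EndElements")
  }
  invisible(path)
}

# boundary quads of the mesh whose four nodes all lie in `nodeset`
facesOnNodeSet <- function(mesh, nodeset) {
  bf <- mesh$boundary_faces
  keep <- rowSums(matrix(bf %in% nodeset, nrow(bf), 4)) == 4
  bf[keep, , drop = FALSE]
}

#' Read a Gmsh ASCII mesh (v2.2 or v4.1)
#'
#' Hexahedral volume cells only; element labels are taken from physical groups
#' (1 = host, 2 = tumour) and boundary quads tagged 11/12 define the
#' inlet/outlet faces.
#'
#' @param path a Gmsh \code{.msh} file.
#' @return an \code{angio_mesh}.
#' @export
loadMesh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stopf("empty mesh file: %s", path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1):(i1 - 1)]
  }
  mf <- sect("MeshFormat")
  if (is.null(mf)) stopf("not a Gmsh file (no $MeshFormat): %s", path)
  ver <- strsplit(trimws(mf[1]), "\\s+")[[1]][1]
  if (startsWith(ver, "2")) parseGmsh22(sect) else if (startsWith(ver, "4"))
    parseGmsh41(sect) else stopf("unsupported Gmsh version %s", ver)
}

numTok <- function(line) as.numeric(strsplit(trimws(line), "\\s+")[[1]])

parseGmsh22 <- function(sect) {
  nl <- sect("Nodes")
  if (is.null(nl)) stopf("missing $Nodes section")
  nn <- as.integer(nl[1])
  ntab <- matrix(scan(text = nl[2:(1 + nn)], quiet = TRUE), nn, 4, byrow = TRUE)
  nodes <- ntab[order(ntab[, 1]), 2:4, drop = FALSE]
  if (any(sort(ntab[, 1]) != seq_len(nn)))
    stopf("non-contiguous node numbering not supported")
  el <- sect("Elements")
  if (is.null(el)) stopf("missing $Elements section")
  ne <- as.integer(el[1])
  rows <- lapply(el[2:(1 + ne)], numTok)
  hex <- list(); hexlab <- integer(0)
  inlet <- integer(0); outlet <- integer(0)
  for (r in rows) {
    type <- r[2]; ntags <- r[3]
    phys <- if (ntags >= 1) r[4] else 0
    conn <- r[(4 + ntags):length(r)]
    if (type == GMSH_HEX) {
      if (length(conn) != 8) stopf("hexahedron with %d nodes", length(conn))
      hex[[length(hex) + 1]] <- conn
      hexlab <- c(hexlab, if (phys == 2) 2L else 1L)
    } else if (type == GMSH_QUAD) {
      if (phys == 11) inlet <- c(inlet, conn)
      else if (phys == 12) outlet <- c(outlet, conn)
    } else if (type %in% c(4, 6, 7, 11)) {
      stopf("non-hexahedral volume cell (Gmsh type %d) not supported", type)
    }
  }
  if (!length(hex)) stopf("no hexahedral cells found")
  elems <- do.call(rbind, hex)
  if (!length(inlet) || !length(outlet))
    stopf("missing inlet/outlet physical surface groups (11/12)")
  hexMesh(nodes, elems, hexlab, unique(inlet), unique(outlet))
}

parseGmsh41 <- function(sect) {
  ent <- sect("Entities")
  if (is.null(ent)) stopf("missing $Entities section")
  hdr <- numTok(ent[1])
  np <- hdr[1]; nc <- hdr[2]; ns <- hdr[3]; nv <- hdr[4]
  phys_of <- list(`2` = c(), `3` = c())
  k <- 2 + np + nc
  if (ns > 0) for (i in seq_len(ns)) {
    r <- numTok(ent[k]); k <- k + 1
    nphys <- r[8]
    phys_of[["2"]][as.character(as.integer(r[1]))] <-
      if (nphys >= 1) as.integer(r[9]) else 0L
  }
  if (nv > 0) for (i in seq_len(nv)) {
    r <- numTok(ent[k]); k <- k + 1
    nphys <- r[8]
    phys_of[["3"]][as.character(as.integer(r[1]))] <-
      if (nphys >= 1) as.integer(r[9]) else 0L
  }
  nl <- sect("Nodes")
  if (is.null(nl)) stopf("missing $Nodes section")
  h <- numTok(nl[1])
  nblocks <- h[1]; ntot <- h[2]
  tags <- integer(0); coords <- NULL
  k <- 2
  for (b in seq_len(nblocks)) {
    bh <- numTok(nl[k]); k <- k + 1
    nb <- bh[4]
    if (nb > 0) {
      tg <- as.integer(nl[k:(k + nb - 1)]); k <- k + nb
      cc <- matrix(scan(text = nl[k:(k + nb - 1)], quiet = TRUE), nb, 3, byrow = TRUE)
      k <- k + nb
      tags <- c(tags, tg)
      coords <- rbind(coords, cc)
    }
  }
  nodes <- coords[order(tags), , drop = FALSE]
  if (any(sort(tags) != seq_len(ntot)))
    stopf("non-contiguous node numbering not supported")
  el <- sect("Elements")
  if (is.null(el)) stopf("missing $Elements section")
  h <- numTok(el[1])
  nblocks <- h[1]
  hex <- NULL; hexlab <- integer(0); inlet <- integer(0); outlet <- integer(0)
  k <- 2
  for (b in seq_len(nblocks)) {
    bh <- numTok(el[k]); k <- k + 1
    dim_ <- bh[1]; etag <- as.integer(bh[2]); type <- bh[3]; nb <- bh[4]
    if (nb == 0) next
    rows <- matrix(scan(text = el[k:(k + nb - 1)], quiet = TRUE), nb,
                   byrow = TRUE, ncol = length(numTok(el[k])))
    k <- k + nb
    phys <- phys_of[[as.character(dim_)]][as.character(etag)]
    if (is.na(phys) || is.null(phys)) phys <- 0L
    if (type == GMSH_HEX) {
      hex <- rbind(hex, rows[, 2:9, drop = FALSE])
      hexlab <- c(hexlab, rep(if (phys == 2) 2L else 1L, nb))
    } else if (type == GMSH_QUAD) {
      conn <- as.integer(rows[, 2:5])
      if (phys == 11) inlet <- c(inlet, conn)
      else if (phys == 12) outlet <- c(outlet, conn)
    } else if (dim_ == 3) {
      stopf("non-hexahedral volume cell (Gmsh type %d) not supported", type)
    }
  }
  if (is.null(hex)) stopf("no hexahedral cells found")
  if (!length(inlet) || !length(outlet))
    stopf("missing inlet/outlet physical surface groups (11/12)")
  hexMesh(nodes, hex, hexlab, unique(inlet), unique(outlet))
}
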