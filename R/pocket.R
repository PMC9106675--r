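#' Pocket detection configuration
#'
#' Tunable parameters of the descriptor engine. Defaults are the package's
#' operating point; every quantity is in Angstrom unless dimensionless.
#'
#' @param grid_spacing lattice spacing of candidate site points (1.0).
#' @param region_margin margin beyond the seed ligand's bounding box that
#'   defines the single binding region (6.0).
#' @param probe_radius solvent probe radius added to atomic van der Waals
#'   radii when excluding grid points inside the protein (1.4).
#' @param ray_count number of fixed ray directions used for enclosure;
#'   one of 12, 42, 162, 642 (icosphere vertex counts; default 162).
#' @param ray_length maximum distance a ray travels before the direction
#'   counts as open (10.0).
#' @param enclosure_threshold minimum enclosure fraction for a grid point
#'   to qualify as a site point (0.5).
#' @param min_site_points minimum site-point count below which the site is
#'   reported as not detected (5).
#' @param contact_cutoff distance from site points within which protein
#'   atoms count as pocket-lining contacts (4.0).
#' @param k_p calibration constant mapping the polar-contact ratio onto the
#'   hydrophilicity factor scale (1.6).
#' @return object of class `pocket_config`.
#' @export
pocket_config <- function(grid_spacing = 1.0, region_margin = 6.0,
                          probe_radius = 1.4, ray_count = 162,
                          ray_length = 10.0, enclosure_threshold = 0.5,
                          min_site_points = 5, contact_cutoff = 4.0,
                          k_p = 1.6) {
  stopifnot(
    grid_spacing > 0, region_margin >= 0, probe_radius >= 0,
    ray_length > 0, enclosure_threshold > 0, enclosure_threshold < 1,
    min_site_points >= 1, contact_cutoff > 0, k_p > 0
  )
  if (!ray_count %in% c(12, 42, 162, 642)) {
    .err("ppidrugg_invalid", "ray_count must be one of 12, 42, 162, 642")
  }
  structure(
    list(
      grid_spacing = grid_spacing, region_margin = region_margin,
      probe_radius = probe_radius, ray_count = ray_count,
      ray_length = ray_length, enclosure_threshold = enclosure_threshold,
      min_site_points = min_site_points, contact_cutoff = contact_cutoff,
      k_p = k_p
    ),
    class = "pocket_config"
  )
}

#' Deterministic quasi-uniform ray directions
#'
#' Unit vectors at the vertices of a subdivided icosahedron (12, 42, 162 or
#' 642 directions), sorted lexicographically so the set is identical on
#' every call and platform.
#'
#' @param n number of directions (12, 42, 162, 642).
#' @return n x 3 matrix of unit vectors.
#' @export
icosphere_directions <- function(n = 162) {
  levels <- c("12" = 0, "42" = 1, "162" = 2, "642" = 3)
  lv <- levels[as.character(n)]
  if (is.na(lv)) .err("ppidrugg_invalid", "n must be one of 12, 42, 162, 642")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(lv)) {
    key <- function(p) paste(round(p, 9), collapse = ",")
    verts <- v
    lookup <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(verts))) assign(key(verts[i, ]), i, envir = lookup)
    midpoint <- function(i, j) {
      m <- verts[i, ] + verts[j, ]
      m <- m / sqrt(sum(m^2))
      k <- key(m)
      idx <- mget(k, envir = lookup, ifnotfound = NA)[[1]]
      if (is.na(idx)) {
        verts <<- rbind(verts, m)
        idx <- nrow(verts)
        assign(k, idx, envir = lookup)
      }
      idx
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    r <- 0L
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[r + 1L, ] <- c(a, ab, ca); nf[r + 2L, ] <- c(b, bc, ab)
      nf[r + 3L, ] <- c(cc, ca, bc); nf[r + 4L, ] <- c(ab, bc, ca)
      r <- r + 4L
    }
    v <- verts; f <- nf
  }
  v <- round(v, 12)
  v <- v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
  dimnames(v) <- NULL
  v
}

#' Candidate grid points of the single binding region
#'
#' Axis-aligned lattice at `grid_spacing`, anchored at the ligand centroid
#' (so descriptors do not depend on the deposition frame) and covering the
#' ligand bounding box expanded by `region_margin`. Points lying within any
#' protein heavy atom's van der Waals radius plus `probe_radius` are
#' removed. May return an empty set.
#'
#' @param structure a `ppi_structure` (protein atoms only are considered).
#' @param ligand a `ppi_ligand` with at least one heavy atom.
#' @param config a [pocket_config()].
#' @return k x 3 matrix of grid points.
#' @export
candidate_grid <- function(structure, ligand, config = pocket_config()) {
  lig <- .xyz(ligand)
  anchor <- ligand$centroid
  sp <- config$grid_spacing
  ax <- lapply(1:3, function(k) {
    lo <- min(lig[, k]) - config$region_margin
    hi <- max(lig[, k]) + config$region_margin
    anchor[k] + sp * (ceiling((lo - anchor[k]) / sp - 1e-9):floor((hi - anchor[k]) / sp + 1e-9))
  })
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  dimnames(pts) <- NULL
  prot <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  if (!nrow(prot) || !nrow(pts)) return(pts)
  axyz <- as.matrix(prot[, c("x", "y", "z")])
  rad <- vdw_radius(prot$element) + config$probe_radius
  keep <- rep(TRUE, nrow(pts))
  # chunk over atoms to bound memory on large structures
  idx <- split(seq_len(nrow(axyz)), ceiling(seq_len(nrow(axyz)) / 512))
  for (ii in idx) {
    d <- .cross_dist(pts[keep, , drop = FALSE], axyz[ii, , drop = FALSE])
    inside <- d < rep(rad[ii], each = sum(keep))
    keep[keep] <- !matrixStats_rowAnys(inside)
    if (!any(keep)) break
  }
  pts[keep, , drop = FALSE]
}

# rowAnys without a matrixStats dependency
matrixStats_rowAnys <- function(m) rowSums(m) > 0

# enclosure fractions for many points at once
.enclosure_many <- function(points, structure, config) {
  if (!nrow(points)) return(numeric(0))
  dirs <- icosphere_directions(config$ray_count)
  prot <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  if (!nrow(prot)) return(rep(0, nrow(points)))
  axyz <- as.matrix(prot[, c("x", "y", "z")])
  rad <- vdw_radius(prot$element)
  reach <- config$ray_length + max(rad)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    rel <- sweep(axyz, 2, points[i, ]) # m x 3, point -> atom
    d2 <- rowSums(rel^2)
    near <- d2 <= reach^2
    if (!any(near)) next
    reln <- rel[near, , drop = FALSE]
    r2 <- rad[near]^2
    tpar <- reln %*% t(dirs) # m x ndir distances along each ray
    perp2 <- d2[near] - tpar^2
    hit <- perp2 <= r2 & tpar > 0
    if (any(hit)) {
      tentry <- tpar - sqrt(pmax(r2 - perp2, 0))
      hit <- hit & tentry <= config$ray_length
    }
    out[i] <- mean(colSums(hit) > 0)
  }
  out
}

#' Enclosure fraction at a point
#'
#' Fraction of the fixed quasi-uniform ray directions along which a protein
#' heavy atom's van der Waals sphere is intersected within `ray_length`.
#' 0 means fully open (no atom within reach), 1 fully buried.
#'
#' @param point numeric 3-vector, not inside any atom.
#' @param structure a `ppi_structure`.
#' @param config a [pocket_config()].
#' @return fraction in \[0, 1\].
#' @export
enclosure_at <- function(point, structure, config = pocket_config()) {
  .enclosure_many(matrix(point, nrow = 1), structure, config)
}

#' Detect the ligand-seeded binding site and compute its descriptors
#'
#' Site points are candidate grid points (see [candidate_grid()]) whose
#' enclosure is at least `enclosure_threshold`, clustered by 26-neighbour
#' grid connectivity; the connected component closest to the ligand
#' centroid is the site (ties: larger component, then lexicographic grid
#' order). Descriptors: `n` is the component's cardinality, `e` the mean
#' enclosure over its points, and `p = k_p * (polar-weighted contact
#' density / total contact density)` where contacts are protein heavy atoms
#' within `contact_cutoff` of site points, polar atoms are N and O, and
#' charged side-chain N/O count double. When fewer than `min_site_points`
#' points survive, the site is reported as not detected (the ND state a
#' flat, ZipA-like interface produces).
#'
#' @param structure a prepared single-chain `ppi_structure`.
#' @param ligand the posed or co-crystallised `ppi_ligand` seeding the
#'   region.
#' @param config a [pocket_config()].
#' @return object of class `site_descriptors`: fields `detected`, `n`,
#'   `e`, `p`, plus the site-point coordinates and per-point enclosures.
#' @export
detect_site <- function(structure, ligand, config = pocket_config()) {
  grid <- candidate_grid(structure, ligand, config)
  if (!nrow(grid)) return(.nd_site(config))
  encl <- .enclosure_many(grid, structure, config)
  ok <- encl >= config$enclosure_threshold
  if (!any(ok)) return(.nd_site(config))
  pts <- grid[ok, , drop = FALSE]
  pe <- encl[ok]
  comp <- .grid_components(pts, ligand$centroid, config$grid_spacing)
  pick <- .pick_component(pts, comp, ligand$centroid)
  sel <- comp == pick
  n <- sum(sel)
  if (n < config$min_site_points) return(.nd_site(config))
  site <- pts[sel, , drop = FALSE]
  e <- mean(pe[sel])
  p <- .hydrophilicity(site, structure, config)
  structure(
    list(
      detected = TRUE, n = n, e = e, p = p,
      site_points = site, enclosure = pe[sel], config = config
    ),
    class = "site_descriptors"
  )
}

.nd_site <- function(config) {
  structure(
    list(
      detected = FALSE, n = NA_integer_, e = NA_real_, p = NA_real_,
      site_points = matrix(numeric(0), ncol = 3), enclosure = numeric(0),
      config = config
    ),
    class = "site_descriptors"
  )
}

#' @export
print.site_descriptors <- function(x, ...) {
  if (!x$detected) {
    cat("<site_descriptors> ND (no site detected)\n")
  } else {
    cat(sprintf(
      "<site_descriptors> n = %d site points, e = %.3f, p = %.3f (Dscore %.3f)\n",
      x$n, x$e, x$p, dscore(x$n, x$e, x$p)
    ))
  }
  invisible(x)
}

# 26-connectivity components on the integer lattice
.grid_components <- function(pts, anchor, spacing) {
  ijk <- round(sweep(pts, 2, anchor) / spacing)
  keys <- paste(ijk[, 1], ijk[, 2], ijk[, 3])
  index <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ijk))) assign(keys[i], i, envir = index)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  comp <- integer(nrow(ijk))
  cur <- 0L
  for (i in seq_len(nrow(ijk))) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- sweep(off, 2, as.numeric(ijk[v, ]), "+")
      nbk <- paste(nb[, 1], nb[, 2], nb[, 3])
      hits <- unlist(mget(nbk, envir = index, ifnotfound = NA), use.names = FALSE)
      hits <- hits[!is.na(hits)]
      new <- hits[comp[hits] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

# component closest to the ligand centroid; ties -> larger, then
# lexicographic order of the component's first grid point
.pick_component <- function(pts, comp, centroid) {
  ids <- sort(unique(comp))
  d <- vapply(ids, function(k) {
    m <- pts[comp == k, , drop = FALSE]
    min(sqrt(rowSums(sweep(m, 2, centroid)^2)))
  }, numeric(1))
  size <- vapply(ids, function(k) sum(comp == k), numeric(1))
  ord <- order(round(d, 9), -size, ids)
  ids[ord[1]]
}

.CHARGED_SC <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2")
)

.hydrophilicity <- function(site, structure, config) {
  prot <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  axyz <- as.matrix(prot[, c("x", "y", "z")])
  dmin <- apply(.cross_dist(axyz, site), 1, min)
  contact <- dmin <= config$contact_cutoff
  if (!any(contact)) return(0)
  ca <- prot[contact, , drop = FALSE]
  polar <- ca$element %in% c("N", "O")
  charged <- mapply(function(rn, an) {
    an %in% (.CHARGED_SC[[rn]] %||% character(0))
  }, ca$resname, ca$name)
  w <- ifelse(polar & charged, 2, ifelse(polar, 1, 0))
  config$k_p * sum(w) / nrow(ca)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
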