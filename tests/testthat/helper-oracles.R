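# Independent oracles, written against the contracts rather than the
# implementation: exhaustive alignment enumeration, plain-loop descriptor
# recomputation, and Monte-Carlo enclosure.

# Maximum global-alignment score by enumerating every alignment path
# (gap of length k costs open + k * ext).
brute_align_score <- function(a, b, S = substitution_matrix(),
                              open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, state, score) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1, j + 1, "M", score + S[A[i], B[j]])
    }
    if (j <= length(B)) {
      rec(i, j + 1, "Ix", score - ext - if (identical(state, "Ix")) 0 else open)
    }
    if (i <= length(A)) {
      rec(i + 1, j, "Iy", score - ext - if (identical(state, "Iy")) 0 else open)
    }
  }
  rec(1L, 1L, "start", 0)
  best
}

# random rotation matrix (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Plain-loop recomputation of the site descriptors from the stated
# definitions: lattice over the ligand box, per-point/per-direction ray
# test, distance-threshold clustering, contact counting.
oracle_site <- function(structure, ligand, config) {
  lig <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  anchor <- colMeans(lig)
  sp <- config$grid_spacing
  ax <- lapply(1:3, function(k) {
    lo <- min(lig[, k]) - config$region_margin
    hi <- max(lig[, k]) + config$region_margin
    anchor[k] + sp * (ceiling((lo - anchor[k]) / sp - 1e-9):floor((hi - anchor[k]) / sp + 1e-9))
  })
  prot <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  axyz <- as.matrix(prot[, c("x", "y", "z")])
  rad <- vdw_radius(prot$element)
  pts <- list()
  for (x in ax[[1]]) for (y in ax[[2]]) for (z in ax[[3]]) {
    d <- sqrt((axyz[, 1] - x)^2 + (axyz[, 2] - y)^2 + (axyz[, 3] - z)^2)
    if (all(d >= rad + config$probe_radius)) pts[[length(pts) + 1]] <- c(x, y, z)
  }
  if (!length(pts)) return(list(detected = FALSE))
  pts <- do.call(rbind, pts)
  dirs <- icosphere_directions(config$ray_count)
  encl <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    blocked <- 0
    for (k in seq_len(nrow(dirs))) {
      rel <- sweep(axyz, 2, pts[i, ])
      tpar <- rel %*% dirs[k, ]
      perp2 <- rowSums(rel^2) - tpar^2
      hit <- perp2 <= rad^2 & tpar > 0 &
        (tpar - sqrt(pmax(rad^2 - perp2, 0))) <= config$ray_length
      if (any(hit)) blocked <- blocked + 1
    }
    encl[i] <- blocked / nrow(dirs)
  }
  keep <- encl >= config$enclosure_threshold
  if (!any(keep)) return(list(detected = FALSE))
  pts <- pts[keep, , drop = FALSE]
  encl <- encl[keep]
  # single-linkage components: neighbours within one diagonal lattice step
  np <- nrow(pts)
  comp <- seq_len(np)
  repeat {
    changed <- FALSE
    for (i in seq_len(np)) for (j in seq_len(np)) {
      if (comp[i] != comp[j] &&
        sqrt(sum((pts[i, ] - pts[j, ])^2)) <= sp * sqrt(3) + 1e-9) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  cen <- ligand$centroid
  ids <- unique(comp)
  dmin <- sapply(ids, function(k) {
    min(sqrt(rowSums(sweep(pts[comp == k, , drop = FALSE], 2, cen)^2)))
  })
  size <- sapply(ids, function(k) sum(comp == k))
  ord <- order(round(dmin, 9), -size, ids)
  sel <- comp == ids[ord[1]]
  if (sum(sel) < config$min_site_points) return(list(detected = FALSE))
  site <- pts[sel, , drop = FALSE]
  dmin_atoms <- sapply(seq_len(nrow(axyz)), function(i) {
    min(sqrt(rowSums(sweep(site, 2, axyz[i, ])^2)))
  })
  contact <- dmin_atoms <= config$contact_cutoff
  w <- 0
  for (i in which(contact)) {
    el <- prot$element[i]
    if (el %in% c("N", "O")) {
      charged <- switch(prot$resname[i],
        ARG = prot$name[i] %in% c("NE", "NH1", "NH2"),
        LYS = prot$name[i] == "NZ",
        ASP = prot$name[i] %in% c("OD1", "OD2"),
        GLU = prot$name[i] %in% c("OE1", "OE2"),
        HIS = prot$name[i] %in% c("ND1", "NE2"),
        FALSE
      )
      w <- w + if (charged) 2 else 1
    }
  }
  list(
    detected = TRUE, n = sum(sel), e = mean(encl[sel]),
    p = config$k_p * w / sum(contact)
  )
}

# Monte-Carlo enclosure at a point: random directions instead of the fixed
# icosphere set.
mc_enclosure <- function(point, structure, config, n_rays = 1e5) {
  prot <- structure$atoms[!structure$atoms$het, , drop = FALSE]
  axyz <- as.matrix(prot[, c("x", "y", "z")])
  rad <- vdw_radius(prot$element)
  rel <- sweep(axyz, 2, point)
  d2 <- rowSums(rel^2)
  near <- d2 <= (config$ray_length + max(rad))^2
  rel <- rel[near, , drop = FALSE]
  r2 <- rad[near]^2
  d2 <- d2[near]
  blocked <- 0L
  done <- 0L
  while (done < n_rays) {
    nb <- min(5000L, n_rays - done)
    g <- matrix(rnorm(3 * nb), nb, 3)
    g <- g / sqrt(rowSums(g^2))
    tpar <- rel %*% t(g)
    perp2 <- d2 - tpar^2
    hit <- perp2 <= r2 & tpar > 0
    hit[hit] <- (tpar[hit] - sqrt(pmax(r2[row(hit)[hit]] - perp2[hit], 0))) <= config$ray_length
    blocked <- blocked + sum(colSums(hit) > 0)
    done <- done + nb
  }
  blocked / n_rays
}
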