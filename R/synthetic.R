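# Run code under a seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic cavity structure
#'
#' Parameters of the pseudo-protein fixtures: a slab of atoms on a cubic
#' lattice with a spherical pocket carved into its top face. `radius` is
#' the accessible cavity radius in Angstrom (atom centres are removed
#' within `radius` plus the carbon van der Waals radius, so the van der
#' Waals surface of the wall sits near `radius`); `depth` is how far the
#' void extends below the surface (0 = flat, ZipA-like slab); lining atoms
#' become polar (alternating N/O) at `polar_fraction`; `rim_height` adds
#' rings of occluding atoms around the mouth. Output is a pure function of
#' the spec (including `seed`).
#'
#' @param radius accessible cavity radius, Angstrom (> 0).
#' @param depth cavity depth below the surface, Angstrom (>= 0; 0 = flat).
#' @param polar_fraction fraction of lining atoms assigned polar elements.
#' @param rim_height height of the occluding rim above the surface (>= 0).
#' @param lattice_spacing slab lattice constant, Angstrom.
#' @param seed integer seed driving all randomness.
#' @param slab_halfwidth,slab_depth slab half-extent in x/y and extent in
#'   z; `NULL` (default) sizes the slab to enclose the cavity and the
#'   enclosure ray length.
#' @return object of class `cavity_spec`.
#' @export
cavity_spec <- function(radius = 4, depth = 4, polar_fraction = 0,
                        rim_height = 0, lattice_spacing = 1.8, seed = 1,
                        slab_halfwidth = NULL, slab_depth = NULL) {
  stopifnot(
    radius > 0, depth >= 0, polar_fraction >= 0, polar_fraction <= 1,
    rim_height >= 0, lattice_spacing > 0
  )
  carve <- radius + .bondi[["C"]]
  if (is.null(slab_halfwidth)) slab_halfwidth <- carve + 11
  if (is.null(slab_depth)) slab_depth <- depth + .bondi[["C"]] + 5.5
  if (carve >= slab_halfwidth || (depth > 0 && depth + .bondi[["C"]] >= slab_depth)) {
    .err("ppidrugg_invalid", "cavity larger than slab")
  }
  structure(list(
    radius = radius, depth = depth, polar_fraction = polar_fraction,
    rim_height = rim_height, lattice_spacing = lattice_spacing,
    seed = seed, slab_halfwidth = slab_halfwidth, slab_depth = slab_depth
  ), class = "cavity_spec")
}

# lattice coordinates of the full (uncarved) slab, deterministic order
.slab_lattice <- function(spec) {
  s <- spec$lattice_spacing
  xs <- s * (-floor(spec$slab_halfwidth / s):floor(spec$slab_halfwidth / s))
  zs <- -s * (0:floor(spec$slab_depth / s))
  g <- expand.grid(x = xs, y = xs, z = zs)
  g[order(g$z, g$y, g$x, decreasing = c(TRUE, FALSE, FALSE), method = "radix"), ]
}

.carve_center <- function(spec) c(0, 0, spec$radius - spec$depth)

#' Generate a pseudo-protein slab with a carved cavity
#'
#' Builds the structure described by a [cavity_spec()]: every slab atom is
#' its own glycine-like residue with atom name `CA` (so the superposition
#' machinery applies unchanged) and carries a real element symbol with its
#' Bondi radius, so the descriptor engine treats fixtures and real PDB
#' structures identically. A probe ligand (`LIG`, 6 heavy atoms) is placed
#' at the cavity centre (or laid on the surface for a flat slab). The
#' attached manifest records the cavity centre and the lining/polar atom
#' rosters, sufficient to recompute every downstream expected value
#' independently.
#'
#' @param spec a [cavity_spec()].
#' @return list with `structure` (`ppi_structure`), `ligand`
#'   (`ppi_ligand`) and `manifest`.
#' @export
make_cavity_structure <- function(spec) {
  stopifnot(inherits(spec, "cavity_spec"))
  g <- .slab_lattice(spec)
  ctr <- .carve_center(spec)
  d_ctr <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  carve_r <- spec$radius + .bondi[["C"]]
  # sphere at the bottom plus, when the cavity is deeper than its radius,
  # a cylindrical shaft up to the surface: deepening then strictly grows
  # the carved region (nested wells), and depth = radius is a hemisphere
  shaft <- g$z >= ctr[3] & g$z <= 0 & sqrt(g$x^2 + g$y^2) < carve_r
  carved <- spec$depth > 0 & (d_ctr < carve_r | shaft)
  kept <- g[!carved, , drop = FALSE]
  removed <- g[carved, , drop = FALSE]
  n <- nrow(kept)
  elem <- rep("C", n)
  lining <- which(sqrt((kept$x - ctr[1])^2 + (kept$y - ctr[2])^2 +
    (kept$z - ctr[3])^2) < carve_r + 1.2 * spec$lattice_spacing)
  polar <- integer(0)
  if (spec$depth > 0 && spec$polar_fraction > 0 && length(lining)) {
    roster <- .with_seed(spec$seed, sample(lining))
    k <- round(spec$polar_fraction * length(lining))
    polar <- roster[seq_len(k)]
    elem[polar] <- rep(c("N", "O"), length.out = k)
  }
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = elem, resname = "GLY",
    chain = "A", resno = seq_len(n), insert = "",
    x = kept$x, y = kept$y, z = kept$z, het = FALSE,
    stringsAsFactors = FALSE
  )
  if (spec$rim_height > 0 && spec$depth > 0) {
    atoms <- rbind(atoms, .rim_atoms(spec, start_serial = n + 1))
  }
  # fixed shallow position inside the void: keeps the grid anchor (the
  # ligand centroid) identical across cavity depths, so descriptor
  # comparisons along a depth series are not confounded by lattice phase
  lig_center <- if (spec$depth > 0) c(0, 0, -min(spec$depth, 2) / 2) else c(0, 0, 2.6)
  lig <- .probe_ligand(lig_center, start_serial = nrow(atoms) + 1)
  structure_out <- ppi_structure(rbind(atoms, lig))
  list(
    structure = structure_out,
    ligand = extract_ligand(structure_out, "LIG"),
    manifest = list(
      spec = spec, cavity_center = lig_center, carve_center = ctr,
      n_protein_atoms = nrow(atoms), n_removed = nrow(removed),
      removed_sites = as.matrix(removed[order(removed$z, removed$y, removed$x), , drop = FALSE]),
      lining_resno = atoms$resno[lining], polar_resno = atoms$resno[polar]
    )
  )
}

# occluding rings around the cavity mouth
.rim_atoms <- function(spec, start_serial) {
  s <- spec$lattice_spacing
  r_ring <- spec$radius + .bondi[["C"]] + 0.5
  zs <- s * seq_len(ceiling(spec$rim_height / s))
  zs <- zs[zs <= spec$rim_height + 1e-9]
  if (!length(zs)) return(NULL)
  n_ang <- max(8, ceiling(2 * pi * r_ring / s))
  ang <- 2 * pi * (seq_len(n_ang) - 1) / n_ang
  pts <- do.call(rbind, lapply(zs, function(z) {
    cbind(r_ring * cos(ang), r_ring * sin(ang), z)
  }))
  n <- nrow(pts)
  data.frame(
    serial = start_serial - 1 + seq_len(n), name = "CA", element = "C",
    resname = "GLY", chain = "A",
    resno = start_serial - 1 + seq_len(n), insert = "",
    x = pts[, 1], y = pts[, 2], z = pts[, 3], het = FALSE,
    stringsAsFactors = FALSE
  )
}

# 6-atom octahedral probe ligand
.probe_ligand <- function(center, start_serial) {
  off <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
  )
  data.frame(
    serial = start_serial - 1 + 1:6, name = paste0("C", 1:6), element = "C",
    resname = "LIG", chain = "A", resno = 9000, insert = "",
    x = center[1] + off[, 1], y = center[2] + off[, 2], z = center[3] + off[, 3],
    het = TRUE, stringsAsFactors = FALSE
  )
}

#' Generate an apo/holo pair sharing one scaffold
#'
#' The holo member carries the full cavity (and the probe ligand); the apo
#' member is the same structure with the cavity partially refilled:
#' `closure` of the carved lattice sites (deepest first) are re-occupied
#' by relocating the nearest lining atoms into them. Residue rosters and
#' sequences are identical, so [superpose_on_reference()] applies
#' directly. `closure = 0` reproduces the holo coordinates; `closure = 1`
#' restores the uncarved slab, whose interface is flat and yields ND —
#' the apo-collapse contrast seen for Bcl-xL and IL-2.
#'
#' @param spec a [cavity_spec()] with `depth > 0`.
#' @param closure fraction of the cavity to close, in \[0, 1\].
#' @return list with `holo` (structure + ligand), `apo` (structure) and
#'   `manifest`.
#' @export
make_apo_holo_pair <- function(spec, closure) {
  if (!is.numeric(closure) || closure < 0 || closure > 1) {
    .err("ppidrugg_invalid", "closure must be in [0, 1]")
  }
  if (spec$depth <= 0) .err("ppidrugg_invalid", "apo/holo pair needs a cavity (depth > 0)")
  holo <- make_cavity_structure(spec)
  removed <- holo$manifest$removed_sites
  k <- round(closure * nrow(removed))
  apo_atoms <- holo$structure$atoms
  apo_atoms <- apo_atoms[!apo_atoms$het, , drop = FALSE]
  moved <- integer(0)
  if (k > 0) {
    ctr <- holo$manifest$carve_center
    pool <- order(sqrt((apo_atoms$x - ctr[1])^2 + (apo_atoms$y - ctr[2])^2 +
      (apo_atoms$z - ctr[3])^2))
    used <- logical(nrow(apo_atoms))
    for (i in seq_len(k)) {
      site <- removed[i, ]
      cand <- pool[!used[pool]]
      d <- sqrt((apo_atoms$x[cand] - site[1])^2 + (apo_atoms$y[cand] - site[2])^2 +
        (apo_atoms$z[cand] - site[3])^2)
      pick <- cand[which.min(d)]
      apo_atoms$x[pick] <- site[1]
      apo_atoms$y[pick] <- site[2]
      apo_atoms$z[pick] <- site[3]
      used[pick] <- TRUE
      moved <- c(moved, pick)
    }
  }
  list(
    holo = list(structure = holo$structure, ligand = holo$ligand),
    apo = ppi_structure(apo_atoms),
    manifest = c(holo$manifest, list(
      closure = closure, n_filled = k, moved_resno = apo_atoms$resno[moved]
    ))
  )
}

#' Specification of a per-target descriptor distribution
#'
#' Describes how to draw per-structure descriptor rows for one target:
#' pocket size `n` from a discretised log-normal (strictly positive,
#' right-skewed), enclosure `e` and hydrophilicity `p` from normals
#' clipped to \[0, 1\] and \[0, Inf). Medians are the location parameters,
#' so the generated distribution's median equals the configured one.
#'
#' @param target target label.
#' @param forms data.frame with columns `form`, `n_structures`,
#'   `median_n`, `sdlog_n`, `median_e`, `sd_e`, `median_p`, `sd_p`.
#' @param seed integer seed.
#' @param sampling `"quantile"` (default) draws at evenly spaced
#'   quantiles with a seeded random pairing across the three descriptors,
#'   making the sample median faithful to the configured median even at
#'   small counts; `"iid"` draws independently.
#' @return object of class `target_distribution_spec`.
#' @export
target_distribution_spec <- function(target, forms, seed = 1,
                                     sampling = c("quantile", "iid")) {
  need <- c("form", "n_structures", "median_n", "sdlog_n", "median_e", "sd_e",
    "median_p", "sd_p")
  miss <- setdiff(need, names(forms))
  if (length(miss)) .err("ppidrugg_invalid", paste("forms is missing:", paste(miss, collapse = ", ")))
  structure(list(
    target = target, forms = forms, seed = seed,
    sampling = match.arg(sampling)
  ), class = "target_distribution_spec")
}

#' Draw a synthetic per-structure descriptor table
#'
#' @param spec a [target_distribution_spec()].
#' @return data.frame with columns `structure_id`, `target`, `form`, `n`,
#'   `e`, `p`, `detected` (always `TRUE`; ND targets are represented by
#'   flat-slab structures, not by this generator).
#' @export
make_descriptor_table <- function(spec) {
  stopifnot(inherits(spec, "target_distribution_spec"))
  .with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(spec$forms)), function(i) {
      f <- spec$forms[i, ]
      N <- f$n_structures
      if (is.na(N) || N < 1) return(NULL)
      if (spec$sampling == "quantile") {
        # stratified quantile draws; ranks are shared between n and e and
        # reversed for p, mirroring the observed coupling of the three
        # descriptors with druggability (large, enclosed pockets tend to
        # be the less hydrophilic ones), so the per-structure score median
        # stays faithful to the configured descriptor medians
        u <- (seq_len(N) - 0.5) / N
        perm <- sample(N)
        un <- u[perm]; ue <- u[perm]; up <- 1 - u[perm]
      } else {
        un <- runif(N); ue <- runif(N); up <- runif(N)
      }
      data.frame(
        structure_id = sprintf("%s_%s_%02d", gsub("[^A-Za-z0-9]", "", spec$target), f$form, seq_len(N)),
        target = spec$target, form = f$form,
        n = pmax(1, round(qlnorm(un, log(f$median_n), f$sdlog_n))),
        e = pmin(1, pmax(0, qnorm(ue, f$median_e, f$sd_e))),
        p = pmax(0, qnorm(up, f$median_p, f$sd_p)),
        detected = TRUE, stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Emulate the full 12-target reference dataset
#'
#' Builds per-target descriptor tables whose configured medians are the
#' published per-target medians ([reference_targets()]), with spreads
#' derived from the published ranges (range/4 on the appropriate scale)
#' and structure counts from the published per-form breakdown. The
#' flat-interface target (ZipA) is emitted as ND records. Druggability
#' scores and classes are appended per record.
#'
#' @param seed integer seed.
#' @param sampling passed to [target_distribution_spec()].
#' @return data.frame of druggability records for all twelve targets.
#' @export
emulate_reference_dataset <- function(seed = 1, sampling = "quantile") {
  ref <- reference_targets()
  forms <- reference_form_medians()
  out <- list()
  for (i in seq_len(nrow(ref))) {
    r <- ref[i, ]
    fsub <- forms[forms$target == r$target & !is.na(forms$n_structures), , drop = FALSE]
    if (is.na(r$median_dscore)) { # flat-interface target: every structure ND
      nd <- do.call(rbind, lapply(seq_len(nrow(fsub)), function(j) {
        data.frame(
          structure_id = sprintf("%s_%s_%02d", gsub("[^A-Za-z0-9]", "", r$target),
            fsub$form[j], seq_len(fsub$n_structures[j])),
          target = r$target, form = fsub$form[j],
          n = NA_real_, e = NA_real_, p = NA_real_, detected = FALSE,
          stringsAsFactors = FALSE
        )
      }))
      out[[i]] <- nd
      next
    }
    fspec <- data.frame(
      form = fsub$form, n_structures = fsub$n_structures,
      median_n = r$median_n, sdlog_n = log(r$n_max / r$n_min) / 4,
      median_e = r$median_e, sd_e = (r$e_max - r$e_min) / 4,
      median_p = r$median_p, sd_p = (r$p_max - r$p_min) / 4,
      stringsAsFactors = FALSE
    )
    out[[i]] <- make_descriptor_table(
      target_distribution_spec(r$target, fspec, seed = seed + i, sampling = sampling)
    )
  }
  rec <- do.call(rbind, out)
  rec$dscore <- ifelse(rec$detected, dscore(rec$n, rec$e, rec$p), NA_real_)
  rec$ppi_class <- classify_ppi(rec$dscore)
  rec$halgren_class <- classify_halgren(rec$dscore)
  rownames(rec) <- NULL
  rec
}

#' Generate a molecular property table with planted Lipinski violations
#'
#' Draws `n_mol` molecules whose Lipinski violation counts follow
#' `violation_profile`; which of the four rules are broken is chosen at
#' random per molecule. The returned table carries a `manifest` attribute
#' recording the planted violation count per molecule — the independent
#' bookkeeping oracle for audits.
#'
#' @param n_mol number of molecules.
#' @param violation_profile numeric vector of length 5 giving the fraction
#'   of molecules with exactly 0-4 violations (normalised to sum to 1).
#' @param seed integer seed.
#' @return data.frame with the eight descriptor columns plus `id`;
#'   attribute `manifest` holds the planted counts.
#' @export
make_property_table <- function(n_mol, violation_profile = c(1, 0, 0, 0, 0),
                                seed = 1) {
  if (length(violation_profile) != 5 || any(violation_profile < 0) ||
    sum(violation_profile) <= 0) {
    .err("ppidrugg_invalid", "violation_profile must be 5 non-negative fractions")
  }
  prob <- violation_profile / sum(violation_profile)
  counts <- floor(prob * n_mol)
  rem <- n_mol - sum(counts)
  if (rem > 0) { # largest remainders get the leftover molecules
    frac <- prob * n_mol - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  planted <- rep(0:4, times = counts)
  .with_seed(seed, {
    planted <- sample(planted)
    rules <- c("mwt", "logp", "hbd", "hba")
    props <- data.frame(
      id = sprintf("mol%03d", seq_len(n_mol)),
      mwt = runif(n_mol, 250, 480),
      hbd = sample(0:4, n_mol, replace = TRUE),
      hba = sample(2:8, n_mol, replace = TRUE),
      logp = runif(n_mol, 0.5, 4.5),
      psa = runif(n_mol, 40, 120),
      rotb = sample(2:9, n_mol, replace = TRUE),
      arom_rings = sample(1:4, n_mol, replace = TRUE),
      alerts = sample(0:1, n_mol, replace = TRUE, prob = c(0.8, 0.2)),
      stringsAsFactors = FALSE
    )
    for (i in seq_len(n_mol)) {
      if (planted[i] == 0) next
      broken <- sample(rules, planted[i])
      if ("mwt" %in% broken) props$mwt[i] <- runif(1, 520, 900)
      if ("logp" %in% broken) props$logp[i] <- runif(1, 5.5, 8)
      if ("hbd" %in% broken) props$hbd[i] <- sample(6:9, 1)
      if ("hba" %in% broken) props$hba[i] <- sample(11:14, 1)
    }
    attr(props, "manifest") <- data.frame(id = props$id, planted_violations = planted)
    props
  })
}
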