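test_that("candidate grid over empty space counts lattice points exactly", {
  lig <- ppi_ligand(atom_df(x = 0, y = 0, z = 0, resname = "LIG", het = TRUE, name = "C1"))
  empty <- ppi_structure(atom_df(x = numeric(0), y = numeric(0), z = numeric(0)))
  cfg <- pocket_config(region_margin = 2, grid_spacing = 1)
  g <- candidate_grid(empty, lig, cfg)
  expect_equal(nrow(g), 125) # 5^3
  # adding one carbon at the origin removes points within 1.7 + 1.4
  one <- ppi_structure(atom_df(x = 0, y = 0, z = 0))
  g2 <- candidate_grid(one, lig, cfg)
  d <- sqrt(rowSums(g^2))
  expect_equal(nrow(g2), sum(d >= 1.7 + 1.4)) # brute-force distance scan
  expect_true(all(sqrt(rowSums(g2^2)) >= 1.7 + 1.4))
})

test_that("enclosure is 0 in empty space and 1 inside a closed shell", {
  cfg <- pocket_config()
  lone <- ppi_structure(atom_df(x = 100, y = 100, z = 100))
  expect_equal(enclosure_at(c(0, 0, 0), lone, cfg), 0)
  # dense spherical shell of carbons, radius 5 (Fibonacci points)
  n <- 500
  i <- seq_len(n)
  phi <- acos(1 - 2 * (i - 0.5) / n)
  th <- pi * (1 + sqrt(5)) * i
  shell <- ppi_structure(atom_df(
    x = 5 * sin(phi) * cos(th), y = 5 * sin(phi) * sin(th), z = 5 * cos(phi)
  ))
  expect_equal(enclosure_at(c(0, 0, 0), shell, cfg), 1)
})

test_that("enclosure above a flat slab matches a Monte-Carlo oracle and stays sub-threshold", {
  flat <- make_cavity_structure(small_cavity_spec(depth = 0))
  cfg <- pocket_config()
  pt <- c(0, 0, 3.2)
  e_fixed <- enclosure_at(pt, flat$structure, cfg)
  set.seed(7)
  e_mc <- mc_enclosure(pt, flat$structure, cfg, n_rays = 5e4)
  expect_lt(abs(e_fixed - e_mc), 0.03)
  expect_lt(e_fixed, cfg$enclosure_threshold)
})

test_that("flat interfaces yield ND; carved cavities yield a detected site", {
  cfg <- small_config()
  flat <- make_cavity_structure(small_cavity_spec(depth = 0))
  expect_false(detect_site(flat$structure, flat$ligand, cfg)$detected)
  cav <- make_cavity_structure(small_cavity_spec())
  s <- detect_site(cav$structure, cav$ligand, cfg)
  expect_true(s$detected)
  expect_gte(s$n, cfg$min_site_points)
  expect_true(s$e >= 0 && s$e <= 1)
  expect_identical(s$p, 0) # all-carbon lining
})

test_that("descriptors are deterministic and exactly translation invariant", {
  cfg <- small_config()
  cav <- make_cavity_structure(small_cavity_spec())
  s1 <- detect_site(cav$structure, cav$ligand, cfg)
  s2 <- detect_site(cav$structure, cav$ligand, cfg)
  expect_identical(s1$n, s2$n)
  expect_identical(s1$e, s2$e)
  expect_identical(s1$p, s2$p)
  # arbitrary (non-lattice) translation of structure plus ligand
  shift <- c(13.73, -2.21, 5.98)
  st <- cav$structure
  st$atoms$x <- st$atoms$x + shift[1]
  st$atoms$y <- st$atoms$y + shift[2]
  st$atoms$z <- st$atoms$z + shift[3]
  lg <- cav$ligand$atoms
  lg$x <- lg$x + shift[1]
  lg$y <- lg$y + shift[2]
  lg$z <- lg$z + shift[3]
  s3 <- detect_site(st, ppi_ligand(lg), cfg)
  expect_identical(s1$n, s3$n)
  expect_equal(s1$e, s3$e, tolerance = 1e-12)
  expect_equal(s1$p, s3$p, tolerance = 1e-12)
})

test_that("descriptors are stable under random rigid motions within stated tolerances", {
  # full-resolution operating point: the 42-ray small fixture is too coarse
  # for these tolerances (see the acceptance suite for the 20-motion run)
  cfg <- pocket_config()
  cav <- make_cavity_structure(cavity_spec(radius = 4, depth = 4))
  s0 <- detect_site(cav$structure, cav$ligand, cfg)
  set.seed(9)
  for (i in 1:5) {
    R <- random_rotation()
    t0 <- rnorm(3, sd = 8)
    st <- cav$structure
    xyz <- sweep(as.matrix(st$atoms[, c("x", "y", "z")]) %*% R, 2, t0, "+")
    st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
    lg <- cav$ligand$atoms
    lxyz <- sweep(as.matrix(lg[, c("x", "y", "z")]) %*% R, 2, t0, "+")
    lg$x <- lxyz[, 1]; lg$y <- lxyz[, 2]; lg$z <- lxyz[, 3]
    s <- detect_site(st, ppi_ligand(lg), cfg)
    expect_true(s$detected)
    expect_lte(abs(s$n - s0$n) / s0$n, 0.15)
    expect_lte(abs(s$e - s0$e), 0.05)
  }
})

test_that("the descriptor engine agrees with a plain-loop brute-force recomputation", {
  cfg <- small_config()
  for (pf in c(0, 0.5)) {
    cav <- make_cavity_structure(small_cavity_spec(polar_fraction = pf))
    s <- detect_site(cav$structure, cav$ligand, cfg)
    o <- oracle_site(cav$structure, cav$ligand, cfg)
    expect_true(s$detected)
    expect_true(o$detected)
    expect_identical(s$n, o$n)
    expect_equal(s$e, o$e, tolerance = 1e-12)
    expect_equal(s$p, o$p, tolerance = 1e-12)
  }
})

test_that("polar lining raises hydrophilicity without reshaping the pocket", {
  # full-resolution operating point: element substitution shifts Bondi
  # radii slightly, and the coarse fixture amplifies that into the
  # site-point count
  cfg <- pocket_config()
  base <- detect_site(
    make_cavity_structure(cavity_spec(radius = 4, depth = 4))$structure,
    make_cavity_structure(cavity_spec(radius = 4, depth = 4))$ligand, cfg
  )
  prev <- -1
  for (pf in c(0.5, 1)) {
    cav <- make_cavity_structure(cavity_spec(radius = 4, depth = 4, polar_fraction = pf))
    s <- detect_site(cav$structure, cav$ligand, cfg)
    expect_gt(s$p, prev)
    expect_gt(s$p, 0)
    expect_lte(s$p, cfg$k_p + 1e-9)
    expect_lte(abs(s$n - base$n) / base$n, 0.15)
    prev <- s$p
  }
})

test_that("deepening and rimming never shrink the pocket descriptors", {
  cfg <- small_config()
  prev_n <- 0
  for (dp in c(2, 3, 4, 5)) {
    cav <- make_cavity_structure(small_cavity_spec(depth = dp))
    s <- detect_site(cav$structure, cav$ligand, cfg)
    expect_gte(s$n, prev_n)
    prev_n <- s$n
  }
  prev_e <- 0
  for (rh in c(0, 1.8, 3.6)) {
    cav <- make_cavity_structure(small_cavity_spec(rim_height = rh))
    s <- detect_site(cav$structure, cav$ligand, cfg)
    expect_gte(s$e, prev_e)
    prev_e <- s$e
  }
})

test_that("icosphere direction sets are unit, deterministic and symmetric", {
  for (n in c(12, 42, 162)) {
    d <- icosphere_directions(n)
    expect_equal(nrow(d), n)
    expect_equal(rowSums(d^2), rep(1, n), tolerance = 1e-9)
    expect_identical(d, icosphere_directions(n))
    # antipodal symmetry of the vertex set
    expect_equal(colSums(d), c(0, 0, 0), tolerance = 1e-9)
  }
  expect_error(icosphere_directions(100), class = "ppidrugg_invalid")
})
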