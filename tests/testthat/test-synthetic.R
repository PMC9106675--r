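test_that("cavity fixtures are deterministic and bookkept by their manifest", {
  sp <- small_cavity_spec(polar_fraction = 0.4, seed = 7)
  a <- make_cavity_structure(sp)
  b <- make_cavity_structure(sp)
  expect_identical(a$structure$atoms, b$structure$atoms)
  expect_identical(a$manifest$polar_resno, b$manifest$polar_resno)
  fa <- tempfile(fileext = ".pdb")
  fb <- tempfile(fileext = ".pdb")
  write_pdb(a$structure, fa)
  write_pdb(b$structure, fb)
  expect_identical(readLines(fa), readLines(fb))
  # manifest accounting: kept protein atoms + carved sites = full lattice
  flat <- make_cavity_structure(small_cavity_spec(depth = 0, seed = 7))
  expect_equal(
    a$manifest$n_protein_atoms + a$manifest$n_removed,
    flat$manifest$n_protein_atoms
  )
})

test_that("polar_fraction 0 gives an all-carbon protein; fractions plant N/O on the lining", {
  a <- make_cavity_structure(small_cavity_spec(polar_fraction = 0))
  prot <- a$structure$atoms[!a$structure$atoms$het, ]
  expect_true(all(prot$element == "C"))
  b <- make_cavity_structure(small_cavity_spec(polar_fraction = 0.5))
  protb <- b$structure$atoms[!b$structure$atoms$het, ]
  polar <- protb$resno[protb$element %in% c("N", "O")]
  expect_setequal(polar, b$manifest$polar_resno)
  expect_true(all(polar %in% b$manifest$lining_resno))
  expect_equal(length(polar), round(0.5 * length(b$manifest$lining_resno)))
})

test_that("oversized cavities and invalid closures are rejected", {
  expect_error(cavity_spec(radius = 20, slab_halfwidth = 10), class = "ppidrugg_invalid")
  expect_error(
    make_apo_holo_pair(small_cavity_spec(), closure = 1.2),
    class = "ppidrugg_invalid"
  )
  expect_error(
    make_apo_holo_pair(small_cavity_spec(depth = 0), closure = 0.5),
    class = "ppidrugg_invalid"
  )
})

test_that("closure interpolates between the holo cavity and a refilled slab", {
  sp <- small_cavity_spec()
  cfg <- small_config()
  pair0 <- make_apo_holo_pair(sp, 0)
  expect_identical(
    pair0$apo$atoms[, c("x", "y", "z")],
    pair0$holo$structure$atoms[!pair0$holo$structure$atoms$het, c("x", "y", "z")]
  )
  n_open <- detect_site(pair0$apo, pair0$holo$ligand, cfg)$n
  pair_half <- make_apo_holo_pair(sp, 0.5)
  s_half <- detect_site(pair_half$apo, pair_half$holo$ligand, cfg)
  pair_full <- make_apo_holo_pair(sp, 1)
  s_full <- detect_site(pair_full$apo, pair_full$holo$ligand, cfg)
  expect_false(s_full$detected) # fully closed: the ND contrast
  expect_true(detect_site(pair_full$holo$structure, pair_full$holo$ligand, cfg)$detected)
  if (s_half$detected) {
    expect_lt(s_half$n, n_open)
    expect_gt(s_half$n, 0)
  }
  # refilled sites occupy exactly the carved lattice positions
  expect_equal(pair_full$manifest$n_filled, pair_full$manifest$n_removed)
  moved <- pair_full$apo$atoms[pair_full$apo$atoms$resno %in% pair_full$manifest$moved_resno, ]
  carved <- pair_full$manifest$removed_sites
  expect_setequal(
    paste(round(moved$x, 6), round(moved$y, 6), round(moved$z, 6)),
    paste(round(carved[, 1], 6), round(carved[, 2], 6), round(carved[, 3], 6))
  )
})

test_that("descriptor tables honour configured medians, spreads and seeds", {
  forms <- data.frame(
    form = "ligand_bound", n_structures = 87,
    median_n = 54, sdlog_n = 0, median_e = 0.66, sd_e = 0,
    median_p = 0.28, sd_p = 0, stringsAsFactors = FALSE
  )
  tab <- make_descriptor_table(target_distribution_spec("HDM2", forms, seed = 1))
  expect_true(all(tab$n == 54)) # zero spread: every draw is the median
  expect_true(all(tab$e == 0.66))
  expect_true(all(tab$p == 0.28))
  forms$sdlog_n <- 0.4
  forms$sd_e <- 0.05
  forms$sd_p <- 0.1
  spec <- target_distribution_spec("HDM2", forms, seed = 2)
  tab2 <- make_descriptor_table(spec)
  expect_equal(nrow(tab2), 87)
  expect_lt(abs(median(tab2$n) - 54) / 54, 0.05)
  expect_lt(abs(median(tab2$e) - 0.66) / 0.66, 0.05)
  expect_lt(abs(median(tab2$p) - 0.28) / 0.28, 0.05)
  expect_true(all(tab2$e >= 0 & tab2$e <= 1))
  expect_true(all(tab2$p >= 0))
  expect_true(all(tab2$n >= 1))
  expect_identical(tab2, make_descriptor_table(spec)) # reproducible
  # iid sampling is available and seeded too
  spec_iid <- target_distribution_spec("HDM2", forms, seed = 2, sampling = "iid")
  expect_identical(make_descriptor_table(spec_iid), make_descriptor_table(spec_iid))
})

test_that("property tables with an all-zero profile pass Ro5 throughout", {
  tab <- make_property_table(25, c(1, 0, 0, 0, 0), seed = 5)
  expect_true(all(ro5_violations(tab) == 0))
  expect_identical(tab, make_property_table(25, c(1, 0, 0, 0, 0), seed = 5))
})

test_that("a half-and-half violation plant splits the audits by exactly 50 points", {
  tab <- make_property_table(100, c(0.5, 0.5, 0, 0, 0), seed = 6)
  audit <- audit_set(tab)
  expect_equal(audit$pct_ro5_minus_1 - audit$pct_ro5, 50.0)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(make_property_table(10, c(1, 0, 0, 0, 0), seed = 99))
  invisible(make_cavity_structure(small_cavity_spec(polar_fraction = 0.3, seed = 99)))
  after <- rnorm(1)
  expect_identical(before, after)
})
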