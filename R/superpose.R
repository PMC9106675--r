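#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of paired point sets by the Kabsch algorithm: the
#' returned proper rotation `R` (reflections corrected via the sign of the
#' determinant) and translation `t` minimise the RMSD of `p %*% R + t`
#' against `q`.
#'
#' @param p,q N x 3 coordinate matrices of paired points, N >= 3 and not
#'   collinear.
#' @return object of class `rigid_transform`: list with `rotation` (3 x 3,
#'   orthonormal, det +1), `translation` (length 3) and `rmsd` (Angstrom).
#' @examples
#' p <- matrix(rnorm(30), ncol = 3)
#' kabsch(p, p)$rmsd
#' @export
kabsch <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (nrow(p) != nrow(q) || ncol(p) != 3 || ncol(q) != 3) {
    .err("ppidrugg_invalid", "p and q must be N x 3 with equal N")
  }
  n <- nrow(p)
  if (n < 3) .err("ppidrugg_degenerate_fit", "need at least 3 paired points")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  sv_p <- svd(pc)$d
  if (sv_p[2] <= 1e-8 * max(sv_p[1], 1)) {
    .err("ppidrugg_degenerate_fit", "collinear points: rotation not determined")
  }
  s <- svd(t(pc) %*% qc)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  tr <- cq - as.numeric(cp %*% R)
  fitted <- sweep(pc %*% R, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rmsd %.4f Angstrom\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param coords N x 3 matrix.
#' @param transform a `rigid_transform`.
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% transform$rotation, 2, transform$translation, "+")
}

# CA coordinates per residue (file order), NA rows for residues lacking a CA
.ca_by_residue <- function(structure, chain) {
  a <- structure$atoms
  a <- a[!a$het & a$chain == chain, , drop = FALSE]
  key <- .res_key(a)
  res <- unique(key)
  ca <- a[a$name == "CA", , drop = FALSE]
  idx <- match(res, .res_key(ca))
  cbind(ca$x[idx], ca$y[idx], ca$z[idx])
}

#' Superpose a reference complex onto a target and transfer its ligand
#'
#' Aligns the target and reference sequences ([global_align()]), fits the
#' C-alpha atoms of the aligned residue pairs by [kabsch()], and applies the
#' reference-to-target transform to the reference ligand. The target's own
#' coordinates are never moved: the posed ligand lands in the target's
#' native frame, ready to seed pocket detection on an apo or
#' peptide/protein-bound structure.
#'
#' @param target a `ppi_structure` (apo or peptide/protein-bound form).
#' @param reference a ligand-bound `ppi_structure`.
#' @param reference_ligand the `ppi_ligand` from the reference complex.
#' @param chain_target,chain_reference chains to align; default first chain.
#' @param gap_open,gap_extend alignment gap penalties.
#' @param trim_outliers if `TRUE`, iteratively drop fitted pairs deviating
#'   by more than 2 SD (at most 3 rounds, never below 20 pairs). Off by
#'   default.
#' @param min_pairs minimum number of fitted residue pairs (default 20).
#' @return object of class `ppi_superposition`: list with `target` (the
#'   unmodified input), `ligand` (the posed `ppi_ligand`), `transform`,
#'   `alignment`, and `n_fit`.
#' @export
superpose_on_reference <- function(target, reference, reference_ligand,
                                   chain_target = chains(target)[1],
                                   chain_reference = chains(reference)[1],
                                   gap_open = 10, gap_extend = 1,
                                   trim_outliers = FALSE, min_pairs = 20) {
  aln <- global_align(
    structure_sequence(target, chain_target),
    structure_sequence(reference, chain_reference),
    gap_open = gap_open, gap_extend = gap_extend
  )
  ca_t <- .ca_by_residue(target, chain_target)
  ca_r <- .ca_by_residue(reference, chain_reference)
  p <- ca_r[aln$pairs[, "b"], , drop = FALSE] # reference moves ...
  q <- ca_t[aln$pairs[, "a"], , drop = FALSE] # ... onto the target frame
  ok <- complete.cases(p) & complete.cases(q)
  p <- p[ok, , drop = FALSE]; q <- q[ok, , drop = FALSE]
  if (nrow(p) < min_pairs) {
    .err("ppidrugg_insufficient_overlap", sprintf(
      "only %d alignable C-alpha pairs (need >= %d)", nrow(p), min_pairs
    ))
  }
  tf <- kabsch(p, q)
  if (trim_outliers) {
    for (round in 1:3) {
      dev <- sqrt(rowSums((apply_transform(p, tf) - q)^2))
      keep <- dev <= mean(dev) + 2 * sd(dev)
      if (all(keep) || sum(keep) < max(min_pairs, 20)) break
      p <- p[keep, , drop = FALSE]; q <- q[keep, , drop = FALSE]
      tf <- kabsch(p, q)
    }
  }
  lig_atoms <- reference_ligand$atoms
  posed <- apply_transform(as.matrix(lig_atoms[, c("x", "y", "z")]), tf)
  lig_atoms$x <- posed[, 1]; lig_atoms$y <- posed[, 2]; lig_atoms$z <- posed[, 3]
  structure(list(
    target = target, ligand = ppi_ligand(lig_atoms),
    transform = tf, alignment = aln, n_fit = nrow(p)
  ), class = "ppi_superposition")
}

#' @export
print.ppi_superposition <- function(x, ...) {
  cat(sprintf(
    "<ppi_superposition> %d aligned pairs (%.1f%% identity), %d fitted C-alpha, rmsd %.3f Angstrom\n",
    nrow(x$alignment$pairs), 100 * x$alignment$identity, x$n_fit, x$transform$rmsd
  ))
  invisible(x)
}
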