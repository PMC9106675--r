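#' @importFrom stats median sd setNames quantile qnorm qlnorm cor complete.cases aggregate runif
#' @importFrom utils write.table read.delim head
NULL

.err <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "ppidrugg_error")))
}

.AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)
.WATERS <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

#' Construct a protein structure object
#'
#' A `ppi_structure` is a heavy-atom coordinate model: an ordered atom table
#' with serial, atom name, element, residue name/number, chain, insertion
#' code, coordinates and a HETATM flag. All descriptor computations in the
#' package operate on this container; hydrogens are dropped on construction
#' (every downstream quantity is heavy-atom based).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `het`.
#' @return object of class `ppi_structure`.
#' @export
ppi_structure <- function(atoms) {
  need <- c(
    "serial", "name", "element", "resname", "chain", "resno",
    "insert", "x", "y", "z", "het"
  )
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    .err("ppidrugg_invalid", paste("missing atom columns:", paste(miss, collapse = ", ")))
  }
  atoms <- atoms[!toupper(atoms$element) %in% c("H", "D"), , drop = FALSE]
  if (nrow(atoms) && any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    .err("ppidrugg_invalid", "non-finite coordinates")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "ppi_structure")
}

#' @export
print.ppi_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "<ppi_structure> %d heavy atoms, %d chain(s) [%s], %d residue(s), %d hetero atom(s)\n",
    nrow(a), length(chains(x)), paste(chains(x), collapse = ","),
    length(unique(.res_key(a[!a$het, , drop = FALSE]))), sum(a$het)
  ))
  invisible(x)
}

.res_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname, sep = "|")
}

#' Chain labels of a structure
#' @param structure a `ppi_structure`.
#' @return character vector of chain identifiers in order of appearance.
#' @export
chains <- function(structure) {
  unique(structure$atoms$chain)
}

#' One-letter amino-acid sequence of a chain
#'
#' Residues are taken in file order from non-HETATM records; non-standard
#' residue names map to `X` (selenomethionine and friends map to their
#' parent letter).
#'
#' @param structure a `ppi_structure`.
#' @param chain chain identifier; defaults to the first chain.
#' @return single character string.
#' @export
structure_sequence <- function(structure, chain = chains(structure)[1]) {
  a <- structure$atoms
  a <- a[!a$het & a$chain == chain, , drop = FALSE]
  if (!nrow(a)) .err("ppidrugg_empty_structure", "chain has no protein atoms")
  key <- .res_key(a)
  res <- a$resname[!duplicated(key)]
  letters1 <- .AA3[toupper(res)]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (PDB v3.x fixed columns, first model only)
#' into a [ppi_structure()]. Alternate locations are resolved to the
#' highest-occupancy copy (first-listed on ties); hydrogens are dropped.
#'
#' @param path path to a PDB file.
#' @return a `ppi_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) .err("ppidrugg_io_error", paste("file not found:", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) .err("ppidrugg_io_error", paste("unreadable PDB:", conditionMessage(e)))
  )
  a <- pdb$atom
  if (is.null(a) || !nrow(a)) .err("ppidrugg_empty_structure", "no ATOM/HETATM records")
  elem <- a$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- .element_from_name(a$elety[blank])
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = toupper(trimws(elem)),
    resname = toupper(trimws(a$resid)),
    chain = ifelse(is.na(a$chain) | a$chain == "", " ", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    het = a$type == "HETATM",
    occ = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE
  )
  atoms <- .resolve_altloc(atoms)
  atoms$occ <- NULL
  atoms$alt <- NULL
  ppi_structure(atoms)
}

# highest occupancy wins; ties broken by file order
.resolve_altloc <- function(atoms) {
  if (all(atoms$alt %in% c("", " "))) return(atoms)
  key <- paste(.res_key(atoms), atoms$name)
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  keep <- !duplicated(key[ord])
  sel <- sort(ord[keep])
  atoms[sel, , drop = FALSE]
}

#' Write a structure to a PDB file
#'
#' @param structure a `ppi_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  if (!nrow(a)) .err("ppidrugg_empty_structure", "nothing to write")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resname, eleno = a$serial,
    elety = a$name, chain = ifelse(a$chain == " ", "", a$chain),
    insert = a$insert, elesy = a$element
  )
  invisible(path)
}

#' Keep only the chain bound to a ligand
#'
#' Mirrors the curation rule that when several copies of a protein are in
#' the asymmetric unit, only the chain bound to the inhibitor is retained:
#' the chain with the smallest minimum heavy-atom distance to the ligand
#' wins, with ties broken by chain label order.
#'
#' @param structure a `ppi_structure` with at least one chain.
#' @param ligand a `ppi_ligand` seeding the selection.
#' @param cutoff maximum heavy-atom contact distance (Angstrom) for a chain
#'   to count as ligand-bound; default 5.0.
#' @return a `ppi_structure` restricted to the selected chain.
#' @export
select_chain <- function(structure, ligand, cutoff = 5.0) {
  a <- structure$atoms
  prot <- a[!a$het, , drop = FALSE]
  if (!nrow(prot)) .err("ppidrugg_empty_structure", "no protein atoms")
  lxyz <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  ch <- sort(unique(prot$chain))
  dmin <- vapply(ch, function(cc) {
    p <- as.matrix(prot[prot$chain == cc, c("x", "y", "z")])
    min(.cross_dist(p, lxyz))
  }, numeric(1))
  if (min(dmin) > cutoff) {
    .err("ppidrugg_no_bound_chain", sprintf(
      "no chain within %.1f Angstrom of ligand (closest %.2f)", cutoff, min(dmin)
    ))
  }
  best <- ch[which.min(dmin)] # sorted labels => ties fall to label order
  ppi_structure(a[a$chain == best, , drop = FALSE])
}

# pairwise distances between two coordinate matrices (rows = atoms)
.cross_dist <- function(p, q) {
  d2 <- outer(rowSums(p^2), rep(1, nrow(q))) +
    outer(rep(1, nrow(p)), rowSums(q^2)) - 2 * p %*% t(q)
  sqrt(pmax(d2, 0))
}

#' Remove solvent and heteroatoms
#'
#' Drops waters and all HETATM residues except an explicitly retained
#' ligand, leaving amino-acid atoms untouched. Idempotent.
#'
#' @param structure a `ppi_structure`.
#' @param keep_ligand residue name of a hetero residue to retain, or `NULL`.
#' @return a `ppi_structure`.
#' @export
strip_non_protein <- function(structure, keep_ligand = NULL) {
  a <- structure$atoms
  keep <- !a$het & !(toupper(a$resname) %in% .WATERS)
  if (!is.null(keep_ligand)) {
    lig <- a$het & toupper(a$resname) == toupper(keep_ligand)
    if (!any(lig)) {
      .err("ppidrugg_missing_ligand", paste("ligand residue not found:", keep_ligand))
    }
    keep <- keep | lig
  }
  out <- a[keep, , drop = FALSE]
  if (!any(!out$het)) .err("ppidrugg_empty_structure", "no protein residues after stripping")
  ppi_structure(out)
}

#' Extract a ligand from a structure
#'
#' Returns the heavy atoms of the named hetero residue as a `ppi_ligand`
#' (atom table, residue name, centroid). Multiple copies without a chain
#' disambiguation raise an ambiguity error rather than guessing.
#'
#' @param structure a `ppi_structure`.
#' @param residue_name 3-letter residue name of the ligand.
#' @param chain_id optional chain restriction.
#' @return a `ppi_ligand`.
#' @export
extract_ligand <- function(structure, residue_name, chain_id = NULL) {
  a <- structure$atoms
  sel <- toupper(a$resname) == toupper(residue_name)
  if (!is.null(chain_id)) sel <- sel & a$chain == chain_id
  a <- a[sel, , drop = FALSE]
  if (!nrow(a)) .err("ppidrugg_missing_ligand", paste("ligand residue not found:", residue_name))
  copies <- unique(paste(a$chain, a$resno, a$insert, sep = "|"))
  if (length(copies) > 1) {
    .err("ppidrugg_ambiguous_ligand", sprintf(
      "%d copies of %s present; specify chain_id/resno", length(copies), residue_name
    ))
  }
  ppi_ligand(a)
}

#' Construct a ligand object
#'
#' @param atoms atom table (heavy atoms) as in [ppi_structure()].
#' @return object of class `ppi_ligand` with fields `atoms`, `resname`
#'   and `centroid` (arithmetic mean of atom coordinates).
#' @export
ppi_ligand <- function(atoms) {
  atoms <- atoms[!toupper(atoms$element) %in% c("H", "D"), , drop = FALSE]
  if (!nrow(atoms)) .err("ppidrugg_missing_ligand", "ligand has no heavy atoms")
  rownames(atoms) <- NULL
  structure(list(
    atoms = atoms,
    resname = atoms$resname[1],
    centroid = colMeans(as.matrix(atoms[, c("x", "y", "z")]))
  ), class = "ppi_ligand")
}

#' @export
print.ppi_ligand <- function(x, ...) {
  cat(sprintf(
    "<ppi_ligand> %s: %d heavy atoms, centroid (%.2f, %.2f, %.2f)\n",
    x$resname, nrow(x$atoms), x$centroid[1], x$centroid[2], x$centroid[3]
  ))
  invisible(x)
}

.xyz <- function(obj) {
  as.matrix(obj$atoms[, c("x", "y", "z")])
}
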