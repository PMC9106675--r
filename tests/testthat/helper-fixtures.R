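# Shared fixtures: a small cavity spec/config pair that keeps the descriptor
# engine fast in tests, and a hand-written multi-chain PDB exercising the
# parser (altlocs, waters, duplicate ligands).

small_cavity_spec <- function(radius = 3, depth = 3, polar_fraction = 0,
                              rim_height = 0, seed = 1) {
  cavity_spec(
    radius = radius, depth = depth, polar_fraction = polar_fraction,
    rim_height = rim_height, seed = seed,
    slab_halfwidth = 9, slab_depth = 8.5
  )
}

small_config <- function(...) {
  pocket_config(region_margin = 4, ray_count = 42, ...)
}

pdb_line <- function(type, serial, name, alt, resname, chain, resno,
                     x, y, z, occ = 1, elem = substr(name, 1, 1)) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf(
    "%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    type, serial, nm, alt, resname, chain, resno, x, y, z, occ, 0, elem
  )
}

# Two chains of 3 ALA (N, CA, C, O each), an altloc pair on chain A's first
# CA (occupancies 0.4 / 0.6), a 3-atom LIG near chain A, a far LIG copy in
# chain B, and two waters.
write_mini_pdb <- function(path) {
  lines <- character(0)
  serial <- 0
  add <- function(...) {
    serial <<- serial + 1
    lines <<- c(lines, pdb_line(..., serial = serial))
  }
  for (ch in c("A", "B")) {
    off <- if (ch == "A") 0 else 30
    for (r in 1:3) {
      base <- c(off + 3 * r, 0, 0)
      if (ch == "A" && r == 1) {
        add("ATOM", name = "N", alt = " ", resname = "ALA", chain = ch, resno = r,
          x = base[1], y = base[2], z = base[3], elem = "N")
        add("ATOM", name = "CA", alt = "A", resname = "ALA", chain = ch, resno = r,
          x = base[1] + 1.0, y = 0.25, z = 0, occ = 0.4, elem = "C")
        add("ATOM", name = "CA", alt = "B", resname = "ALA", chain = ch, resno = r,
          x = base[1] + 1.5, y = 0.75, z = 0, occ = 0.6, elem = "C")
      } else {
        add("ATOM", name = "N", alt = " ", resname = "ALA", chain = ch, resno = r,
          x = base[1], y = base[2], z = base[3], elem = "N")
        add("ATOM", name = "CA", alt = " ", resname = "ALA", chain = ch, resno = r,
          x = base[1] + 1.5, y = 0.5, z = 0, elem = "C")
      }
      add("ATOM", name = "C", alt = " ", resname = "ALA", chain = ch, resno = r,
        x = base[1] + 2, y = 1.5, z = 0, elem = "C")
      add("ATOM", name = "O", alt = " ", resname = "ALA", chain = ch, resno = r,
        x = base[1] + 2, y = 2.5, z = 0.5, elem = "O")
    }
  }
  for (i in 1:3) {
    add("HETATM", name = paste0("C", i), alt = " ", resname = "LIG", chain = "A",
      resno = 101, x = 4 + i, y = -2, z = 1, elem = "C")
  }
  add("HETATM", name = "C1", alt = " ", resname = "LIG", chain = "B", resno = 101,
    x = 60, y = -2, z = 1, elem = "C")
  for (i in 1:2) {
    add("HETATM", name = "O", alt = " ", resname = "HOH", chain = "A", resno = 200 + i,
      x = 0, y = 10 + i, z = 0, elem = "O")
  }
  writeLines(c(lines, "END"), path)
  path
}

# small bare atom table for hand-built structures
atom_df <- function(x, y, z, element = "C", name = "CA", resname = "GLY",
                    chain = "A", het = FALSE, resno = seq_along(x)) {
  n <- length(x)
  data.frame(
    serial = seq_len(n), name = rep_len(name, n), element = rep_len(element, n),
    resname = rep_len(resname, n), chain = rep_len(chain, n), resno = resno,
    insert = rep_len("", n), x = x, y = y, z = z, het = rep_len(het, n),
    stringsAsFactors = FALSE
  )
}
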