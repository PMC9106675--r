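#' Bondi van der Waals radii
#'
#' Heavy-atom van der Waals radii (Angstrom) from Bondi (1964,
#' J. Phys. Chem. 68:441), the set used throughout the pocket descriptor
#' engine. Elements absent from the table fall back to the carbon radius.
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in Angstrom.
#' @examples
#' vdw_radius(c("C", "N", "O", "S"))
#' @export
vdw_radius <- function(element) {
  r <- .bondi[toupper(element)]
  r[is.na(r)] <- .bondi[["C"]]
  unname(r)
}

.bondi <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90, B = 1.92, SI = 2.10, ZN = 1.39, FE = 1.70,
  MG = 1.73, CA = 1.70, MN = 1.70, "NA" = 2.27, K = 2.75
)

# Infer an element symbol from a PDB atom name when the element column is
# blank. Two-letter elements only matter for halogens/metals here; standard
# amino-acid atoms start with the element letter after any digit.
.element_from_name <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "SE", "ZN", "FE", "MG", "MN"),
    two, substr(nm, 1, 1)
  )
  out[out == ""] <- "C"
  out
}
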