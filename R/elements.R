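# Built-in element tables. Covalent radii are the fixed set used for bond
# inference; metals are deliberately excluded from auto-bonding (their
# coordination contacts are role-declared, not inferred).

.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
  MG = 1.41, CA = 1.76, FE = 1.32
)

.metal_elements <- c("MG", "CA", "FE", "MN", "ZN", "NI", "CU", "CO")

.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  MG = 24.305, CA = 40.078, FE = 55.845, MN = 54.938, ZN = 65.38,
  NI = 58.693, CU = 63.546, CO = 58.933
)

# van der Waals radii used for the nonbonded stand-in potential (Bondi-style).
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  MG = 1.73, CA = 2.31, FE = 2.00, MN = 2.05, ZN = 2.10,
  NI = 1.97, CU = 1.96, CO = 2.00
)

#' Look up element properties
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of the requested property.
#' @keywords internal
element_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  if (anyNA(m)) {
    stop("unknown element(s): ", paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' @rdname element_mass
#' @keywords internal
element_covalent_radius <- function(element) {
  r <- .covalent_radii[toupper(element)]
  unname(r)
}

#' @rdname element_mass
#' @keywords internal
element_vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.7
  unname(r)
}

is_metal_element <- function(element) toupper(element) %in% .metal_elements
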