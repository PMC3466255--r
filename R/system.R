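#' Molecular system objects
#'
#' A `qmdmd_system` bundles everything the pipeline knows about one simulated
#' object: an atom table, a bond table with reference lengths, optional
#' angle-auxiliary (1-3) reference pairs, role assignments (metal, substrate,
#' cofactor, water, site residues), named key atoms used by the mechanism
#' stage, and the metal's backend parameters (ionic radius, formal charge).
#'
#' @param atoms tibble with columns `atom_id` (integer, unique), `element`,
#'   `atom_name`, `residue_name`, `residue_id`, `chain_id`, `x`, `y`, `z`
#'   (Angstrom), `mass` (amu), `frozen` (logical).
#' @param bonds tibble with columns `i`, `j` (atom ids) and `ref_length`
#'   (Angstrom); unordered pairs, no self bonds.
#' @param roles named list of integer atom-id vectors; must contain `metal`
#'   (exactly one atom) and may contain `substrate`, `cofactor`, `water`,
#'   `site_residues`.
#' @param aux_pairs optional tibble like `bonds` holding 1-3 reference
#'   distances used for angular stiffness in the sampler.
#' @param key_atoms optional named integer vector tagging mechanistically
#'   special atoms (e.g. `s_donor`, `methyl_c`, `o_acceptor`, `h_acceptor`,
#'   `n_base`).
#' @param metal_params list with `label`, `radius` (Angstrom) and `charge`
#'   (elementary charges) for the bound metal.
#' @return an object of class `qmdmd_system`.
#' @export
new_system <- function(atoms, bonds, roles,
                       aux_pairs = NULL, key_atoms = integer(),
                       metal_params = NULL) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (is.null(aux_pairs)) {
    aux_pairs <- tibble::tibble(i = integer(), j = integer(), ref_length = numeric())
  }
  sys <- structure(
    list(
      atoms = atoms, bonds = bonds, roles = roles,
      aux_pairs = tibble::as_tibble(aux_pairs),
      key_atoms = key_atoms, metal_params = metal_params
    ),
    class = "qmdmd_system"
  )
  validate_system(sys)
  sys
}

#' @rdname new_system
#' @param system a `qmdmd_system`.
#' @export
validate_system <- function(system) {
  a <- system$atoms
  needed <- c("atom_id", "element", "atom_name", "residue_name", "residue_id",
              "chain_id", "x", "y", "z", "mass", "frozen")
  missing_cols <- setdiff(needed, names(a))
  if (length(missing_cols) > 0) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(a$atom_id)) stop("atom_id values must be unique")
  if (!all(is.finite(c(a$x, a$y, a$z)))) stop("non-finite atom position")
  if (!all(a$mass > 0)) stop("atom mass must be positive")
  b <- system$bonds
  if (nrow(b) > 0) {
    if (any(b$i == b$j)) stop("self-bond in bond table")
    if (!all(b$ref_length > 0.5 & b$ref_length < 3.0)) {
      stop("bond reference length outside (0.5, 3.0) Angstrom")
    }
    if (!all(c(b$i, b$j) %in% a$atom_id)) stop("bond references unknown atom id")
  }
  role_ids <- unlist(system$roles, use.names = FALSE)
  if (!all(role_ids %in% a$atom_id)) stop("role refers to unknown atom id")
  if (!is.null(system$roles$metal) && length(system$roles$metal) != 1L) {
    stop("a system with a metal role must declare exactly one metal atom")
  }
  invisible(system)
}

#' Atom coordinates as a matrix
#'
#' @param system a `qmdmd_system`.
#' @param ids optional atom ids to extract (rows in the given order).
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(system, ids = NULL) {
  a <- system$atoms
  if (!is.null(ids)) a <- a[match(ids, a$atom_id), , drop = FALSE]
  m <- cbind(a$x, a$y, a$z)
  rownames(m) <- a$atom_id
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace atom coordinates
#'
#' @inheritParams coords
#' @param xyz numeric matrix (length(ids) x 3).
#' @return the modified system.
#' @export
set_coords <- function(system, xyz, ids = NULL) {
  a <- system$atoms
  rows <- if (is.null(ids)) seq_len(nrow(a)) else match(ids, a$atom_id)
  if (anyNA(rows)) stop("unknown atom id in set_coords()")
  a$x[rows] <- xyz[, 1]
  a$y[rows] <- xyz[, 2]
  a$z[rows] <- xyz[, 3]
  system$atoms <- a
  system
}

#' Interatomic distance within a system
#' @inheritParams coords
#' @param i,j atom ids.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(system, i, j) {
  p <- coords(system, c(i, j))
  sqrt(sum((p[1, ] - p[2, ])^2))
}

heavy_atom_ids <- function(system) {
  system$atoms$atom_id[toupper(system$atoms$element) != "H"]
}

#' @export
print.qmdmd_system <- function(x, ...) {
  cat("<qmdmd_system> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  if (!is.null(x$metal_params)) {
    cat("  metal: ", x$metal_params$label,
        " (r = ", x$metal_params$radius, " A, q = +", x$metal_params$charge, ")\n",
        sep = "")
  }
  cat("  roles: ", paste(names(x$roles), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an atom table
#'
#' @param x a `qmdmd_system`.
#' @param ... unused.
#' @return the atom tibble.
#' @export
tidy.qmdmd_system <- function(x, ...) x$atoms
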