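#' Read a molecular structure from PDB
#'
#' Parses a (possibly multi-model) PDB file through bio3d, assigns element
#' symbols and masses, infers covalent bonds from interatomic distances, and
#' assigns the metal/water roles that can be recognised from residue content.
#' Metals are never auto-bonded: metal coordination is treated as role-declared
#' contacts, not covalent bonds.
#'
#' A bond is recorded between two non-metal atoms when their distance is below
#' `(1 + bond_tolerance) * (r_i + r_j)` with `r` the built-in covalent radii;
#' its reference length is the observed distance.
#'
#' @param path PDB file path.
#' @param bond_tolerance fractional slack on the covalent-radius sum
#'   (default 0.15).
#' @return a `qmdmd_system`, or a list of them for a multi-model file.
#' @export
read_structure <- function(path, bond_tolerance = 0.15) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  blank <- is.na(elem) | elem == ""
  if (any(blank)) {
    # fall back on the first alphabetic character(s) of the atom name
    guess <- toupper(gsub("[^A-Za-z].*$", "", trimws(at$elety[blank])))
    two <- substr(guess, 1, 2) %in% names(.atomic_masses)
    elem[blank] <- ifelse(two, substr(guess, 1, 2), substr(guess, 1, 1))
  }
  unknown <- !(elem %in% names(.atomic_masses))
  if (any(unknown)) {
    stop("unknown element for atom(s): ",
         paste(sprintf("%s %s/%s%d", trimws(at$elety[unknown]), elem[unknown],
                       at$resid[unknown], at$resno[unknown])[seq_len(min(5, sum(unknown)))],
               collapse = "; "))
  }
  if ("alt" %in% names(at) && any(!is.na(at$alt) & !(at$alt %in% c("", "A")))) {
    warning("alternate locations present; keeping the first altloc only")
  }

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_model <- nrow(xyz)

  build_one <- function(model_xyz) {
    m <- matrix(model_xyz, ncol = 3, byrow = TRUE)
    atoms <- tibble::tibble(
      atom_id = seq_len(nrow(at)),
      element = elem,
      atom_name = trimws(at$elety),
      residue_name = trimws(at$resid),
      residue_id = at$resno,
      chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
      x = m[, 1], y = m[, 2], z = m[, 3],
      mass = element_mass(elem),
      frozen = FALSE
    )
    bonds <- infer_bonds(atoms, bond_tolerance)
    roles <- list()
    metal_ids <- atoms$atom_id[is_metal_element(atoms$element)]
    if (length(metal_ids) == 1L) roles$metal <- metal_ids
    water_ids <- atoms$atom_id[atoms$residue_name %in% c("HOH", "WAT", "H2O")]
    if (length(water_ids) > 0) roles$water <- water_ids
    new_system(atoms, bonds, roles)
  }

  systems <- lapply(seq_len(n_model), function(k) build_one(xyz[k, ]))
  if (n_model == 1L) systems[[1]] else systems
}

#' Infer covalent bonds from geometry
#'
#' @param atoms atom tibble (see [new_system()]).
#' @param bond_tolerance fractional slack on covalent-radius sums.
#' @return bond tibble with observed distances as reference lengths.
#' @export
infer_bonds <- function(atoms, bond_tolerance = 0.15) {
  n <- nrow(atoms)
  out_i <- integer(); out_j <- integer(); out_r <- numeric()
  if (n >= 2) {
    rad <- element_covalent_radius(atoms$element)
    bondable <- !is.na(rad) & !is_metal_element(atoms$element)
    xyz <- cbind(atoms$x, atoms$y, atoms$z)
    idx <- which(bondable)
    if (length(idx) >= 2) {
      d <- as.matrix(stats::dist(xyz[idx, , drop = FALSE]))
      cut <- (1 + bond_tolerance) * outer(rad[idx], rad[idx], `+`)
      hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
      if (nrow(hit) > 0) {
        out_i <- atoms$atom_id[idx[hit[, 1]]]
        out_j <- atoms$atom_id[idx[hit[, 2]]]
        out_r <- d[hit]
      }
    }
  }
  tibble::tibble(i = out_i, j = out_j, ref_length = out_r)
}

#' Write a system to PDB
#'
#' Atoms in metal, water, substrate or cofactor roles are emitted as HETATM
#' records; everything else as ATOM. Coordinates must fit the fixed-width PDB
#' coordinate field.
#'
#' @param system a `qmdmd_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path) {
  a <- system$atoms
  if (any(abs(c(a$x, a$y, a$z)) >= 10000)) {
    stop("coordinates exceed the PDB fixed-width range (|x| < 10000)")
  }
  het_ids <- unlist(system$roles[c("metal", "water", "substrate", "cofactor")],
                    use.names = FALSE)
  type <- ifelse(a$atom_id %in% het_ids, "HETATM", "ATOM")
  xyz <- as.numeric(t(cbind(a$x, a$y, a$z)))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = type,
    resno = a$residue_id, resid = a$residue_name,
    eleno = a$atom_id, elety = a$atom_name,
    chain = a$chain_id, elesy = a$element
  )
  invisible(path)
}
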