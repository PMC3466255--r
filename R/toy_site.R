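# Synthetic metal-site generator. Builds a toy octahedral site around a
# central cation: carboxylate/amide arms on anchored flexible linkers, a
# water ligand, a bidentate catechol-like substrate carrying the methyl
# acceptor O and an abstractable H, a frozen S-CH3 donor group aimed at the
# acceptor, and a base site that takes the proton. All native metrics are met
# exactly at the constructed geometry, which doubles as the recovery oracle.

.metal_presets <- list(
  mg  = list(label = "MG", radius = 0.72,  charge = 2),
  ca  = list(label = "CA", radius = 1.00,  charge = 2),
  fe2 = list(label = "FE", radius = 0.78,  charge = 2),
  fe3 = list(label = "FE", radius = 0.645, charge = 3)
)

#' Metal parameter presets
#'
#' Shannon-style six-coordinate ionic radii and formal charges for the four
#' study cations: Mg(II), Ca(II), Fe(II) and Fe(III).
#'
#' @param name one of "mg", "ca", "fe2", "fe3".
#' @return list with `label`, `radius` (Angstrom), `charge`.
#' @export
metal_preset <- function(name) {
  p <- .metal_presets[[tolower(name)]]
  if (is.null(p)) stop("unknown metal preset: ", name)
  p
}

.default_native_distances <- c(
  "Metal-O1(Arm1)"    = 2.13,
  "Metal-O2(Arm1)"    = 3.28,
  "Metal-O(Arm2)"     = 2.35,
  "Metal-O1(Arm3)"    = 2.24,
  "Metal-O(water)"    = 2.04,
  "Metal-O1(Sub)"     = 2.14,
  "Metal-O2(Sub)"     = 2.21,
  "O2(Sub)-C(Don)"    = 2.71,
  "O(Arm1)-O(water)"  = 2.77,
  "O2(Sub)-H(Sub)"    = 1.00,
  "O2(Sub)-N(Base)"   = 2.90
)

.default_native_angles <- c("O2(Sub)-C(Don)-S(Don)" = 170)

#' Specify a toy metal site
#'
#' @param metal_label element label for the cation (default "MG").
#' @param metal_radius ionic radius, Angstrom (in (0.4, 1.4)).
#' @param metal_charge formal charge, elementary charges.
#' @param n_arms number of ligand arms in `[2, 6]` (carboxylate/amide-like).
#' @param include_water logical; add an aqua ligand.
#' @param include_substrate logical; add the bidentate substrate with acceptor
#'   O and abstractable H.
#' @param include_donor logical; add the S-CH3 donor group on a frozen
#'   scaffold.
#' @param include_base logical; add the proton-accepting base site.
#' @param native_distances named numeric vector of target distances (Angstrom);
#'   defaults reproduce the experimentally observed Mg-site geometry.
#' @param native_angles named numeric vector of target angles (degrees).
#' @param arm_length number of linker pseudo-atoms per arm.
#' @param seed integer seed stored with the spec.
#' @return object of class `toy_site_spec`.
#' @export
toy_site_spec <- function(metal_label = "MG", metal_radius = 0.72,
                          metal_charge = 2, n_arms = 3,
                          include_water = TRUE, include_substrate = TRUE,
                          include_donor = TRUE, include_base = TRUE,
                          native_distances = NULL, native_angles = NULL,
                          arm_length = 2, seed = 1L) {
  if (metal_radius <= 0.4 || metal_radius >= 1.4) {
    stop("metal_radius must lie in (0.4, 1.4) Angstrom")
  }
  if (n_arms < 2 || n_arms > 6) stop("n_arms must lie in [2, 6]")
  nd <- .default_native_distances
  if (!is.null(native_distances)) nd[names(native_distances)] <- native_distances
  na <- .default_native_angles
  if (!is.null(native_angles)) na[names(native_angles)] <- native_angles
  if (any(nd <= 0)) stop("native distances must be positive")
  used_dirs <- n_arms + include_water + 2 * include_substrate
  if (used_dirs > 6) {
    stop("coordination oversubscribed: n_arms + water + 2*substrate must be <= 6")
  }
  structure(
    list(metal_label = metal_label, metal_radius = metal_radius,
         metal_charge = metal_charge, n_arms = n_arms,
         include_water = include_water, include_substrate = include_substrate,
         include_donor = include_donor, include_base = include_base,
         native_distances = nd, native_angles = na,
         arm_length = arm_length, seed = as.integer(seed)),
    class = "toy_site_spec"
  )
}

unit <- function(v) v / sqrt(sum(v^2))

rodrigues <- function(v, axis, angle) {
  k <- unit(axis)
  v * cos(angle) + pracma_cross(k, v) * sin(angle) + k * sum(k * v) * (1 - cos(angle))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

perp_of <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit(pracma_cross(d, ref))
}

# Zigzag chain: consecutive bonds of given lengths at ~112 degree angles,
# advancing along dhat in the (dhat, ehat) plane.
grow_chain <- function(start, dhat, ehat, lengths, parity0 = 0L) {
  s <- sin(56 * pi / 180); cc <- cos(56 * pi / 180)
  out <- matrix(NA_real_, length(lengths), 3)
  p <- start
  for (k in seq_along(lengths)) {
    sgn <- if ((k + parity0) %% 2 == 0) 1 else -1
    p <- p + lengths[k] * (s * dhat + sgn * cc * ehat)
    out[k, ] <- p
  }
  out
}

#' Build a toy metal site with known ground truth
#'
#' Constructs the system deterministically so that every requested native
#' metric is met exactly at the returned positions. Donor-group (S-CH3
#' scaffold) heavy atoms and all arm anchor atoms are flagged frozen; they
#' form the rigid "protein frame" the site is suspended in.
#'
#' @param spec a [toy_site_spec()].
#' @return list with `system` (a `qmdmd_system`) and `truth` (native
#'   positions, native metrics, and the surrogate parameters implied).
#' @export
make_toy_site <- function(spec) {
  stopifnot(inherits(spec, "toy_site_spec"))
  nd <- spec$native_distances
  ang <- spec$native_angles

  rows <- list(); bonds_i <- integer(); bonds_j <- integer()
  next_id <- 0L
  add_atom <- function(element, name, resname, resid, pos, frozen = FALSE) {
    next_id <<- next_id + 1L
    rows[[next_id]] <<- list(atom_id = next_id, element = element,
                             atom_name = name, residue_name = resname,
                             residue_id = resid, chain_id = "A",
                             x = pos[1], y = pos[2], z = pos[3],
                             mass = element_mass(element), frozen = frozen)
    next_id
  }
  add_bond <- function(i, j) {
    bonds_i <<- c(bonds_i, i); bonds_j <<- c(bonds_j, j)
  }

  key <- c()
  resid <- 1L
  metal_id <- add_atom(spec$metal_label, spec$metal_label, spec$metal_label,
                       resid, c(0, 0, 0))

  need <- function(label) {
    v <- nd[[label]]
    if (is.null(v) || is.na(v)) stop("missing native distance: ", label)
    v
  }

  # --- coordination directions -------------------------------------------
  # arms claim +x, -x, +y first; substrate takes +z (O1) and -y (O2);
  # water takes ~-z (tilted toward arm1 when an O(Arm1)-O(water) target is
  # set); leftover axes go to extra arms.
  axes <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  taken <- rep(FALSE, 6)
  arm_dirs <- list()
  n_arms <- spec$n_arms
  arm_slots <- c(1, 2, 3)
  taken[1:3] <- TRUE
  if (spec$include_substrate) taken[c(4, 5)] <- TRUE
  if (spec$include_water) taken[6] <- TRUE
  extra_needed <- max(0, n_arms - 3)
  free_slots <- which(!taken)
  if (extra_needed > length(free_slots)) stop("no free coordination directions left")
  arm_slots <- c(arm_slots[seq_len(min(3, n_arms))], free_slots[seq_len(extra_needed)])

  arm_atoms <- list()
  linker_len <- 1.52

  build_generic_arm <- function(k, dhat, d_metal_o, kind) {
    rn <- sprintf("AR%d", k)
    o1 <- d_metal_o * dhat
    ehat <- perp_of(dhat)
    ids <- c()
    if (kind == "carboxylate_bidentate") {
      d12 <- need("Metal-O2(Arm1)")
      chord <- 2 * 1.25 * sin(62 * pi / 180)
      o2x <- (d12^2 + d_metal_o^2 - chord^2) / (2 * d_metal_o)
      rho2 <- d12^2 - o2x^2
      if (rho2 < 0) {
        stop("infeasible native distances for pair Metal-O2(Arm1) / Metal-O1(Arm1)")
      }
      e1 <- perp_of(dhat); e2 <- unit(pracma_cross(dhat, e1))
      o2 <- o2x * dhat + sqrt(rho2) * unit(e1 + e2)
      mid <- (o1 + o2) / 2
      h <- sqrt(1.25^2 - (chord / 2)^2)
      u <- unit(o2 - o1)
      r_out <- unit(mid)
      nhat <- unit(r_out - sum(r_out * u) * u)
      cpos <- mid + h * nhat
      id_o1 <- add_atom("O", "O1", rn, resid, o1)
      id_o2 <- add_atom("O", "O2", rn, resid, o2)
      id_c <- add_atom("C", "CG", rn, resid, cpos)
      add_bond(id_o1, id_c); add_bond(id_o2, id_c)
      ids <- c(id_o1, id_o2, id_c)
      chain_start <- cpos; chain_dir <- unit(cpos); prev <- id_c
    } else if (kind == "amide") {
      id_o1 <- add_atom("O", "O1", rn, resid, o1)
      cpos <- grow_chain(o1, dhat, ehat, 1.23)[1, ]
      id_c <- add_atom("C", "CG", rn, resid, cpos)
      add_bond(id_o1, id_c)
      # sp2 carbon: O, N and the chain branch ~120 degrees apart in-plane
      npos <- cpos - 1.33 * ehat
      id_n <- add_atom("N", "ND", rn, resid, npos)
      add_bond(id_c, id_n)
      ids <- c(id_o1, id_c, id_n)
      chain_start <- cpos; chain_dir <- dhat; prev <- id_c
    } else { # simple carboxylate-like, single coordinating O
      id_o1 <- add_atom("O", "O1", rn, resid, o1)
      cpos <- grow_chain(o1, dhat, ehat, 1.25)[1, ]
      id_c <- add_atom("C", "CG", rn, resid, cpos)
      add_bond(id_o1, id_c)
      ids <- c(id_o1, id_c)
      chain_start <- cpos; chain_dir <- dhat; prev <- id_c
    }
    lens <- rep(linker_len, spec$arm_length + 1L)
    chain <- grow_chain(chain_start, chain_dir, ehat, lens, parity0 = 1L)
    for (m in seq_len(nrow(chain))) {
      is_anchor <- m == nrow(chain)
      id <- add_atom("C", if (is_anchor) "ANC" else sprintf("L%d", m),
                     rn, resid, chain[m, ], frozen = is_anchor)
      add_bond(prev, id)
      ids <- c(ids, id)
      prev <- id
    }
    ids
  }

  for (k in seq_len(n_arms)) {
    resid <- resid + 1L
    dhat <- unit(axes[[arm_slots[k]]])
    kind <- if (k == 1) "carboxylate_bidentate"
            else if (k == 3) "amide"
            else "carboxylate"
    dlab <- switch(as.character(k),
                   "1" = "Metal-O1(Arm1)", "2" = "Metal-O(Arm2)",
                   "3" = "Metal-O1(Arm3)",
                   sprintf("Metal-O(Arm%d)", k))
    d_mo <- if (dlab %in% names(nd)) nd[[dlab]] else 2.15
    arm_atoms[[k]] <- build_generic_arm(k, dhat, d_mo, kind)
  }

  # --- water --------------------------------------------------------------
  water_ids <- integer()
  if (spec$include_water) {
    resid <- resid + 1L
    dw <- need("Metal-O(water)")
    if ("O(Arm1)-O(water)" %in% names(nd) && n_arms >= 1) {
      d1 <- need("Metal-O1(Arm1)"); D <- need("O(Arm1)-O(water)")
      sinphi <- (d1^2 + dw^2 - D^2) / (2 * d1 * dw)
      if (abs(sinphi) > 1) {
        stop("infeasible native distances for pair O(Arm1)-O(water)")
      }
      wo <- dw * c(sinphi, 0, -sqrt(1 - sinphi^2))
    } else {
      wo <- dw * c(0, 0, -1)
    }
    id_wo <- add_atom("O", "OW", "HOH", resid, wo)
    outw <- unit(wo); ew <- perp_of(outw)
    half <- 104.5 / 2 * pi / 180
    id_h1 <- add_atom("H", "HW1", "HOH", resid,
                      wo + 0.96 * (cos(half) * outw + sin(half) * ew))
    id_h2 <- add_atom("H", "HW2", "HOH", resid,
                      wo + 0.96 * (cos(half) * outw - sin(half) * ew))
    add_bond(id_wo, id_h1); add_bond(id_wo, id_h2)
    water_ids <- c(id_wo, id_h1, id_h2)
    key["water_o"] <- id_wo
  }

  # --- substrate (catechol-like, bidentate) ------------------------------
  sub_ids <- integer()
  if (spec$include_substrate) {
    resid <- resid + 1L
    o1 <- need("Metal-O1(Sub)") * c(0, 0, 1)
    o2 <- need("Metal-O2(Sub)") * c(0, -1, 0)
    span <- sqrt(sum((o2 - o1)^2))
    a <- (span - 1.40) / 2
    if (a > 1.36 || a < 0) {
      stop("infeasible native distances for pair O1(Sub)-O2(Sub): ",
           "bridge C1-C2 cannot span ", round(span, 3), " Angstrom")
    }
    h <- sqrt(1.36^2 - a^2)
    u <- unit(o2 - o1)
    mid <- (o1 + o2) / 2
    w_out <- unit(mid - sum(mid * u) * u)
    c1 <- o1 + a * u + h * w_out
    c2 <- o2 - a * u + h * w_out
    id_o1 <- add_atom("O", "O1", "SUB", resid, o1)
    id_o2 <- add_atom("O", "O2", "SUB", resid, o2)
    id_c1 <- add_atom("C", "C1", "SUB", resid, c1)
    id_c2 <- add_atom("C", "C2", "SUB", resid, c2)
    add_bond(id_o1, id_c1); add_bond(id_c1, id_c2); add_bond(id_c2, id_o2)
    sub_ids <- c(id_o1, id_o2, id_c1, id_c2)
    key["o_acceptor"] <- id_o2
    key["o_sub1"] <- id_o1

    if (spec$include_base) {
      dbase <- unit(c(-0.55, -0.65, 0.52))
      hpos <- o2 + need("O2(Sub)-H(Sub)") * dbase
      id_h <- add_atom("H", "HO2", "SUB", resid, hpos)
      add_bond(id_o2, id_h)
      sub_ids <- c(sub_ids, id_h)
      key["h_acceptor"] <- id_h

      resid <- resid + 1L
      npos <- o2 + need("O2(Sub)-N(Base)") * dbase
      id_n <- add_atom("N", "NB", "BAS", resid, npos)
      eb <- perp_of(dbase)
      chain <- grow_chain(npos, dbase, eb, rep(linker_len, spec$arm_length + 1L))
      prev <- id_n
      base_ids <- id_n
      for (m in seq_len(nrow(chain))) {
        is_anchor <- m == nrow(chain)
        id <- add_atom("C", if (is_anchor) "ANC" else sprintf("L%d", m),
                       "BAS", resid, chain[m, ], frozen = is_anchor)
        add_bond(prev, id)
        base_ids <- c(base_ids, id)
        prev <- id
      }
      key["n_base"] <- id_n
      arm_atoms[["base"]] <- base_ids
    }

    if (spec$include_donor) {
      resid <- resid + 1L
      ec <- unit(c(0.25, -0.50, -0.83))
      cm <- o2 + need("O2(Sub)-C(Don)") * ec
      alpha <- ang[["O2(Sub)-C(Don)-S(Don)"]]
      if (is.null(alpha) || is.na(alpha)) alpha <- 170
      axis <- unit(pracma_cross(ec, c(0, 0, 1)))
      sdir <- rodrigues(ec, axis, (180 - alpha) * pi / 180)
      spos <- cm + 1.80 * unit(sdir)
      id_cm <- add_atom("C", "CM", "DON", resid, cm)
      id_s <- add_atom("S", "SD", "DON", resid, spos, frozen = TRUE)
      add_bond(id_s, id_cm)
      away <- unit(spos - cm)
      a1 <- rodrigues(away, perp_of(away), 110 * pi / 180)
      a2 <- rodrigues(a1, away, 2 * pi / 3)
      id_cs1 <- add_atom("C", "CS1", "DON", resid, spos + 1.81 * a1, frozen = TRUE)
      id_cs2 <- add_atom("C", "CS2", "DON", resid, spos + 1.81 * a2, frozen = TRUE)
      add_bond(id_s, id_cs1); add_bond(id_s, id_cs2)
      key["s_donor"] <- id_s
      key["methyl_c"] <- id_cm
      don_ids <- c(id_s, id_cm, id_cs1, id_cs2)
      arm_atoms[["donor"]] <- don_ids
    }
  }

  atoms <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  bonds <- tibble::tibble(i = bonds_i, j = bonds_j)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  bonds$ref_length <- sqrt(rowSums((xyz[bonds$i, , drop = FALSE] -
                                      xyz[bonds$j, , drop = FALSE])^2))

  roles <- list(metal = metal_id)
  if (length(water_ids)) roles$water <- water_ids
  if (length(sub_ids)) roles$substrate <- sub_ids
  if (!is.null(arm_atoms[["donor"]])) roles$cofactor <- arm_atoms[["donor"]]
  site <- unlist(arm_atoms[seq_len(n_arms)], use.names = FALSE)
  site <- c(site, if (!is.null(arm_atoms[["base"]])) arm_atoms[["base"]])
  roles$site_residues <- site

  aux <- one_three_pairs(atoms, bonds)

  metal_params <- list(label = spec$metal_label, radius = spec$metal_radius,
                       charge = spec$metal_charge, reference_radius = 0.72)
  sys <- new_system(atoms, bonds, roles, aux_pairs = aux,
                    key_atoms = key, metal_params = metal_params)

  # record per-donor base equilibrium distances (at the reference radius) so
  # the surrogate's metal-ligand wells are anchored to the native geometry
  donors <- donor_atoms(sys, cutoff = 2.6)
  base_eq <- vapply(donors, function(d) atom_distance(sys, metal_id, d), numeric(1))
  names(base_eq) <- donors
  sys$metal_params$donor_base_eq <- base_eq

  # weak pocket-packing restraints for the surrogate: the toy has no protein
  # matrix, so ligand orientation (water, substrate, methyl) would otherwise
  # have zero-stiffness modes the real pocket removes. 1-4 pairs give chains
  # torsional reference stiffness; ties to the frozen frame pin rigid-body
  # modes. All reference lengths are native by construction.
  fp14 <- one_four_pairs(atoms, bonds)
  excl_ids <- unname(key[names(key) %in% c("methyl_c", "h_acceptor")])
  fp14 <- fp14[!(fp14$i %in% excl_ids | fp14$j %in% excl_ids), ]
  fp14$k <- 8
  # tie targets: the outermost linker of every arm (the truncation-bond inner
  # partner, frozen during the quantum stage) and the donor scaffold -- these
  # atoms are always present in the extracted cluster, so the pocket
  # stiffness survives extraction, and pairwise ties keep the energy
  # rotation/translation invariant
  last_linker <- sprintf("L%d", spec$arm_length)
  frame_targets <- atoms$atom_id[atoms$atom_name %in% c(last_linker, "SD", "CS1", "CS2")]
  if (length(frame_targets) == 0) frame_targets <- atoms$atom_id[atoms$frozen]
  tie_rows <- list()
  axyz <- cbind(atoms$x, atoms$y, atoms$z)
  nearest_target <- function(id, n_tie, k_tie) {
    tg <- setdiff(frame_targets, id)
    p <- axyz[id, ]
    d <- sqrt(rowSums(sweep(axyz[tg, , drop = FALSE], 2, p)^2))
    ord <- order(d)[seq_len(min(n_tie, length(d)))]
    tibble::tibble(i = id, j = tg[ord], ref_length = d[ord], k = k_tie)
  }
  pocket_ids <- setdiff(atoms$atom_id[!atoms$frozen],
                        c(excl_ids, metal_id, frame_targets))
  for (id in pocket_ids) {
    tie_rows[[length(tie_rows) + 1]] <- nearest_target(id, 4L, 6)
  }
  if ("methyl_c" %in% names(key)) {
    tie_rows[[length(tie_rows) + 1]] <- nearest_target(key[["methyl_c"]], 1L, 2)
  }
  sys$frame_pairs <- dplyr::bind_rows(c(list(fp14), tie_rows))

  # reference values for the surrogate's transfer and proton-coupling terms,
  # anchored to the native construction geometry
  if (all(c("s_donor", "methyl_c", "o_acceptor") %in% names(key))) {
    r_oc <- atom_distance(sys, key[["o_acceptor"]], key[["methyl_c"]])
    r_sc <- atom_distance(sys, key[["s_donor"]], key[["methyl_c"]])
    sys$surrogate_ref <- list(xi_w = r_oc - r_sc, sigma0 = r_oc + r_sc)
    if (all(c("h_acceptor", "n_base") %in% names(key))) {
      sys$surrogate_ref$r_oh0 <- atom_distance(sys, key[["o_acceptor"]], key[["h_acceptor"]])
      sys$surrogate_ref$r_on <- atom_distance(sys, key[["o_acceptor"]], key[["n_base"]])
    }
  }

  truth <- list(
    native_positions = coords(sys),
    native_metrics = native_metrics_of(sys, spec),
    spec = spec
  )
  list(system = sys, truth = truth)
}

graph_distance_pairs <- function(atoms, bonds, dist_target) {
  n <- nrow(atoms)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  ii <- integer(); jj <- integer()
  for (a in seq_len(n)) {
    # BFS out to dist_target
    depth <- rep(NA_integer_, n)
    depth[a] <- 0L
    queue <- a
    while (length(queue) > 0) {
      x <- queue[1]; queue <- queue[-1]
      if (depth[x] >= dist_target) next
      for (y in adj[[x]]) {
        if (is.na(depth[y])) {
          depth[y] <- depth[x] + 1L
          queue <- c(queue, y)
        }
      }
    }
    hit <- which(depth == dist_target)
    hit <- hit[hit > a]
    ii <- c(ii, rep(a, length(hit))); jj <- c(jj, hit)
  }
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  tibble::tibble(
    i = ii, j = jj,
    ref_length = if (length(ii)) sqrt(rowSums((xyz[ii, , drop = FALSE] -
                                                 xyz[jj, , drop = FALSE])^2))
                 else numeric()
  )
}

one_four_pairs <- function(atoms, bonds) graph_distance_pairs(atoms, bonds, 3L)

# all pairs at graph distance exactly 2, with native reference lengths
one_three_pairs <- function(atoms, bonds) graph_distance_pairs(atoms, bonds, 2L)

native_metrics_of <- function(sys, spec) {
  vals <- c()
  for (lab in names(spec$native_distances)) {
    ids <- resolve_native_label(sys, lab)
    if (is.null(ids)) next
    vals[lab] <- atom_distance(sys, ids[1], ids[2])
  }
  for (lab in names(spec$native_angles)) {
    ids <- resolve_native_label(sys, lab, n = 3)
    if (is.null(ids)) next
    p <- coords(sys, ids)
    vals[lab] <- interior_angle(p[1, ], p[2, ], p[3, ])
  }
  k <- sys$key_atoms
  if (all(c("o_acceptor", "s_donor") %in% names(k))) {
    vals["O2(Sub)-S(Don)"] <- atom_distance(sys, k[["o_acceptor"]], k[["s_donor"]])
  }
  vals
}

# maps the native-distance labels onto atom ids of the constructed toy
resolve_native_label <- function(sys, lab, n = 2) {
  a <- sys$atoms
  find1 <- function(resname, name) {
    id <- a$atom_id[a$residue_name == resname & a$atom_name == name]
    if (length(id) == 1) id else NA_integer_
  }
  metal <- sys$roles$metal
  ids <- switch(lab,
    "Metal-O1(Arm1)" = c(metal, find1("AR1", "O1")),
    "Metal-O2(Arm1)" = c(metal, find1("AR1", "O2")),
    "Metal-O(Arm2)"  = c(metal, find1("AR2", "O1")),
    "Metal-O1(Arm3)" = c(metal, find1("AR3", "O1")),
    "Metal-O(Arm4)"  = c(metal, find1("AR4", "O1")),
    "Metal-O(Arm5)"  = c(metal, find1("AR5", "O1")),
    "Metal-O(Arm6)"  = c(metal, find1("AR6", "O1")),
    "Metal-O(water)" = c(metal, find1("HOH", "OW")),
    "Metal-O1(Sub)"  = c(metal, find1("SUB", "O1")),
    "Metal-O2(Sub)"  = c(metal, find1("SUB", "O2")),
    "O2(Sub)-C(Don)" = c(find1("SUB", "O2"), find1("DON", "CM")),
    "O(Arm1)-O(water)" = c(find1("AR1", "O1"), find1("HOH", "OW")),
    "O2(Sub)-H(Sub)" = c(find1("SUB", "O2"), find1("SUB", "HO2")),
    "O2(Sub)-N(Base)" = c(find1("SUB", "O2"), find1("BAS", "NB")),
    "O2(Sub)-C(Don)-S(Don)" = c(find1("SUB", "O2"), find1("DON", "CM"),
                                find1("DON", "SD")),
    NULL
  )
  if (is.null(ids) || anyNA(ids) || length(ids) != n) return(NULL)
  ids
}

interior_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Coordinating donor atoms
#'
#' Heavy atoms within `cutoff` of the metal at the current geometry.
#'
#' @param system a `qmdmd_system` with a metal role.
#' @param cutoff coordination cutoff, Angstrom.
#' @return integer atom ids.
#' @export
donor_atoms <- function(system, cutoff = 2.6) {
  metal <- system$roles$metal
  if (is.null(metal)) stop("system has no metal role")
  a <- system$atoms
  xyz <- cbind(a$x, a$y, a$z)
  mpos <- xyz[match(metal, a$atom_id), ]
  d <- sqrt(rowSums(sweep(xyz, 2, mpos)^2))
  cand <- a$atom_id[d > 0 & d <= cutoff & toupper(a$element) != "H"]
  setdiff(cand, metal)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Distort a system with Gaussian positional noise
#'
#' Adds i.i.d. Gaussian noise (sd `sigma` per Cartesian component) to every
#' non-frozen atom; frozen atoms (anchors, donor scaffold) are untouched.
#'
#' @param system a `qmdmd_system`.
#' @param sigma noise standard deviation per component, Angstrom (>= 0).
#' @param seed integer seed.
#' @return the distorted system.
#' @export
distort <- function(system, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(system)
  free <- !system$atoms$frozen
  n <- sum(free)
  noise <- with_local_seed(seed, matrix(stats::rnorm(3 * n, 0, sigma), n, 3))
  xyz <- coords(system)
  xyz[free, ] <- xyz[free, ] + noise
  set_coords(system, xyz)
}

#' Swap the metal's backend parameters
#'
#' Changes the metal's element label, ionic radius and charge without touching
#' the geometry; structural relaxation is the pipeline's job.
#'
#' @param system a `qmdmd_system` with a metal role.
#' @param metal_radius new ionic radius, Angstrom.
#' @param metal_charge new formal charge.
#' @param label new element label (optional; kept if omitted).
#' @return the modified system.
#' @export
make_metal_variant <- function(system, metal_radius, metal_charge, label = NULL) {
  if (is.null(system$roles$metal)) stop("system has no metal role")
  mp <- system$metal_params
  if (is.null(mp)) mp <- list(reference_radius = metal_radius)
  mp$radius <- metal_radius
  mp$charge <- metal_charge
  if (!is.null(label)) {
    mp$label <- label
    row <- match(system$roles$metal, system$atoms$atom_id)
    if (toupper(label) %in% names(.atomic_masses)) {
      system$atoms$element[row] <- toupper(label)
      system$atoms$mass[row] <- element_mass(label)
    }
    system$atoms$atom_name[row] <- toupper(label)
    system$atoms$residue_name[row] <- toupper(label)
  }
  system$metal_params <- mp
  system
}
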