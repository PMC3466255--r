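# Three-domain partitioning with a breathing boundary.
#
# The sampler sees the metal and its directly coordinated donor atoms frozen
# (QM-only core); the quantum stage sees the shared active-site cluster
# extracted, hydrogen-capped at every severed boundary bond, with caps and
# their bond partners frozen. The two static masks together realize the
# breathing boundary.

CAP_FACTOR <- 0.7052

#' A truncation rule for the QM region
#'
#' Selects one residue's contribution to the shared (QM-DMD) domain. With
#' `inner`/`outer` given, the residue is cut at that bond and only the
#' fragment on the `inner` side is included; without them the whole residue
#' is included (no boundary bond).
#'
#' @param residue residue name or id.
#' @param inner,outer atom names of the truncation bond (inner = kept side).
#' @return a rule list.
#' @export
qm_rule <- function(residue, inner = NULL, outer = NULL) {
  if (xor(is.null(inner), is.null(outer))) {
    stop("either give both inner and outer atom names, or neither")
  }
  list(residue = residue, inner = inner, outer = outer)
}

default_qm_rules <- function(system) {
  a <- system$atoms
  rules <- list()
  for (rn in unique(a$residue_name)) {
    ra <- a[a$residue_name == rn, ]
    if (any(ra$atom_id %in% system$roles$metal)) next
    anchors <- ra$atom_id[ra$atom_name == "ANC"]
    if (length(anchors) > 0) {
      # cut at the bond into each frozen anchor
      for (anc in anchors) {
        b <- system$bonds
        hit <- which((b$i == anc & b$j %in% ra$atom_id) |
                     (b$j == anc & b$i %in% ra$atom_id))
        inner_id <- setdiff(c(b$i[hit], b$j[hit]), anc)[1]
        rules[[length(rules) + 1]] <- qm_rule(
          rn, inner = a$atom_name[match(inner_id, a$atom_id)],
          outer = "ANC"
        )
      }
    } else if (any(ra$atom_name %in% c("CS1", "CS2"))) {
      for (nm in intersect(c("CS1", "CS2"), ra$atom_name)) {
        rules[[length(rules) + 1]] <- qm_rule(rn, inner = "SD", outer = nm)
      }
    } else {
      rules[[length(rules) + 1]] <- qm_rule(rn)
    }
  }
  rules
}

#' Assign the three domains
#'
#' The QM-only core is the metal plus every heavy atom within
#' `coordination_cutoff` of it at the current geometry. The shared QM-DMD
#' domain collects the selected residue fragments (minus the core); the rest
#' of the system is DMD-only. Boundary bonds are recorded with their current
#' lengths.
#'
#' @param system a `qmdmd_system` with a metal role.
#' @param qm_selection list of [qm_rule()]s; `NULL` selects every non-metal
#'   residue with its default truncation (cut at the bond into a frozen
#'   anchor atom, or into the frozen donor scaffold).
#' @param coordination_cutoff donor-identification cutoff, Angstrom.
#' @return object of class `qmdmd_partition` with fields `qm_only`, `qm_dmd`,
#'   `dmd_only`, `boundary_bonds`.
#' @export
assign_domains <- function(system, qm_selection = NULL, coordination_cutoff = 2.6) {
  a <- system$atoms
  if (is.null(qm_selection)) qm_selection <- default_qm_rules(system)
  if (length(qm_selection) == 0) {
    stop("empty QM selection: the shared QM-DMD cluster must be non-empty")
  }
  metal <- system$roles$metal
  donors <- donor_atoms(system, coordination_cutoff)
  qm_only <- c(metal, donors)

  adj <- bond_adjacency(system)
  qm_dmd <- integer()
  bb_inner <- integer(); bb_outer <- integer()
  for (rule in qm_selection) {
    sel <- if (is.numeric(rule$residue)) a$residue_id == rule$residue
           else a$residue_name == rule$residue
    rid <- a$atom_id[sel]
    if (length(rid) == 0) stop("QM rule names a missing residue: ", rule$residue)
    if (is.null(rule$inner)) {
      qm_dmd <- c(qm_dmd, rid)
    } else {
      inner_id <- rid[a$atom_name[match(rid, a$atom_id)] == rule$inner]
      outer_id <- rid[a$atom_name[match(rid, a$atom_id)] == rule$outer]
      if (length(inner_id) != 1 || length(outer_id) != 1) {
        stop("QM rule for ", rule$residue, " names missing atom(s): ",
             rule$inner, "-", rule$outer)
      }
      frag <- fragment_from(adj, inner_id, forbidden = outer_id)
      if (!(inner_id %in% frag)) {
        stop("no path from truncation bond into residue ", rule$residue)
      }
      qm_dmd <- c(qm_dmd, intersect(frag, rid))
      bb_inner <- c(bb_inner, inner_id); bb_outer <- c(bb_outer, outer_id)
    }
  }
  qm_dmd <- setdiff(unique(qm_dmd), qm_only)
  dmd_only <- setdiff(a$atom_id, c(qm_only, qm_dmd))
  if (length(qm_dmd) == 0) {
    stop("QM selection produced an empty QM-DMD domain")
  }

  ref_len <- vapply(seq_along(bb_inner),
                    function(k) atom_distance(system, bb_inner[k], bb_outer[k]),
                    numeric(1))
  elems <- a$element[match(c(bb_inner, bb_outer), a$atom_id)]
  if (any(!toupper(elems) %in% c("C", "N"))) {
    warning("boundary bond(s) sever a non-C/N atom; the 0.7052 capping ",
            "factor is applied uniformly")
  }
  structure(
    list(qm_only = qm_only, qm_dmd = qm_dmd, dmd_only = dmd_only,
         boundary_bonds = tibble::tibble(inner = bb_inner, outer = bb_outer,
                                         ref_length = ref_len)),
    class = "qmdmd_partition"
  )
}

bond_adjacency <- function(system) {
  n <- max(system$atoms$atom_id)
  adj <- vector("list", n)
  for (r in seq_len(nrow(system$bonds))) {
    i <- system$bonds$i[r]; j <- system$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

fragment_from <- function(adj, start, forbidden) {
  seen <- integer(0)
  queue <- start
  while (length(queue) > 0) {
    x <- queue[1]; queue <- queue[-1]
    if (x %in% seen || x %in% forbidden) next
    seen <- c(seen, x)
    queue <- c(queue, setdiff(adj[[x]], seen))
  }
  seen
}

#' Extract the hydrogen-capped active-site cluster
#'
#' Copies the QM-only and QM-DMD atoms out of the system and saturates every
#' severed boundary bond with a hydrogen placed along the bond at
#' 0.7052 x R(inner-outer). Cap hydrogens and their inner bond partners are
#' frozen for the quantum stage; the QM-only atoms are the sampler's frozen
#' set.
#'
#' @param system a `qmdmd_system`.
#' @param partition a `qmdmd_partition` for it.
#' @return object of class `qmdmd_cluster`.
#' @export
extract_capped_cluster <- function(system, partition) {
  member_ids <- c(partition$qm_only, partition$qm_dmd)
  a <- system$atoms
  rows <- match(member_ids, a$atom_id)
  if (anyNA(rows)) stop("partition references atoms missing from the system")
  atoms <- a[rows, ]
  bb <- partition$boundary_bonds
  cap_rows <- list()
  next_id <- max(a$atom_id)
  xyz <- coords(system)
  for (k in seq_len(nrow(bb))) {
    pi <- xyz[match(bb$inner[k], a$atom_id), ]
    po <- xyz[match(bb$outer[k], a$atom_id), ]
    v <- po - pi
    len <- sqrt(sum(v^2))
    if (len < 1e-12) stop("boundary bond of zero length (atoms ",
                          bb$inner[k], "-", bb$outer[k], ")")
    cap_pos <- pi + CAP_FACTOR * v
    next_id <- next_id + 1L
    cap_rows[[k]] <- tibble::tibble(
      atom_id = next_id, element = "H", atom_name = "HCP",
      residue_name = "CAP", residue_id = 9999L, chain_id = "A",
      x = cap_pos[1], y = cap_pos[2], z = cap_pos[3],
      mass = 1.008, frozen = TRUE,
      parent = bb$inner[k], source_outer = bb$outer[k],
      bond_ref = bb$ref_length[k]
    )
  }
  caps <- if (length(cap_rows)) dplyr::bind_rows(cap_rows) else NULL
  cap_ids <- if (is.null(caps)) integer() else caps$atom_id
  all_atoms <- dplyr::bind_rows(
    atoms,
    if (!is.null(caps)) caps[, names(atoms)]
  )
  structure(
    list(
      atoms = all_atoms,
      member_ids = member_ids,
      caps = caps,
      frozen_in_qm = unique(c(cap_ids,
                              if (!is.null(caps)) caps$parent else integer())),
      frozen_in_dmd = partition$qm_only,
      source_positions = xyz[rows, , drop = FALSE]
    ),
    class = "qmdmd_cluster"
  )
}

cluster_coords <- function(cluster) {
  m <- cbind(cluster$atoms$x, cluster$atoms$y, cluster$atoms$z)
  rownames(m) <- cluster$atoms$atom_id
  colnames(m) <- c("x", "y", "z")
  m
}

#' Constraint windows from a QM-optimized cluster
#'
#' Each requested atom pair becomes a hard distance window centred on its
#' current (QM-optimized) separation with the given half width.
#'
#' @param cluster a `qmdmd_cluster` (typically after [partial_optimize()]).
#' @param pair_spec two-column matrix (or list of length-2 vectors) of atom
#'   ids; cap hydrogens are not allowed (they do not exist in the full
#'   system).
#' @param half_width window half width, Angstrom (default 0.01).
#' @return a `constraint_set` tibble with columns i, j, target, half_width.
#' @export
constraints_from_cluster <- function(cluster, pair_spec, half_width = 0.01) {
  if (is.list(pair_spec)) pair_spec <- do.call(rbind, pair_spec)
  if (is.null(pair_spec) || length(pair_spec) == 0) {
    return(structure(tibble::tibble(i = integer(), j = integer(),
                                    target = numeric(), half_width = numeric()),
                     class = c("constraint_set", "tbl_df", "tbl", "data.frame")))
  }
  pair_spec <- matrix(as.integer(pair_spec), ncol = 2)
  cap_ids <- if (is.null(cluster$caps)) integer() else cluster$caps$atom_id
  if (any(pair_spec %in% cap_ids)) {
    stop("constraint pair references a cap hydrogen")
  }
  keyp <- paste(pmin(pair_spec[, 1], pair_spec[, 2]),
                pmax(pair_spec[, 1], pair_spec[, 2]))
  if (anyDuplicated(keyp)) {
    warning("duplicate constraint pair(s) collapsed")
    pair_spec <- pair_spec[!duplicated(keyp), , drop = FALSE]
  }
  xyz <- cluster_coords(cluster)
  rows_i <- match(pair_spec[, 1], cluster$atoms$atom_id)
  rows_j <- match(pair_spec[, 2], cluster$atoms$atom_id)
  if (anyNA(rows_i) || anyNA(rows_j)) stop("constraint pair not in cluster")
  target <- unname(sqrt(rowSums((xyz[rows_i, , drop = FALSE] -
                                   xyz[rows_j, , drop = FALSE])^2)))
  structure(
    tibble::tibble(i = pair_spec[, 1], j = pair_spec[, 2],
                   target = target, half_width = half_width),
    class = c("constraint_set", "tbl_df", "tbl", "data.frame")
  )
}

#' Default constraint pairs ("green lines") for a system
#'
#' Metal-coordinating donors are tied to their first non-frozen bonded
#' neighbour; the acceptor O is tied to the transferring methyl carbon; the
#' abstractable H is tied to the base nitrogen.
#'
#' @param system a `qmdmd_system`.
#' @param partition its `qmdmd_partition`.
#' @return two-column integer matrix of atom-id pairs.
#' @export
default_constraint_pairs <- function(system, partition) {
  a <- system$atoms
  adj <- bond_adjacency(system)
  member <- c(partition$qm_only, partition$qm_dmd)
  donors <- setdiff(partition$qm_only, system$roles$metal)
  pairs <- list()
  frozen_ids <- a$atom_id[a$frozen]
  for (d in donors) {
    nb <- setdiff(adj[[d]], frozen_ids)
    nb <- nb[nb %in% member]
    nb <- nb[toupper(a$element[match(nb, a$atom_id)]) != "H"]
    if (length(nb) > 0) pairs[[length(pairs) + 1]] <- c(d, nb[1])
  }
  key <- system$key_atoms
  bonded <- paste(pmin(system$bonds$i, system$bonds$j),
                  pmax(system$bonds$i, system$bonds$j))
  add_if <- function(i, j) {
    if (is.na(i) || is.na(j)) return()
    if (paste(min(i, j), max(i, j)) %in% bonded) return()
    pairs[[length(pairs) + 1]] <<- c(i, j)
  }
  if (all(c("o_acceptor", "methyl_c") %in% names(key))) {
    add_if(key[["o_acceptor"]], key[["methyl_c"]])
  }
  if (all(c("h_acceptor", "n_base") %in% names(key))) {
    add_if(key[["h_acceptor"]], key[["n_base"]])
  }
  do.call(rbind, pairs)
}

#' Reinstall an (optimized) cluster into the full system
#'
#' Member atom positions overwrite the system's; cap hydrogens are discarded.
#' A member displaced more than 5 A from its pre-extraction position triggers
#' a boundary-mismatch warning, not an error.
#'
#' @param system the full `qmdmd_system`.
#' @param cluster a `qmdmd_cluster` extracted from it.
#' @return the updated system.
#' @export
reinstall_cluster <- function(system, cluster) {
  ids <- cluster$member_ids
  rows_c <- match(ids, cluster$atoms$atom_id)
  xyz_new <- cluster_coords(cluster)[rows_c, , drop = FALSE]
  disp <- sqrt(rowSums((xyz_new - cluster$source_positions)^2))
  if (any(disp > 5)) {
    warning("cluster member(s) moved > 5 A since extraction; boundary mismatch")
  }
  set_coords(system, xyz_new, ids = ids)
}
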