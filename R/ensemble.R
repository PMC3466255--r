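# Ensemble machinery: Kabsch RMSD, hierarchical clustering of trajectory
# snapshots, centroid / lowest-energy representatives, and the rank-sum
# scoring rule that picks the structure passed to the quantum stage.

#' Kabsch superposition RMSD
#'
#' Minimal root-mean-square deviation between two coordinate sets over all
#' rigid rotations and translations.
#'
#' @param A,B coordinate matrices (n x 3) in the same atom order, or
#'   `qmdmd_system` objects.
#' @param selection optional atom ids (systems) or row indices (matrices).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(A, B, selection = NULL) {
  if (inherits(A, "qmdmd_system")) A <- coords(A, selection)
  else if (!is.null(selection)) A <- A[selection, , drop = FALSE]
  if (inherits(B, "qmdmd_system")) B <- coords(B, selection)
  else if (!is.null(selection)) B <- B[selection, , drop = FALSE]
  if (nrow(A) < 3 || nrow(B) < 3) stop("need at least 3 atoms for superposition")
  if (nrow(A) != nrow(B)) stop("coordinate sets differ in size")
  kabsch_rmsd_cpp(A, B)
}

#' Pairwise Kabsch-RMSD matrix over trajectory snapshots
#'
#' @param trajectory a `qmdmd_trajectory`.
#' @param selection atom ids to superpose (default: all heavy atoms).
#' @return symmetric F x F matrix of RMSDs.
#' @export
rmsd_matrix <- function(trajectory, selection = NULL) {
  ids <- trajectory$atoms$atom_id
  if (is.null(selection)) {
    selection <- ids[toupper(trajectory$atoms$element) != "H"]
  }
  rows <- match(selection, ids)
  if (anyNA(rows)) stop("selection atom id not in trajectory")
  if (length(rows) < 3) stop("need at least 3 atoms for superposition")
  frames <- trajectory$positions[rows, , , drop = FALSE]
  rmsd_matrix_cpp(frames)
}

#' Cluster a DMD ensemble by geometric similarity
#'
#' Agglomerative (average-linkage) clustering on the pairwise Kabsch-RMSD
#' matrix, cut at `k` clusters. Deterministic for a fixed snapshot order.
#'
#' @param trajectory a `qmdmd_trajectory`.
#' @param k number of clusters (default 5).
#' @param selection atom ids used for the RMSD (default: heavy atoms of the
#'   whole trajectory; the driver passes the QM-DMD region).
#' @param dist_matrix optionally a precomputed RMSD matrix.
#' @return integer cluster assignment per snapshot (1..k).
#' @export
cluster_ensemble <- function(trajectory, k = 5, selection = NULL,
                             dist_matrix = NULL) {
  n <- nrow(trajectory$frames)
  if (k > n) stop("k = ", k, " exceeds the ", n, " available snapshots")
  if (k == 1) return(rep(1L, n))
  if (is.null(dist_matrix)) dist_matrix <- rmsd_matrix(trajectory, selection)
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = "average")
  stats::cutree(hc, k = k)
}

#' Representatives of each cluster
#'
#' Two per cluster: the snapshot closest to the centroid (minimizing summed
#' RMSD to all members) and the one with the lowest DMD potential energy.
#'
#' @param assignment integer cluster labels per snapshot.
#' @param trajectory the clustered `qmdmd_trajectory`.
#' @param dist_matrix pairwise RMSD matrix used for the centroid criterion
#'   (recomputed if missing).
#' @param selection passed to [rmsd_matrix()] when recomputing.
#' @return tibble with one row per representative: cluster, snapshot, role
#'   (centroid / min_energy), dmd_energy.
#' @export
select_representatives <- function(assignment, trajectory,
                                   dist_matrix = NULL, selection = NULL) {
  if (is.null(dist_matrix)) dist_matrix <- rmsd_matrix(trajectory, selection)
  energies <- trajectory$frames$potential_energy
  out <- list()
  for (cl in sort(unique(assignment))) {
    members <- which(assignment == cl)
    if (length(members) == 1) {
      cent <- members; emin <- members
    } else {
      sums <- rowSums(dist_matrix[members, members, drop = FALSE])
      cent <- members[which.min(sums)]
      emin <- members[which.min(energies[members])]
    }
    out[[length(out) + 1]] <- tibble::tibble(
      cluster = cl,
      snapshot = c(cent, emin),
      role = c("centroid", "min_energy"),
      dmd_energy = energies[c(cent, emin)]
    )
  }
  dplyr::bind_rows(out)
}

#' Rank-sum scoring: choose the structure for the quantum stage
#'
#' Each representative is ranked (ascending) by QM energy and by DMD energy;
#' the combined score is the rank sum. Lowest score wins; ties break to the
#' lower QM energy, then to the lower snapshot index.
#'
#' @param representatives tibble from [select_representatives()].
#' @param qm_energies backend energies, one per representative row.
#' @param dmd_energies DMD potential energies (defaults to the tibble's).
#' @return the winning row of `representatives`, with `score`, `qm_energy`
#'   columns added; the full scored table is attached as attribute `"scored"`.
#' @export
score_and_choose <- function(representatives, qm_energies,
                             dmd_energies = representatives$dmd_energy) {
  stopifnot(length(qm_energies) == nrow(representatives),
            all(is.finite(qm_energies)), all(is.finite(dmd_energies)))
  tab <- representatives
  tab$qm_energy <- qm_energies
  tab$dmd_energy <- dmd_energies
  tab$score <- rank(qm_energies, ties.method = "min") +
    rank(dmd_energies, ties.method = "min")
  ord <- order(tab$score, tab$qm_energy, tab$snapshot)
  chosen <- tab[ord[1], ]
  attr(chosen, "scored") <- tab
  chosen
}
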