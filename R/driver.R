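# The QM/DMD iteration loop: sample with constrained DMD, cluster the
# ensemble, pick representatives, score them by combined QM/DMD rank,
# partially optimize the chosen capped cluster at the quantum stage,
# reinstall it, and carry forward whichever of input/output has the lower
# active-site subset energy.

#' Energy-based iteration acceptance
#'
#' Evaluates the backend energy on the active-site subset extracted from the
#' input and output structures and carries forward the lower one (ties prefer
#' the output: progress).
#'
#' @param input_structure,output_structure `qmdmd_system`s sharing atom ids.
#' @param subset atom ids of the scoring subset (site residues + metal +
#'   substrate + water).
#' @param backend a `qmdmd_backend`.
#' @return list with `structure` (the carried one), `carried`
#'   ("input"/"output"), `energy_input`, `energy_output`.
#' @export
accept_iteration <- function(input_structure, output_structure, subset, backend) {
  if (length(subset) == 0) stop("empty scoring subset")
  e_in <- backend_energy(backend, coords(input_structure, subset), ids = subset)
  e_out <- backend_energy(backend, coords(output_structure, subset), ids = subset)
  if (e_out <= e_in) {
    list(structure = output_structure, carried = "output",
         energy_input = e_in, energy_output = e_out)
  } else {
    list(structure = input_structure, carried = "input",
         energy_input = e_in, energy_output = e_out)
  }
}

qm_subset_ids <- function(system) {
  unique(c(system$roles$metal, system$roles$site_residues,
           system$roles$substrate, system$roles$water))
}

backbone_ids <- function(system) {
  a <- system$atoms
  ids <- a$atom_id[a$atom_name == "ANC" | grepl("^L[0-9]+$", a$atom_name)]
  if (length(ids) >= 3) ids else heavy_atom_ids(system)
}

#' Run the iterative QM/DMD protocol
#'
#' Starting from a clash-removal run and a seeding quantum relaxation of the
#' active-site cluster, each iteration executes: annealing + production DMD
#' (with constraint windows taken from the previous QM-optimized cluster),
#' Kabsch-RMSD clustering of the 1,000-pose ensemble into `k_clusters`,
#' centroid and minimum-energy representatives, single-point backend energies,
#' rank-sum choice of one structure, extraction and capping of its cluster,
#' partial optimization, reinstallation, and the subset-energy acceptance
#' rule. Every structure is archived in the returned history whether or not
#' it is carried forward.
#'
#' @param system starting `qmdmd_system`.
#' @param n_iterations number of QM/DMD iterations (default 20).
#' @param seed master seed; per-stage seeds derive from it.
#' @param backend a `qmdmd_backend` (default: surrogate built from `system`).
#' @param qm_selection,coordination_cutoff passed to [assign_domains()].
#' @param constraint_pairs two-column matrix of constrained pairs (default:
#'   [default_constraint_pairs()]).
#' @param half_width constraint window half width, Angstrom.
#' @param k_clusters clusters per ensemble (default 5).
#' @param production [dmd_params()] for the production phase.
#' @param opt_tol gradient tolerance of the quantum partial optimization.
#' @param ground_truth optional native coordinate matrix; adds a
#'   ground-truth heavy-atom RMSD column to the convergence table.
#' @param output_dir optional directory: per-iteration PDBs and the
#'   convergence TSV are written there.
#' @return a `qmdmd_run` object: `history` (one record per iteration),
#'   `final` system, `convergence` tibble.
#' @export
run_qmdmd <- function(system, n_iterations = 20, seed = 1L,
                      backend = NULL,
                      qm_selection = NULL, coordination_cutoff = 2.6,
                      constraint_pairs = NULL, half_width = 0.01,
                      k_clusters = 5,
                      production = dmd_params(),
                      opt_tol = 1e-3,
                      ground_truth = NULL,
                      output_dir = NULL) {
  if (is.null(backend)) backend <- surrogate_backend(system)
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
  }
  heavy <- heavy_atom_ids(system)
  subset <- qm_subset_ids(system)
  gt_rmsd <- function(sys) {
    if (is.null(ground_truth)) return(NA_real_)
    kabsch_rmsd(coords(sys, heavy), ground_truth[match(heavy, system$atoms$atom_id), ,
                                                 drop = FALSE])
  }

  # preparation: clash-removal run (only the system's own frozen atoms are
  # held -- the QM-only freeze belongs to the QM/DMD phases proper), then a
  # seeding QM relaxation that gives the first DMD phase its QM-derived
  # constraint targets and a core geometry consistent with them
  pot0 <- build_potentials(system, NULL, frozen_mask = system$atoms$frozen)
  current <- remove_clashes(system, NULL, pot0, seed = seed)
  partition <- assign_domains(current, qm_selection, coordination_cutoff)
  cl0 <- extract_capped_cluster(current, partition)
  opt0 <- partial_optimize(cl0, backend, tol = opt_tol)
  current <- reinstall_cluster(current, opt0)
  last_opt_cluster <- opt0

  history <- list()
  prev_accepted <- current
  conv <- list()

  for (it in seq_len(n_iterations)) {
    it_seed <- seed + it * 1009L
    partition <- suppressWarnings(
      assign_domains(current, qm_selection, coordination_cutoff)
    )
    mask <- dmd_freeze_mask(current, partition)
    pairs <- constraint_pairs
    if (is.null(pairs)) pairs <- default_constraint_pairs(current, partition)
    constraints <- constraints_from_cluster(last_opt_cluster, pairs, half_width)
    potentials <- build_potentials(current, constraints, frozen_mask = mask)

    traj <- run_schedule(current, partition, potentials, seed = it_seed,
                         production = production)
    region_ids <- c(partition$qm_only, partition$qm_dmd)
    sel <- intersect(heavy, region_ids)
    M <- rmsd_matrix(traj, sel)
    assignment <- cluster_ensemble(traj, k_clusters, dist_matrix = M)
    reps <- select_representatives(assignment, traj, dist_matrix = M)

    snapshot_system <- function(f) {
      set_coords(current, traj$positions[, , f])
    }
    qm_e <- vapply(reps$snapshot, function(f) {
      cl <- extract_capped_cluster(snapshot_system(f), partition)
      backend_energy(backend, cl)
    }, numeric(1))
    chosen <- score_and_choose(reps, qm_e)

    chosen_sys <- snapshot_system(chosen$snapshot)
    cl_ch <- extract_capped_cluster(chosen_sys, partition)
    opt_cl <- partial_optimize(cl_ch, backend, tol = opt_tol)
    output_sys <- reinstall_cluster(chosen_sys, opt_cl)
    last_opt_cluster <- opt_cl

    acc <- accept_iteration(current, output_sys, subset, backend)

    met <- tibble::tibble(
      iteration = it,
      backbone_rmsd = kabsch_rmsd(coords(acc$structure, backbone_ids(current)),
                                  coords(prev_accepted, backbone_ids(current))),
      site_rmsd = kabsch_rmsd(coords(acc$structure, region_ids),
                              coords(prev_accepted, region_ids)),
      qm_energy = min(acc$energy_input, acc$energy_output),
      carried = acc$carried,
      gt_rmsd = gt_rmsd(acc$structure)
    )
    conv[[it]] <- met

    history[[it]] <- list(
      iteration = it,
      selection = attr(chosen, "scored"),
      chosen_snapshot = chosen$snapshot,
      trajectory_frames = traj$frames,
      n_events = traj$n_events,
      constraint_maxdev = traj$constraint_maxdev,
      optimized_cluster = opt_cl,
      output_structure = output_sys,
      accepted = acc$carried,
      energy_input = acc$energy_input,
      energy_output = acc$energy_output,
      metrics = met
    )
    if (!is.null(output_dir)) {
      itdir <- file.path(output_dir, sprintf("iter_%02d", it))
      dir.create(itdir, showWarnings = FALSE)
      write_structure(output_sys, file.path(itdir, "system.pdb"))
      jsonlite::write_json(attr(chosen, "scored"),
                           file.path(itdir, "selection.json"))
    }
    prev_accepted <- acc$structure
    current <- acc$structure
  }

  convergence <- if (length(conv)) dplyr::bind_rows(conv) else
    tibble::tibble(iteration = integer(), backbone_rmsd = numeric(),
                   site_rmsd = numeric(), qm_energy = numeric(),
                   carried = character(), gt_rmsd = numeric())
  if (!is.null(output_dir)) {
    utils::write.table(convergence, file.path(output_dir, "convergence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(
    list(history = history, final = current, convergence = convergence,
         n_iterations = n_iterations, seed = seed),
    class = "qmdmd_run"
  )
}

#' @export
print.qmdmd_run <- function(x, ...) {
  cat("<qmdmd_run> ", x$n_iterations, " iterations (seed ", x$seed, ")\n", sep = "")
  print(x$convergence)
  invisible(x)
}

#' Convergence trace of a run
#' @param x a `qmdmd_run`.
#' @param ... unused.
#' @return tibble: iteration, backbone RMSD, QM-DMD-region all-atom RMSD,
#'   subset QM energy, carried structure, optional ground-truth RMSD.
#' @export
tidy.qmdmd_run <- function(x, ...) x$convergence

#' One-row summary of a run
#' @param x a `qmdmd_run`.
#' @param ... unused.
#' @export
glance.qmdmd_run <- function(x, ...) {
  cv <- x$convergence
  tibble::tibble(
    n_iterations = x$n_iterations,
    final_qm_energy = utils::tail(cv$qm_energy, 1),
    final_gt_rmsd = utils::tail(cv$gt_rmsd, 1),
    n_accepted_outputs = sum(cv$carried == "output")
  )
}

#' Static-cluster control (no protein repacking)
#'
#' One extract -> partial-optimize pass from the given geometry, with no DMD
#' sampling: the "no-repacking control" against which the full protocol's
#' structural adjustment is judged.
#'
#' @param system a `qmdmd_system`.
#' @param partition optional `qmdmd_partition` (default: [assign_domains()]).
#' @param backend optional backend (default: surrogate from `system`).
#' @param opt_tol gradient tolerance.
#' @return the optimized `qmdmd_cluster`, with attribute
#'   `mode = "no-repacking control"`.
#' @export
static_cluster_mode <- function(system, partition = NULL, backend = NULL,
                                opt_tol = 1e-4) {
  if (is.null(partition)) partition <- assign_domains(system)
  if (is.null(backend)) backend <- surrogate_backend(system)
  cl <- extract_capped_cluster(system, partition)
  out <- partial_optimize(cl, backend, tol = opt_tol)
  attr(out, "mode") <- "no-repacking control"
  out
}
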