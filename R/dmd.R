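# Constrained event-driven DMD: stepwise pair potentials, hard constraint
# windows, frozen QM-only core, Andersen thermostat, and the annealing /
# production schedule.

#' DMD run parameters
#'
#' Temperatures are reduced: theta in kcal/mol with <KE> = (3 N_free / 2)
#' theta. One DMD time unit corresponds to about 50 fs.
#'
#' @param temperature reduced temperature theta (production default 0.10).
#' @param heat_exchange_rate Andersen ghost-collision rate, 1/t.u.
#' @param duration phase length, t.u.
#' @param save_interval snapshot spacing, t.u. (must divide duration).
#' @param seed integer seed.
#' @param tu_to_fs conversion constant, fs per t.u. (informational).
#' @return a `dmd_params` list.
#' @export
dmd_params <- function(temperature = 0.10, heat_exchange_rate = 0.1,
                       duration = 10000, save_interval = 10,
                       seed = 1L, tu_to_fs = 50) {
  stopifnot(temperature > 0, heat_exchange_rate >= 0, duration > 0,
            save_interval > 0)
  if (abs(duration / save_interval - round(duration / save_interval)) > 1e-9) {
    stop("save_interval must divide duration")
  }
  structure(list(temperature = temperature,
                 heat_exchange_rate = heat_exchange_rate,
                 duration = duration, save_interval = save_interval,
                 seed = as.integer(seed), tu_to_fs = tu_to_fs),
            class = "dmd_params")
}

#' Build the stepwise pair-potential table
#'
#' Bonds become infinite square wells spanning +/-5% of the reference length;
#' 1-3 (angle-auxiliary) pairs +/-10%; constraint pairs become hard windows
#' `target +/- half_width`. Remaining pairs get a 3-step discretized
#' attractive well: hard core at `core_factor` x the vdW-radius sum and two
#' attractive shells at 1.0x and 1.25x with the given depths. The metal
#' participates only through constraints and freezing; frozen-frozen pairs
#' are excluded. A hard core that would already swallow the current geometry
#' is shrunk below it (declared native contacts are not clashes).
#'
#' @param system a `qmdmd_system`.
#' @param constraints a `constraint_set` (may be empty).
#' @param core_factor hard-core radius as a fraction of the vdW sum.
#' @param shell_depths attractive well depths, kcal/mol (length 2).
#' @param frozen_mask optional logical vector marking atoms frozen during the
#'   phase (defaults to the system's frozen flags).
#' @return a `dmd_potentials` list of pair tables for the engine.
#' @export
build_potentials <- function(system, constraints = NULL,
                             core_factor = 0.85,
                             shell_depths = c(-0.10, -0.05),
                             frozen_mask = NULL) {
  a <- system$atoms
  n <- nrow(a)
  if (is.null(frozen_mask)) frozen_mask <- a$frozen
  xyz <- coords(system)
  id2row <- function(ids) match(ids, a$atom_id)

  win <- list()  # per pair: list(i, j, radii, energies, constraint, target)
  keyf <- function(i, j) paste(pmin(i, j), pmax(i, j))
  window_of <- new.env()

  add_window <- function(i, j, lo, hi, constraint = FALSE, target = NA) {
    k <- keyf(i, j)
    prev <- window_of[[k]]
    if (!is.null(prev)) {
      lo2 <- max(prev$lo, lo); hi2 <- min(prev$hi, hi)
      if (lo2 >= hi2) {
        stop("conflicting distance windows on pair ", i, "-", j,
             ": [", round(prev$lo, 3), ", ", round(prev$hi, 3), "] vs [",
             round(lo, 3), ", ", round(hi, 3), "]")
      }
      prev$lo <- lo2; prev$hi <- hi2
      prev$constraint <- prev$constraint || constraint
      if (constraint) prev$target <- target
      window_of[[k]] <- prev
    } else {
      window_of[[k]] <- list(i = i, j = j, lo = lo, hi = hi,
                             constraint = constraint, target = target)
    }
  }

  b <- system$bonds
  for (r in seq_len(nrow(b))) {
    add_window(b$i[r], b$j[r], 0.95 * b$ref_length[r], 1.05 * b$ref_length[r])
  }
  ax <- system$aux_pairs
  for (r in seq_len(nrow(ax))) {
    add_window(ax$i[r], ax$j[r], 0.90 * ax$ref_length[r], 1.10 * ax$ref_length[r])
  }
  # pocket-frame reference pairs (when the system carries them) become wide
  # hard windows: they keep sampling on the native side of mirror-image
  # chain/ligand flips the minimal stand-in potential cannot otherwise
  # penalize, standing in for the packing terms of a full force field
  fp <- system$frame_pairs
  if (!is.null(fp) && nrow(fp) > 0) {
    for (r in seq_len(nrow(fp))) {
      add_window(fp$i[r], fp$j[r], 0.85 * fp$ref_length[r], 1.15 * fp$ref_length[r])
    }
  }
  if (!is.null(constraints) && nrow(constraints) > 0) {
    for (r in seq_len(nrow(constraints))) {
      add_window(constraints$i[r], constraints$j[r],
                 constraints$target[r] - constraints$half_width[r],
                 constraints$target[r] + constraints$half_width[r],
                 constraint = TRUE, target = constraints$target[r])
    }
  }

  pair_i <- integer(); pair_j <- integer()
  radii_off <- 0L; radii <- numeric(); energies <- numeric()
  cons_idx <- integer(); cons_target <- numeric()
  np <- 0L

  push_pair <- function(i, j, rads, ens, constraint = FALSE, target = NA) {
    ri <- id2row(i); rj <- id2row(j)
    if (frozen_mask[ri] && frozen_mask[rj]) return()
    pair_i[np + 1L] <<- ri - 1L; pair_j[np + 1L] <<- rj - 1L
    radii <<- c(radii, rads); energies <<- c(energies, ens)
    radii_off <<- c(radii_off, length(radii))
    np <<- np + 1L
    if (constraint) {
      cons_idx[length(cons_idx) + 1L] <<- np - 1L
      cons_target[length(cons_target) + 1L] <<- target
    }
  }

  for (k in ls(window_of)) {
    w <- window_of[[k]]
    push_pair(w$i, w$j, c(w$lo, w$hi), c(Inf, 0, Inf),
              constraint = w$constraint, target = w$target)
  }

  # nonbonded stand-in for everything else (no metal, no windowed pair)
  metal <- system$roles$metal
  vdw <- element_vdw_radius(a$element)
  cmb <- utils::combn(a$atom_id, 2)
  for (q in seq_len(ncol(cmb))) {
    i <- cmb[1, q]; j <- cmb[2, q]
    if (!is.null(metal) && (i == metal || j == metal)) next
    if (!is.null(window_of[[keyf(i, j)]])) next
    ri <- id2row(i); rj <- id2row(j)
    if (frozen_mask[ri] && frozen_mask[rj]) next
    S <- vdw[ri] + vdw[rj]
    core <- core_factor * S
    d0 <- sqrt(sum((xyz[ri, ] - xyz[rj, ])^2))
    if (d0 <= core * 1.02) core <- d0 / 1.02
    rads <- c(core, max(S, core * 1.05), max(1.25 * S, core * 1.10))
    push_pair(i, j, rads, c(Inf, shell_depths[1], shell_depths[2], 0))
  }

  structure(
    list(pair_i = pair_i, pair_j = pair_j,
         radii_off = as.integer(radii_off), radii = radii,
         energies = energies,
         cons_idx = as.integer(cons_idx), cons_target = cons_target,
         frozen_mask = frozen_mask, n_atoms = n),
    class = "dmd_potentials"
  )
}

# Steepest-descent-style relief of hard-wall violations: minimizes the summed
# squared violation depths of all windowed pairs over the free atoms.
relieve_clashes <- function(system, potentials, tol = 1e-10) {
  a <- system$atoms
  xyz <- coords(system)
  free_rows <- which(!potentials$frozen_mask)
  if (length(free_rows) == 0) return(system)
  pi <- potentials$pair_i + 1L; pj <- potentials$pair_j + 1L
  off <- potentials$radii_off
  viol <- function(m) {
    tot <- 0
    grad <- matrix(0, nrow(m), 3)
    for (p in seq_along(pi)) {
      rads <- potentials$radii[(off[p] + 1):off[p + 1]]
      ens <- potentials$energies[(off[p] + p):(off[p + 1] + p)]
      dvec <- m[pi[p], ] - m[pj[p], ]
      r <- sqrt(sum(dvec^2))
      k <- findInterval(r, rads) + 1L
      if (is.finite(ens[k])) next
      # walk toward the nearest allowed region boundary
      fin <- which(is.finite(ens))
      lows <- c(0, rads)[fin]; highs <- c(rads, Inf)[fin]
      dlo <- pmax(lows - r, 0); dhi <- pmax(r - highs, 0)
      depth <- pmin(dlo + dhi, Inf)
      bidx <- which.min(depth)
      dtar <- if (r < lows[bidx]) lows[bidx] else highs[bidx]
      dev <- r - dtar
      tot <- tot + dev^2
      u <- dvec / max(r, 1e-9)
      grad[pi[p], ] <- grad[pi[p], ] + 2 * dev * u
      grad[pj[p], ] <- grad[pj[p], ] - 2 * dev * u
    }
    list(value = tot, grad = grad)
  }
  pack <- function(m) as.numeric(m[free_rows, ])
  fn <- function(par) {
    xyz[free_rows, ] <- matrix(par, ncol = 3)
    viol(xyz)$value
  }
  gr <- function(par) {
    xyz[free_rows, ] <- matrix(par, ncol = 3)
    as.numeric(viol(xyz)$grad[free_rows, ])
  }
  p <- pack(xyz)
  if (fn(p) <= tol) return(system)
  warning("initial geometry violates hard walls; running clash relief")
  for (round in 1:5) {
    opt <- stats::optim(p, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = 2000, factr = 1, pgtol = 1e-12))
    p <- opt$par
    if (fn(p) <= tol) break
  }
  xyz[free_rows, ] <- matrix(p, ncol = 3)
  set_coords(system, xyz)
}

#' Run one DMD phase
#'
#' Event-driven propagation at a single thermostat set-point. The QM-only
#' atoms of the partition are frozen in addition to the system's own frozen
#' flags. Snapshots are saved every `save_interval` t.u.
#'
#' @param system a `qmdmd_system`.
#' @param partition a `qmdmd_partition` (or `NULL`: only the system's frozen
#'   flags apply).
#' @param potentials a `dmd_potentials` table built with the same freeze mask.
#' @param params a [dmd_params()].
#' @param track_energy record the maximum total-energy drift at pair events
#'   (for conservation checks; adds O(n) work per event).
#' @param vel0 optional initial velocity matrix (n x 3).
#' @return a `qmdmd_trajectory`.
#' @export
run_phase <- function(system, partition, potentials, params,
                      track_energy = FALSE, vel0 = NULL) {
  system <- relieve_clashes(system, potentials)
  res <- run_dmd_cpp(
    coords(system), system$atoms$mass, potentials$frozen_mask,
    potentials$pair_i, potentials$pair_j,
    potentials$radii_off, potentials$radii, potentials$energies,
    potentials$cons_idx, potentials$cons_target,
    params$temperature, params$heat_exchange_rate,
    params$duration, params$save_interval,
    params$seed, track_energy,
    if (is.null(vel0)) NULL else vel0
  )
  n <- nrow(system$atoms)
  nf <- res$n_frames
  pos <- aperm(array(res$snapshots[seq_len(nf * n * 3)], dim = c(3, n, nf)),
               c(2, 1, 3))
  structure(
    list(
      atoms = system$atoms,
      roles = system$roles,
      positions = pos,
      frames = tibble::tibble(
        frame = seq_len(nf),
        time = res$times[seq_len(nf)],
        potential_energy = res$potential_energy[seq_len(nf)],
        kinetic_energy = res$kinetic_energy[seq_len(nf)]
      ),
      params = params,
      final = set_coords(system, res$final_pos),
      final_vel = res$final_vel,
      constraint_maxdev = res$constraint_maxdev,
      n_events = res$n_events,
      max_energy_drift = res$max_energy_drift,
      mean_kinetic_energy = res$mean_kinetic_energy,
      n_free = sum(!potentials$frozen_mask)
    ),
    class = "qmdmd_trajectory"
  )
}

#' @export
print.qmdmd_trajectory <- function(x, ...) {
  cat("<qmdmd_trajectory> ", nrow(x$frames), " frames x ", nrow(x$atoms),
      " atoms, ", format(x$n_events, big.mark = ","), " events\n", sep = "")
  invisible(x)
}

#' @export
tidy.qmdmd_trajectory <- function(x, ...) x$frames

#' Run the annealing + production schedule
#'
#' The temperature is ramped to `anneal_start` and stepped down in five
#' 500-t.u. stages by equal decrements ending at the production set-point,
#' after which the production phase runs; only production snapshots are
#' returned.
#'
#' @param system a `qmdmd_system`.
#' @param partition a `qmdmd_partition` or `NULL`.
#' @param potentials a `dmd_potentials`.
#' @param seed integer seed (per-stage seeds are derived from it).
#' @param production a [dmd_params()] for the production phase.
#' @param anneal_start starting reduced temperature of the anneal.
#' @param anneal_steps number of stepped anneal stages.
#' @param anneal_step_duration t.u. per anneal stage.
#' @return the production `qmdmd_trajectory`.
#' @export
run_schedule <- function(system, partition, potentials, seed = 1L,
                         production = dmd_params(seed = seed),
                         anneal_start = 0.20, anneal_steps = 5,
                         anneal_step_duration = 500) {
  temps <- anneal_start -
    (seq_len(anneal_steps) - 1) *
      (anneal_start - production$temperature) / anneal_steps
  cur <- system
  for (s in seq_along(temps)) {
    p <- dmd_params(temperature = temps[s],
                    heat_exchange_rate = production$heat_exchange_rate,
                    duration = anneal_step_duration,
                    save_interval = anneal_step_duration,
                    seed = seed + s)
    tr <- run_phase(cur, partition, potentials, p)
    cur <- tr$final
  }
  prod <- dmd_params(temperature = production$temperature,
                     heat_exchange_rate = production$heat_exchange_rate,
                     duration = production$duration,
                     save_interval = production$save_interval,
                     seed = seed + anneal_steps + 1L)
  run_phase(cur, partition, potentials, prod)
}

#' Clash-removal run
#'
#' A short 1,000-t.u. run at the production temperature with a high heat
#' exchange rate (10 per t.u.), returning only the final frame; an efficient
#' way to relieve bad contacts in a starting structure.
#'
#' @inheritParams run_schedule
#' @param duration run length, t.u.
#' @param temperature reduced temperature.
#' @param exchange_rate ghost-collision rate, 1/t.u.
#' @return the relaxed `qmdmd_system`.
#' @export
remove_clashes <- function(system, partition, potentials, seed = 1L,
                           duration = 1000, temperature = 0.10,
                           exchange_rate = 10) {
  p <- dmd_params(temperature = temperature, heat_exchange_rate = exchange_rate,
                  duration = duration, save_interval = duration, seed = seed)
  tr <- run_phase(system, partition, potentials, p)
  tr$final
}

#' Frozen mask for a DMD phase
#'
#' System frozen flags plus the partition's QM-only core.
#'
#' @param system a `qmdmd_system`.
#' @param partition a `qmdmd_partition` or `NULL`.
#' @return logical vector over atoms.
#' @export
dmd_freeze_mask <- function(system, partition = NULL) {
  mask <- system$atoms$frozen
  if (!is.null(partition)) {
    mask <- mask | system$atoms$atom_id %in% partition$qm_only
  }
  mask
}
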