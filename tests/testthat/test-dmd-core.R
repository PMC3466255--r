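toy_with_potentials <- function(constrained = TRUE) {
  s <- default_toy()$system
  part <- suppressWarnings(assign_domains(s))
  mask <- dmd_freeze_mask(s, part)
  cons <- NULL
  if (constrained) {
    cl <- extract_capped_cluster(s, part)
    cons <- constraints_from_cluster(cl, default_constraint_pairs(s, part))
  }
  list(system = s, partition = part,
       potentials = build_potentials(s, cons, frozen_mask = mask),
       constraints = cons)
}

test_that("potential windows follow the bond/constraint rules", {
  s <- default_toy()$system
  part <- suppressWarnings(assign_domains(s))
  mask <- dmd_freeze_mask(s, part)
  cl <- extract_capped_cluster(s, part)
  cons <- constraints_from_cluster(cl, rbind(default_constraint_pairs(s, part)[1, ]))
  pot <- build_potentials(s, cons, frozen_mask = mask)

  # locate the constraint pair and check its hard window target +/- 0.01
  ci <- pot$cons_idx + 1L
  off <- pot$radii_off
  rads <- pot$radii[(off[ci] + 1):off[ci + 1]]
  expect_equal(rads, c(cons$target[1] - 0.01, cons$target[1] + 0.01),
               tolerance = 1e-12)
  ens <- pot$energies[(off[ci] + ci):(off[ci + 1] + ci)]
  expect_identical(ens, c(Inf, 0, Inf))

  # a bond well spans +/- 5% of the reference length (pick a bond that is
  # neither constrained nor frozen-frozen)
  conskey <- paste(pmin(cons$i, cons$j), pmax(cons$i, cons$j))
  mask_of <- function(id) dmd_freeze_mask(s, part)[match(id, s$atoms$atom_id)]
  cand <- which(!(paste(pmin(s$bonds$i, s$bonds$j),
                        pmax(s$bonds$i, s$bonds$j)) %in% conskey) &
                  !(mask_of(s$bonds$i) & mask_of(s$bonds$j)))
  b1 <- s$bonds[cand[1], ]
  ri <- match(b1$i, s$atoms$atom_id) - 1L
  rj <- match(b1$j, s$atoms$atom_id) - 1L
  prow <- which((pot$pair_i == ri & pot$pair_j == rj) |
                (pot$pair_i == rj & pot$pair_j == ri))
  expect_length(prow, 1L)
  rads <- pot$radii[(off[prow] + 1):off[prow + 1]]
  expect_equal(rads, c(0.95, 1.05) * b1$ref_length, tolerance = 1e-12)

  # no frozen-frozen pairs are emitted
  expect_false(any(mask[pot$pair_i + 1L] & mask[pot$pair_j + 1L]))
  # the metal carries no nonbonded terms (it appears only via freezing)
  mrow0 <- match(s$roles$metal, s$atoms$atom_id) - 1L
  expect_false(any(pot$pair_i == mrow0 | pot$pair_j == mrow0))
})

test_that("conflicting windows on one pair are an error", {
  s <- default_toy()$system
  part <- suppressWarnings(assign_domains(s))
  cl <- extract_capped_cluster(s, part)
  b1 <- s$bonds[1, ]
  cons <- constraints_from_cluster(cl, rbind(c(b1$i, b1$j)))
  cons$target <- b1$ref_length * 2   # far outside the bond well
  expect_error(build_potentials(s, cons, frozen_mask = dmd_freeze_mask(s, part)),
               "conflicting")
})

test_that("event-driven propagation conserves energy exactly between thermostat events", {
  # two atoms bound in one infinite well, thermostat off
  at <- tibble::tibble(
    atom_id = 1:2, element = "C", atom_name = c("C1", "C2"),
    residue_name = "LIG", residue_id = 1L, chain_id = "A",
    x = c(0, 1.5), y = 0, z = 0, mass = 12.011, frozen = FALSE
  )
  s2 <- new_system(at, tibble::tibble(i = 1L, j = 2L, ref_length = 1.5),
                   roles = list())
  pot <- build_potentials(s2, NULL, frozen_mask = c(FALSE, FALSE))
  p <- dmd_params(temperature = 0.5, heat_exchange_rate = 1e-9,
                  duration = 20000, save_interval = 400, seed = 3)
  tr <- run_phase(s2, NULL, pot, p, track_energy = TRUE)
  expect_gt(tr$n_events, 1e3)
  expect_lte(tr$max_energy_drift, 1e-9)
})

test_that("snapshot accounting and determinism hold for a short phase", {
  tw <- toy_with_potentials()
  p <- dmd_params(duration = 200, save_interval = 10, seed = 11)
  tr1 <- run_phase(tw$system, tw$partition, tw$potentials, p)
  expect_equal(nrow(tr1$frames), 20L)
  expect_equal(diff(tr1$frames$time), rep(10, 19))

  tr2 <- run_phase(tw$system, tw$partition, tw$potentials, p)
  expect_identical(tr1$positions, tr2$positions)

  # frozen atoms are bit-identical across the whole trajectory
  mask <- tw$potentials$frozen_mask
  for (f in c(1, 10, 20)) {
    expect_identical(tr1$positions[mask, , f], unname(coords(tw$system)[mask, ]))
  }
})

test_that("constraint windows are never violated during sampling", {
  tw <- toy_with_potentials()
  p <- dmd_params(duration = 500, save_interval = 10, seed = 2)
  tr <- run_phase(tw$system, tw$partition, tw$potentials, p)
  expect_lte(max(tr$constraint_maxdev), 0.01 + 1e-9)
})

test_that("the annealing schedule returns only production snapshots", {
  tw <- toy_with_potentials()
  prod <- dmd_params(duration = 400, save_interval = 20, seed = 5)
  tr <- run_schedule(tw$system, tw$partition, tw$potentials, seed = 5,
                     production = prod,
                     anneal_steps = 2, anneal_step_duration = 50)
  expect_equal(nrow(tr$frames), 20L)
  expect_equal(max(tr$frames$time), 400)
  expect_equal(min(tr$frames$time), 20)
})

test_that("clash removal relieves overlaps and is reproducible", {
  s <- distort(default_toy()$system, 0.3, seed = 9)
  pot <- build_potentials(s, NULL, frozen_mask = s$atoms$frozen)
  out1 <- suppressWarnings(remove_clashes(s, NULL, pot, seed = 4))
  out2 <- suppressWarnings(remove_clashes(s, NULL, pot, seed = 4))
  expect_identical(coords(out1), coords(out2))
  # the relieved structure enters a phase without clash-relief warnings
  expect_no_warning(run_phase(out1, NULL, pot,
                              dmd_params(duration = 50, save_interval = 10,
                                         seed = 1)))
})

test_that("a fully frozen system yields identical snapshots", {
  s <- default_toy()$system
  mask <- rep(TRUE, nrow(s$atoms))
  pot <- build_potentials(s, NULL, frozen_mask = mask)
  tr <- run_phase(s, NULL, pot, dmd_params(duration = 50, save_interval = 10,
                                           seed = 1))
  for (f in seq_len(nrow(tr$frames))) {
    expect_identical(tr$positions[, , f], unname(coords(s)))
  }
})
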