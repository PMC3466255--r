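small_production <- function(seed = 1L) {
  dmd_params(duration = 500, save_interval = 10, seed = seed)
}

test_that("the acceptance rule carries the lower-energy structure and logs both", {
  ts <- default_toy()
  s <- ts$system
  be <- surrogate_backend(s)
  sub <- qmdmd:::qm_subset_ids(s)
  worse <- distort(s, 0.2, seed = 3)

  acc <- accept_iteration(worse, s, sub, be)
  expect_equal(acc$carried, "output")
  expect_lte(acc$energy_output, acc$energy_input)

  acc2 <- accept_iteration(s, worse, sub, be)
  expect_equal(acc2$carried, "input")
  expect_identical(coords(acc2$structure), coords(s))

  # equal energies prefer the output (progress)
  acc3 <- accept_iteration(s, s, sub, be)
  expect_equal(acc3$carried, "output")
})

test_that("zero iterations return an empty history", {
  s <- default_toy()$system
  run <- suppressWarnings(run_qmdmd(s, n_iterations = 0, seed = 1,
                                    production = small_production()))
  expect_length(run$history, 0)
  expect_equal(nrow(run$convergence), 0L)
  expect_s3_class(run$final, "qmdmd_system")
})

test_that("a fixed seed reproduces the run bit for bit", {
  s <- distort(default_toy()$system, 0.15, seed = 5)
  r1 <- suppressWarnings(run_qmdmd(s, n_iterations = 1, seed = 42,
                                   production = small_production(42)))
  r2 <- suppressWarnings(run_qmdmd(s, n_iterations = 1, seed = 42,
                                   production = small_production(42)))
  expect_identical(coords(r1$final), coords(r2$final))
  expect_identical(r1$convergence, r2$convergence)
})

test_that("the carried-forward subset energy is non-increasing across iterations", {
  ts <- default_toy()
  s <- distort(ts$system, 0.3, seed = 8)
  run <- suppressWarnings(run_qmdmd(s, n_iterations = 3, seed = 8,
                                    production = small_production(8),
                                    ground_truth = ts$truth$native_positions))
  expect_true(all(diff(run$convergence$qm_energy) <= 1e-9))
  expect_true(all(is.finite(run$convergence$backbone_rmsd)))
  expect_equal(nrow(run$convergence), 3L)
  # tidiers
  expect_identical(tidy(run), run$convergence)
  expect_equal(glance(run)$n_iterations, 3L)
})

test_that("static-cluster mode optimizes without sampling and is deterministic", {
  ts <- default_toy()
  s <- ts$system
  cl1 <- suppressWarnings(static_cluster_mode(s))
  expect_equal(attr(cl1, "mode"), "no-repacking control")
  # native input is already a minimum: essentially unchanged
  disp <- sqrt(rowSums((qmdmd:::cluster_coords(cl1)[seq_along(cl1$member_ids), ] -
                          cl1$source_positions)^2))
  expect_lt(max(disp), 0.05)

  cl2 <- suppressWarnings(static_cluster_mode(s))
  expect_identical(qmdmd:::cluster_coords(cl1), qmdmd:::cluster_coords(cl2))

  # swapping in a larger cation lengthens the metal-donor contacts
  v <- make_metal_variant(s, 1.00, 2, "CA")
  clv <- suppressWarnings(static_cluster_mode(v))
  m <- s$roles$metal
  dn <- donor_atoms(s)
  d_of <- function(cl) {
    xyz <- qmdmd:::cluster_coords(cl)
    ids <- cl$atoms$atom_id
    vapply(dn, function(d) sqrt(sum((xyz[match(m, ids), ] -
                                       xyz[match(d, ids), ])^2)), numeric(1))
  }
  expect_true(all(d_of(clv) > d_of(cl1)))
})
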