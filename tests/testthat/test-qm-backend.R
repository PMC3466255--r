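test_that("analytic gradients agree with central differences on random geometries", {
  s <- default_toy()$system
  be <- surrogate_backend(s)
  ids <- s$atoms$atom_id
  set.seed(11)
  worst <- 0
  for (g in 1:20) {
    xyz <- coords(s) + matrix(rnorm(3 * nrow(s$atoms), 0, 0.15), ncol = 3)
    ana <- qmdmd:::surrogate_eval(be, xyz, ids, TRUE)$gradient
    # probe 5 random coordinates per geometry
    for (probe in 1:5) {
      r <- sample(nrow(xyz), 1); cc <- sample(3, 1)
      h <- 1e-6
      xp <- xyz; xp[r, cc] <- xp[r, cc] + h
      xm <- xyz; xm[r, cc] <- xm[r, cc] - h
      num <- (qmdmd:::surrogate_eval(be, xp, ids, FALSE)$energy -
                qmdmd:::surrogate_eval(be, xm, ids, FALSE)$energy) / (2 * h)
      denom <- max(abs(num), 1)
      worst <- max(worst, abs(ana[r, cc] - num) / denom)
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("the energy is invariant under rigid rotation and translation", {
  s <- default_toy()$system
  be <- surrogate_backend(s)
  ids <- s$atoms$atom_id
  e0 <- backend_energy(be, s)
  th <- 0.63
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  e1 <- backend_energy(be, coords(s) %*% R + 2.5, ids = ids)
  expect_lt(abs(e1 - e0), 1e-9)
})

test_that("an isolated 12-6 pair at its minimum separation gives the well depth", {
  at <- tibble::tibble(
    atom_id = 1:2, element = "C", atom_name = c("C1", "C2"),
    residue_name = "LIG", residue_id = 1L, chain_id = "A",
    x = c(0, 10), y = 0, z = 0, mass = 12.011, frozen = FALSE
  )
  s2 <- new_system(at, tibble::tibble(i = integer(), j = integer(),
                                      ref_length = numeric()), roles = list())
  pars <- surrogate_params(lj_eps = 0.07)
  be <- surrogate_backend(s2, pars)
  expect_equal(nrow(be$lj), 1L)
  rmin <- be$lj$rmin[1]
  xyz <- rbind(c(0, 0, 0), c(rmin, 0, 0))
  expect_equal(backend_energy(be, xyz, ids = 1:2), -0.07, tolerance = 1e-12)
})

test_that("partial optimization honors frozen atoms and degenerate inputs", {
  s <- default_toy()$system
  be <- surrogate_backend(s)
  frz <- s$atoms$atom_id[s$atoms$frozen]

  # already at (essentially) a minimum: nothing moves appreciably
  opt1 <- partial_optimize(s, be, frozen = frz, tol = 1e-4)
  opt2 <- partial_optimize(opt1, be, frozen = frz, tol = 1e-4)
  expect_lt(max(abs(coords(opt2) - coords(opt1))), 1e-3)
  expect_identical(coords(opt1)[s$atoms$frozen, ], coords(s)[s$atoms$frozen, ])

  # everything frozen: identity with a flag
  all_ids <- s$atoms$atom_id
  opt3 <- partial_optimize(s, be, frozen = all_ids)
  expect_identical(coords(opt3), coords(s))
  expect_true(attr(opt3, "nothing_to_optimize"))
})

test_that("a single free atom relaxes into its harmonic well", {
  at <- tibble::tibble(
    atom_id = 1:2, element = "C", atom_name = c("C1", "C2"),
    residue_name = "LIG", residue_id = 1L, chain_id = "A",
    x = c(0, 2.0), y = 0, z = 0, mass = 12.011, frozen = c(TRUE, FALSE)
  )
  s2 <- new_system(at, tibble::tibble(i = 1L, j = 2L, ref_length = 1.5),
                   roles = list())
  be <- surrogate_backend(s2)
  opt <- partial_optimize(s2, be, frozen = 1L, tol = 1e-8)
  expect_equal(atom_distance(opt, 1, 2), 1.5, tolerance = 1e-6)
})

test_that("harmonic frequencies reproduce the closed form sqrt(k/m)", {
  # one free atom on a k = 300 bond to a frozen partner: the stretch mode has
  # omega = sqrt(2k/m) in internal units
  at <- tibble::tibble(
    atom_id = 1:2, element = "C", atom_name = c("C1", "C2"),
    residue_name = "LIG", residue_id = 1L, chain_id = "A",
    x = c(0, 1.5), y = 0, z = 0, mass = 12.011, frozen = c(TRUE, FALSE)
  )
  s2 <- new_system(at, tibble::tibble(i = 1L, j = 2L, ref_length = 1.5),
                   roles = list())
  be <- surrogate_backend(s2)
  h <- cluster_hessian(s2, be, free_atoms = 2L)
  omega_expected <- sqrt(2 * 300 / 12.011)
  expect_equal(max(h$frequencies), omega_expected, tolerance = 1e-4)
  expect_equal(h$n_imaginary, 0L)
  expect_gt(h$zpe, 0)
})

test_that("the two-well transfer term has clean minima and one saddle", {
  tt <- transfer_triple(barrier = 5)
  rea <- find_minimum(tt$system, tt$backend, frozen = c(1L, 3L))
  expect_equal(rea$n_imaginary, 0L)
  ts <- find_ts(rea, find_product(rea, tt$backend, frozen = c(1L, 3L)),
                tt$backend, frozen = c(1L, 3L))
  expect_equal(ts$n_imaginary, 1L)
})

test_that("metal charge deepens the metal-donor attraction at fixed geometry", {
  s <- default_toy()$system
  e_q <- function(q) {
    v <- make_metal_variant(s, 0.72, q)
    be <- surrogate_backend(v)
    m <- be$morse
    sum(m$D * ((1 - exp(-m$a * (vapply(seq_len(nrow(m)), function(r)
      atom_distance(v, m$i[r], m$j[r]), numeric(1)) - m$r0)))^2 - 1))
  }
  expect_gt(e_q(2), e_q(2.5))
  expect_gt(e_q(2.5), e_q(3))
})

test_that("hessian at a non-stationary geometry is flagged", {
  s <- distort(default_toy()$system, 0.2, seed = 2)
  be <- surrogate_backend(s)
  expect_warning(cluster_hessian(s, be), "non-stationary")
})
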