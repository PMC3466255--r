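test_that("every requested native metric is met exactly at construction", {
  ts <- default_toy()
  tgt <- c(ts$truth$spec$native_distances, ts$truth$spec$native_angles)
  got <- ts$truth$native_metrics[names(tgt)]
  expect_lt(max(abs(got - tgt)), 1e-6)
  # the experimental water coordination distance in particular
  expect_equal(unname(ts$truth$native_metrics[["Metal-O(water)"]]), 2.04,
               tolerance = 1e-9)
})

test_that("construction is deterministic and honors component switches", {
  a <- make_toy_site(toy_site_spec())
  b <- make_toy_site(toy_site_spec())
  expect_identical(coords(a$system), coords(b$system))

  bare <- make_toy_site(toy_site_spec(include_substrate = FALSE,
                                      include_donor = FALSE,
                                      include_base = FALSE))
  expect_false("o_acceptor" %in% names(bare$system$key_atoms))
  expect_null(bare$system$roles$substrate)
})

test_that("infeasible native distances fail with the offending pair named", {
  expect_error(
    make_toy_site(toy_site_spec(native_distances = c("Metal-O2(Sub)" = 8))),
    "O1\\(Sub\\)-O2\\(Sub\\)"
  )
  expect_error(
    make_toy_site(toy_site_spec(native_distances = c("O(Arm1)-O(water)" = 10))),
    "O\\(Arm1\\)-O\\(water\\)"
  )
})

test_that("distortion is Gaussian on free atoms and leaves frozen atoms alone", {
  s <- default_toy()$system
  expect_identical(distort(s, 0, seed = 1), s)
  expect_error(distort(s, -0.1), "sigma")

  d <- distort(s, 0.5, seed = 7)
  frozen <- s$atoms$frozen
  expect_identical(coords(d)[frozen, ], coords(s)[frozen, ])
  expect_identical(d$bonds, s$bonds)

  # per-component |dx| has the half-normal mean sigma*sqrt(2/pi); use many
  # draws across seeds and check within 3 standard errors
  sigma <- 0.5
  deltas <- unlist(lapply(1:30, function(sd) {
    dd <- distort(s, sigma, seed = sd)
    abs(coords(dd)[!frozen, ] - coords(s)[!frozen, ])
  }))
  mu_expect <- sigma * sqrt(2 / pi)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - mu_expect), 3 * se)
})

test_that("metal variants change parameters, never geometry", {
  s <- default_toy()$system
  v <- make_metal_variant(s, 1.00, 2, "CA")
  expect_identical(coords(v), coords(s))
  expect_equal(v$metal_params$radius, 1.00)
  expect_equal(v$metal_params$label, "CA")

  v2 <- make_metal_variant(s, 0.78, 3)
  expect_equal(v2$metal_params$charge, s$metal_params$charge + 1)

  # unknown label with explicit parameters is accepted
  v3 <- make_metal_variant(s, 0.9, 2, "XX")
  expect_equal(v3$metal_params$label, "XX")
})

test_that("the native geometry is a backend minimum (no atom moves > 0.05 A)", {
  ts <- default_toy()
  s <- ts$system
  be <- surrogate_backend(s)
  opt <- partial_optimize(s, be, frozen = s$atoms$atom_id[s$atoms$frozen],
                          tol = 1e-5)
  disp <- sqrt(rowSums((coords(opt) - coords(s))^2))
  expect_lt(max(disp), 0.05)
})

test_that("larger metal radius strictly lengthens every equilibrium metal-donor distance", {
  s <- default_toy()$system
  frz <- s$atoms$atom_id[s$atoms$frozen]
  m <- s$roles$metal
  dn <- donor_atoms(s)
  eq_dists <- function(radius) {
    v <- make_metal_variant(s, radius, 2)
    o <- partial_optimize(v, surrogate_backend(v), frozen = frz, tol = 1e-4)
    vapply(dn, function(d) atom_distance(o, m, d), numeric(1))
  }
  d1 <- eq_dists(0.72); d2 <- eq_dists(0.86); d3 <- eq_dists(1.00)
  expect_true(all(d2 > d1))
  expect_true(all(d3 > d2))
})
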