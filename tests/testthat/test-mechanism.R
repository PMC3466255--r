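test_that("the quartic double well is solved to closed form", {
  b <- 5
  tt <- transfer_triple(barrier = b)
  rea <- find_minimum(tt$system, tt$backend, frozen = c(1L, 3L))
  expect_equal(rea$kind, "reactant")
  expect_equal(rea$n_imaginary, 0L)
  expect_equal(rea$energy, 0, tolerance = 1e-8)

  prod <- find_product(rea, tt$backend, frozen = c(1L, 3L))
  expect_equal(prod$kind, "product")
  expect_equal(prod$n_imaginary, 0L)
  expect_lt(prod$metrics$xi, 0)

  ts <- find_ts(rea, prod, tt$backend, frozen = c(1L, 3L))
  expect_equal(ts$n_imaginary, 1L)
  expect_true(attr(ts, "polished"))
  # symmetric well: saddle at xi = 0, barrier exactly b
  expect_lt(abs(ts$metrics$xi), 1e-6)
  expect_lt(abs((ts$energy - rea$energy) - b), 1e-6)
  expect_true(ts$mode_on_transfer_group)
})

test_that("a start at the barrier top is flagged as a saddle, not accepted silently", {
  tt <- transfer_triple(barrier = 5)
  sys <- tt$system
  # place the methyl exactly between the wells (xi = 0)
  sys <- set_coords(sys, rbind(c(0, 0, 0), c(2.255, 0, 0), c(4.51, 0, 0)))
  expect_warning(find_minimum(sys, tt$backend, frozen = c(1L, 3L)),
                 "imaginary")
})

test_that("raising the asymmetry moves the saddle toward the product (Hammond)", {
  xi_ts <- vapply(c(0, 1, 2, 3, 4), function(d) {
    tt <- transfer_triple(barrier = 6, delta0 = d)
    rea <- find_minimum(tt$system, tt$backend, frozen = c(1L, 3L))
    prod <- find_product(rea, tt$backend, frozen = c(1L, 3L))
    ts <- find_ts(rea, prod, tt$backend, frozen = c(1L, 3L))
    ts$metrics$xi
  }, numeric(1))
  expect_true(all(diff(xi_ts) < 0))
})

test_that("an ensemble of identical reactants has zero spread", {
  s <- default_toy()$system
  part <- suppressWarnings(assign_domains(s))
  be <- surrogate_backend(s)
  cl <- extract_capped_cluster(s, part)
  prof <- suppressWarnings(reaction_profile(list(cl, cl), be, n_scan = 21))
  expect_equal(prof$n_excluded, 0L)
  expect_equal(prof$summary$sd[prof$summary$quantity == "dE_ts"], 0,
               tolerance = 1e-6)
  expect_equal(prof$summary$sd[prof$summary$quantity == "dE_rxn"], 0,
               tolerance = 1e-6)
  expect_gt(glance(prof)$mean_dE_ts, 0)
})

test_that("the abstracted proton elongates monotonically along the reaction", {
  s <- default_toy()$system
  part <- suppressWarnings(assign_domains(s))
  be <- surrogate_backend(s)
  cl <- extract_capped_cluster(s, part)
  rea <- suppressWarnings(find_minimum(cl, be))
  prod <- suppressWarnings(find_product(rea, be, n_scan = 21))
  ts <- suppressWarnings(find_ts(rea, prod, be, n_scan = 21))

  track <- base_proton_track(list(prod, rea, ts))
  expect_equal(track$kind, c("reactant", "ts", "product"))
  expect_true(attr(track, "monotone"))
  expect_gt(diff(range(track$r_oh_base)), 0.5)

  # coupling off: R(O-H) stays at its reference value
  be_off <- surrogate_backend(s, surrogate_params(couple_proton = FALSE))
  rea0 <- suppressWarnings(find_minimum(cl, be_off))
  prod0 <- suppressWarnings(find_product(rea0, be_off, n_scan = 21))
  expect_equal(rea0$metrics$r_oh_base, prod0$metrics$r_oh_base,
               tolerance = 0.02)

  # no base site: absent marker, not zero
  tt <- transfer_triple()
  rea3 <- find_minimum(tt$system, tt$backend, frozen = c(1L, 3L))
  track3 <- base_proton_track(list(rea3))
  expect_true(is.na(track3$r_oh_base))
  expect_true(is.na(attr(track3, "monotone")))
})
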