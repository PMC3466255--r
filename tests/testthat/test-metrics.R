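triangle_system <- function() {
  at <- tibble::tibble(
    atom_id = 1:3, element = c("O", "C", "N"),
    atom_name = c("O1", "C1", "N1"), residue_name = "TRI",
    residue_id = 1L, chain_id = "A",
    x = c(0, 0, 3), y = c(0, 0, 4), z = 0,
    mass = c(15.999, 12.011, 14.007), frozen = FALSE
  )
  new_system(at, tibble::tibble(i = integer(), j = integer(),
                                ref_length = numeric()), roles = list())
}

test_that("distances and interior angles follow plane geometry", {
  s <- triangle_system()
  rsel <- function(atom) list(residue = "TRI", atom = atom)
  d <- metric_spec("d", "distance", list(rsel("C1"), rsel("N1")))
  expect_equal(measure(s, d), 5)  # 3-4-5 triangle

  s2 <- triangle_system()
  s2 <- set_coords(s2, rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)))
  a <- metric_spec("a", "angle", list(rsel("O1"), rsel("C1"), rsel("N1")))
  expect_equal(measure(s2, a), 90)

  s3 <- set_coords(s2, rbind(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)))
  expect_equal(measure(s3, a), 180)

  # rigid-motion invariance
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  s4 <- set_coords(s2, coords(s2) %*% R + 5)
  expect_equal(measure(s4, a), measure(s2, a), tolerance = 1e-9)
})

test_that("selector failures are informative", {
  s <- triangle_system()
  bad <- metric_spec("bad", "distance",
                     list(list(residue = "TRI", atom = "XX"),
                          list(residue = "TRI", atom = "C1")))
  expect_error(measure(s, bad), "matches no atom")
  amb <- metric_spec("amb", "distance",
                     list(list(residue = "TRI"), list(residue = "TRI", atom = "C1")))
  expect_error(measure(s, amb), "ambiguous")
})

test_that("ensemble tables render mean (sd) in table style", {
  s <- triangle_system()
  rsel <- function(atom) list(residue = "TRI", atom = atom)
  sp <- metric_spec("C-N", "distance", list(rsel("C1"), rsel("N1")))
  # two snapshots at 2.0 and 2.2: hand arithmetic 2.10 (0.14)
  s1 <- set_coords(s, rbind(c(0, 0, 0), c(0, 0, 0), c(2.0, 0, 0)))
  s2 <- set_coords(s, rbind(c(0, 0, 0), c(0, 0, 0), c(2.2, 0, 0)))
  tab <- ensemble_table(list(s1, s2), list(sp))
  expect_equal(tab$rendered, "2.10 (0.14)")
  expect_equal(tab$mean, 2.1)
  # brute-force recomputation agrees exactly
  vals <- c(measure(s1, sp), measure(s2, sp))
  expect_identical(tab$mean, mean(vals))
  expect_identical(tab$sd, sd(vals))

  one <- ensemble_table(list(s1), list(sp))
  expect_equal(one$rendered, "2.00 (0.00)")
  expect_equal(one$n, 1L)
  expect_match(attr(one, "note"), "n = 1")
})

test_that("ensemble spread of a thermal pair matches equipartition", {
  # a single harmonic bond sampled at temperature theta has
  # sd(r) ~ sqrt(theta / (2 k)); sample independently with Metropolis on the
  # backend surface and compare
  at <- tibble::tibble(
    atom_id = 1:2, element = "C", atom_name = c("C1", "C2"),
    residue_name = "LIG", residue_id = 1L, chain_id = "A",
    x = c(0, 1.5), y = 0, z = 0, mass = 12.011, frozen = c(TRUE, FALSE)
  )
  s2 <- new_system(at, tibble::tibble(i = 1L, j = 2L, ref_length = 1.5),
                   roles = list())
  be <- surrogate_backend(s2)   # k_bond = 300
  theta <- 0.10
  snaps <- metropolis_snapshots(s2, be, theta, n = 1500, step = 0.05, seed = 4)
  sp <- metric_spec("r", "distance",
                    list(list(residue = "LIG", atom = "C1"),
                         list(residue = "LIG", atom = "C2")))
  tab <- ensemble_table(snaps, list(sp))
  expect_equal(tab$sd, sqrt(theta / (2 * 300)), tolerance = 0.1)
})

test_that("variant comparison flags directions and rejects mismatched tables", {
  s <- default_toy()$system
  specs <- default_metric_specs(s)
  t_ref <- ensemble_table(list(s), specs)
  expect_true(all(grepl("longer|shorter|equal",
                        compare_variants(list(mg = t_ref, same = t_ref))$vs_ref_same)))
  expect_true(all(compare_variants(list(mg = t_ref, same = t_ref))$vs_ref_same == "equal"))

  # relaxed Ca variant: all metal-donor rows flagged longer
  frz <- s$atoms$atom_id[s$atoms$frozen]
  v <- make_metal_variant(s, 1.00, 2, "CA")
  vopt <- partial_optimize(v, surrogate_backend(v), frozen = frz, tol = 1e-4)
  t_ca <- ensemble_table(list(vopt), specs)
  cmp <- compare_variants(list(mg = t_ref, ca = t_ca))
  donor_rows <- cmp$label %in% c("Metal-O1(Arm1)", "Metal-O(Arm2)",
                                 "Metal-O1(Arm3)", "Metal-O(water)",
                                 "Metal-O1(Sub)", "Metal-O2(Sub)")
  expect_true(all(cmp$vs_ref_ca[donor_rows] == "longer"))

  t_short <- t_ref[-1, ]
  expect_error(compare_variants(list(mg = t_ref, bad = t_short)), "different metrics")
})
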