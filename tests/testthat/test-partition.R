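test_that("domain assignment finds the metal's six donors and covers all atoms", {
  s <- default_toy()$system
  part <- suppressWarnings(assign_domains(s, coordination_cutoff = 2.6))

  # independent oracle: direct distance scan over heavy atoms
  xyz <- coords(s)
  mrow <- match(s$roles$metal, s$atoms$atom_id)
  d <- sqrt(rowSums(sweep(xyz, 2, xyz[mrow, ])^2))
  donors_oracle <- s$atoms$atom_id[d > 0 & d <= 2.6 & s$atoms$element != "H"]
  expect_equal(length(donors_oracle), 6L)
  expect_setequal(part$qm_only, c(s$roles$metal, donors_oracle))

  # disjoint cover
  all_ids <- sort(c(part$qm_only, part$qm_dmd, part$dmd_only))
  expect_equal(all_ids, sort(s$atoms$atom_id))
})

test_that("an empty QM selection is rejected", {
  s <- default_toy()$system
  expect_error(assign_domains(s, qm_selection = list()), "non-empty")
})

test_that("a single-arm selection yields exactly one boundary bond", {
  s <- default_toy()$system
  part <- assign_domains(s, qm_selection = list(qm_rule("AR2", "L2", "ANC")))
  expect_equal(nrow(part$boundary_bonds), 1L)
  expect_error(
    assign_domains(s, qm_selection = list(qm_rule("NOPE", "L2", "ANC"))),
    "missing residue"
  )
})

test_that("cap hydrogens sit at 0.7052 R along the severed bond for any geometry", {
  s <- default_toy()$system
  part <- suppressWarnings(assign_domains(s))
  cl <- extract_capped_cluster(s, part)
  expect_equal(nrow(cl$caps), nrow(part$boundary_bonds))
  xyz <- coords(s)
  for (k in seq_len(nrow(cl$caps))) {
    cp <- cl$caps[k, ]
    pin <- xyz[match(cp$parent, s$atoms$atom_id), ]
    pout <- xyz[match(cp$source_outer, s$atoms$atom_id), ]
    capv <- c(cp$x, cp$y, cp$z) - pin
    bondv <- pout - pin
    ratio <- sqrt(sum(capv^2)) / sqrt(sum(bondv^2))
    expect_lt(abs(ratio - 0.7052), 1e-9)
    cosang <- sum(capv * bondv) / sqrt(sum(capv^2) * sum(bondv^2))
    expect_lt(abs(cosang - 1), 1e-12)
  }
  # worked case: bond of 1.50 A gives a 1.0578 A cap; (0,0,0)-(2,0,0) gives
  # a cap at (1.4104, 0, 0)
  expect_equal(0.7052 * 1.50, 1.0578)
  expect_equal(0.7052 * 2, 1.4104)

  # caps + their inner partners are the QM-frozen set
  expect_setequal(cl$frozen_in_qm, c(cl$caps$atom_id, cl$caps$parent))
  # the sampler's frozen set is the QM-only core
  expect_setequal(cl$frozen_in_dmd, part$qm_only)
})

test_that("constraints copy current cluster distances and reject caps/duplicates", {
  s <- default_toy()$system
  part <- suppressWarnings(assign_domains(s))
  cl <- extract_capped_cluster(s, part)
  pairs <- default_constraint_pairs(s, part)
  expect_gte(nrow(pairs), 5)

  cons <- constraints_from_cluster(cl, pairs)
  expect_s3_class(cons, "constraint_set")
  for (r in seq_len(nrow(cons))) {
    expect_equal(cons$target[r], atom_distance(s, cons$i[r], cons$j[r]),
                 tolerance = 1e-12)
  }
  expect_true(all(cons$half_width == 0.01))

  expect_equal(nrow(constraints_from_cluster(cl, NULL)), 0L)
  expect_warning(constraints_from_cluster(cl, rbind(pairs, pairs[1, ])),
                 "duplicate")
  cap_id <- cl$caps$atom_id[1]
  expect_error(constraints_from_cluster(cl, rbind(c(cap_id, pairs[1, 1]))),
               "cap")
})

test_that("extract then reinstall is the identity; moved members propagate; caps vanish", {
  s <- default_toy()$system
  part <- suppressWarnings(assign_domains(s))
  cl <- extract_capped_cluster(s, part)

  s_back <- reinstall_cluster(s, cl)
  expect_identical(coords(s_back), coords(s))

  # move one member 0.2 A
  cl2 <- cl
  row <- match(cl$member_ids[5], cl2$atoms$atom_id)
  cl2$atoms$x[row] <- cl2$atoms$x[row] + 0.2
  s2 <- reinstall_cluster(s, cl2)
  moved <- which(rowSums(abs(coords(s2) - coords(s))) > 0)
  expect_equal(s$atoms$atom_id[moved], cl$member_ids[5])

  # cap ids never appear in the reinstalled system
  expect_false(any(cl$caps$atom_id %in% s2$atoms$atom_id))

  # large displacement warns about boundary mismatch
  cl3 <- cl
  cl3$atoms$x[row] <- cl3$atoms$x[row] + 8
  expect_warning(reinstall_cluster(s, cl3), "boundary mismatch")
})

test_that("severing a non-C/N boundary bond is flagged", {
  s <- default_toy()$system
  expect_warning(assign_domains(s), "non-C/N")
})
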