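test_that("Kabsch RMSD is zero on identity and rigid transforms", {
  set.seed(1)
  A <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_rmsd(A, A), 0, tolerance = 1e-12)

  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  B <- A %*% R + matrix(rep(c(1, -2, 3), each = nrow(A)), ncol = 3)
  expect_lt(kabsch_rmsd(A, B), 1e-9)

  expect_error(kabsch_rmsd(A[1:2, ], A[1:2, ]), "3 atoms")
})

test_that("Kabsch RMSD matches a brute-force rotational search", {
  set.seed(42)
  for (case in 1:12) {
    n <- sample(4:10, 1)
    A <- matrix(rnorm(3 * n), ncol = 3)
    B <- A + matrix(rnorm(3 * n, 0, 0.3), ncol = 3)
    expect_lt(abs(kabsch_rmsd(A, B) - brute_force_rmsd(A, B)), 1e-8)
  }
})

make_two_pose_traj <- function(n_a = 10, n_b = 10) {
  s <- default_toy()$system
  heavy <- s$atoms$element != "H"
  pose_a <- coords(s)
  pose_b <- pose_a
  free <- which(!s$atoms$frozen)
  set.seed(3)
  pose_b[free, ] <- pose_b[free, ] + matrix(rnorm(3 * length(free), 0, 1.2),
                                            ncol = 3)
  frames <- c(replicate(n_a, pose_a + rnorm(length(pose_a), 0, 0.01),
                        simplify = FALSE),
              replicate(n_b, pose_b + rnorm(length(pose_b), 0, 0.01),
                        simplify = FALSE))
  pos <- array(unlist(frames), dim = c(nrow(pose_a), 3, n_a + n_b))
  structure(list(
    atoms = s$atoms, roles = s$roles, positions = pos,
    frames = tibble::tibble(frame = seq_len(n_a + n_b),
                            time = 10 * seq_len(n_a + n_b),
                            potential_energy = rnorm(n_a + n_b),
                            kinetic_energy = 0)
  ), class = "qmdmd_trajectory")
}

test_that("average-linkage clustering splits well-separated poses perfectly", {
  tr <- make_two_pose_traj()
  asg <- cluster_ensemble(tr, k = 2)
  expect_length(unique(asg[1:10]), 1)
  expect_length(unique(asg[11:20]), 1)
  expect_false(asg[1] == asg[11])

  expect_equal(cluster_ensemble(tr, k = 1), rep(1L, 20))
  expect_error(cluster_ensemble(tr, k = 21), "exceeds")
})

test_that("representatives match exhaustive centroid and energy scans", {
  tr <- make_two_pose_traj(25, 25)
  M <- rmsd_matrix(tr)
  asg <- cluster_ensemble(tr, k = 2, dist_matrix = M)
  reps <- select_representatives(asg, tr, dist_matrix = M)
  expect_equal(nrow(reps), 4L)

  for (cl in 1:2) {
    members <- which(asg == cl)
    # exhaustive double-loop centroid oracle
    sums <- vapply(members, function(m) sum(M[m, members]), numeric(1))
    cent_oracle <- members[which.min(sums)]
    emin_oracle <- members[which.min(tr$frames$potential_energy[members])]
    expect_equal(reps$snapshot[reps$cluster == cl & reps$role == "centroid"],
                 cent_oracle)
    expect_equal(reps$snapshot[reps$cluster == cl & reps$role == "min_energy"],
                 emin_oracle)
  }

  # singleton cluster: both representatives coincide
  asg1 <- asg; asg1[1] <- 3L
  reps1 <- select_representatives(asg1, tr, dist_matrix = M)
  expect_equal(unique(reps1$snapshot[reps1$cluster == 3]), 1L)
})

test_that("rank-sum scoring picks dominated winners and breaks ties as stated", {
  reps <- tibble::tibble(cluster = 1:2, snapshot = c(5L, 9L),
                         role = "centroid", dmd_energy = c(-3, -1))
  # dominant in both energies
  ch <- score_and_choose(reps, qm_energies = c(-10, -5))
  expect_equal(ch$snapshot, 5L)

  # QM ranks 1,2 vs DMD ranks 2,1: tie broken by lower QM energy
  reps2 <- tibble::tibble(cluster = 1:2, snapshot = c(5L, 9L),
                          role = "centroid", dmd_energy = c(-1, -3))
  ch2 <- score_and_choose(reps2, qm_energies = c(-10, -5))
  expect_equal(ch2$snapshot, 5L)

  # exhaustive rank-sum oracle on 10 representatives
  set.seed(7)
  for (rep_case in 1:5) {
    qm <- rnorm(10); dmd <- rnorm(10)
    reps10 <- tibble::tibble(cluster = 1:10, snapshot = sample(100, 10),
                             role = "centroid", dmd_energy = dmd)
    score <- rank(qm, ties.method = "min") + rank(dmd, ties.method = "min")
    oracle <- reps10$snapshot[order(score, qm, reps10$snapshot)][1]
    expect_equal(score_and_choose(reps10, qm)$snapshot, oracle)
  }
})
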