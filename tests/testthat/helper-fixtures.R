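# Shared fixtures, built in code at test time.

default_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_site(toy_site_spec())
    cache
  }
})

# minimal 3-atom S-CH3...O system exposing only the transfer term
transfer_triple <- function(barrier = 5, delta0 = 0, charge_coupling = 0,
                            kappa = 0, kappa_rxn = 0, charge = 2) {
  atoms <- tibble::tibble(
    atom_id = 1:3, element = c("S", "C", "O"),
    atom_name = c("SD", "CM", "O2"), residue_name = "SYN",
    residue_id = 1L, chain_id = "A",
    x = c(0, 1.8, 4.51), y = 0, z = 0,
    mass = c(32.06, 12.011, 15.999), frozen = c(TRUE, FALSE, TRUE)
  )
  sys <- new_system(atoms,
                    tibble::tibble(i = integer(), j = integer(),
                                   ref_length = numeric()),
                    roles = list(),
                    key_atoms = c(s_donor = 1L, methyl_c = 2L, o_acceptor = 3L),
                    metal_params = list(label = "NONE", radius = 0.7,
                                        charge = charge))
  backend <- surrogate_backend(
    sys, surrogate_params(barrier = barrier, delta0 = delta0,
                          charge_coupling = charge_coupling,
                          kappa = kappa, kappa_rxn = kappa_rxn)
  )
  list(system = sys, backend = backend)
}

# brute-force Kabsch oracle: best over a quaternion grid, polished with
# Nelder-Mead on the quaternion parameters
brute_force_rmsd <- function(A, B, n_grid = 600, seed = 1) {
  ca <- colMeans(A); cb <- colMeans(B)
  X <- sweep(A, 2, ca); Y <- sweep(B, 2, cb)
  rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) sqrt(mean(rowSums((X %*% t(rot(q)) - Y)^2)))
  qs <- matrix(stats::rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj)
  best <- qs[which.min(vals), ]
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-15))
  opt2 <- stats::optim(opt$par, obj, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-15))
  min(opt$value, opt2$value)
}

# Metropolis sampler on the backend surface (used as an independent source
# of Boltzmann-distributed snapshots)
metropolis_snapshots <- function(system, backend, theta, n = 1000,
                                 step = 0.03, burn = 500, thin = 5, seed = 1) {
  set.seed(seed)
  free <- which(!system$atoms$frozen)
  xyz <- coords(system)
  ids <- system$atoms$atom_id
  e <- backend_energy(backend, xyz, ids = ids)
  out <- vector("list", n)
  got <- 0; it <- 0
  while (got < n) {
    it <- it + 1
    prop <- xyz
    r <- sample(free, 1)
    prop[r, ] <- prop[r, ] + stats::rnorm(3, 0, step)
    e2 <- backend_energy(backend, prop, ids = ids)
    if (stats::runif(1) < exp(-(e2 - e) / theta)) {
      xyz <- prop; e <- e2
    }
    if (it > burn && it %% thin == 0) {
      got <- got + 1
      out[[got]] <- set_coords(system, xyz)
    }
  }
  out
}
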