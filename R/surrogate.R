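# Analytic surrogate energy backend for the active-site cluster.
#
# The pipeline's contract only requires {energy, gradient, partial_optimize,
# hessian}; this built-in backend supplies a smooth (C^2 away from the 12-6
# core) surface with the qualitative response properties the study design
# needs: metal-ligand wells whose equilibrium tracks the ionic radius and
# whose depth tracks the charge, and a two-well methyl-transfer term along
# xi = R(O-C) - R(S-C) whose height/asymmetry respond to donor-acceptor
# collinearity and metal charge.

# hbar in internal units (energy kcal/mol, mass amu, length Angstrom); the
# implied time unit is 48.9 fs.
.hbar_internal <- 0.310466

#' Surrogate backend parameters
#'
#' @param k_bond harmonic force constant for covalent bonds, kcal/mol/A^2.
#' @param k_aux force constant for 1-3 (angle-auxiliary) pairs.
#' @param morse_depth metal-donor Morse well depth at charge +2, kcal/mol.
#' @param morse_a Morse range parameter, 1/A.
#' @param lj_eps 12-6 well depth, kcal/mol.
#' @param lj_rmin_factor 12-6 minimum as a fraction of the vdW-radius sum.
#' @param barrier two-well electronic barrier height b, kcal/mol.
#' @param delta0 reaction asymmetry (product minus reactant) at charge +2.
#' @param charge_coupling increase of the asymmetry per unit metal charge
#'   above +2, kcal/mol/e.
#' @param kappa collinearity coupling on the barrier: the quartic part of the
#'   transfer term is scaled by `1 + kappa*(1 + cos(alpha))` with alpha the
#'   O-C-S interior angle.
#' @param kappa_rxn collinearity coupling on the reaction asymmetry: the
#'   endothermicity switch is scaled by `1 + kappa_rxn*(1 + cos(alpha))`;
#'   misalignment destabilizes the product more than it raises the barrier.
#' @param k_sigma restraint on R(O-C)+R(S-C), kcal/mol/A^2.
#' @param k_proton force constant of the proton-coupling wells.
#' @param couple_proton logical; move the abstractable H from the acceptor O
#'   toward the base as the transfer coordinate advances.
#' @param proton_span total O-H elongation across the reaction, Angstrom.
#' @return a `surrogate_params` list.
#' @export
surrogate_params <- function(k_bond = 300, k_aux = 60,
                             morse_depth = 30, morse_a = 2.0,
                             lj_eps = 0.02, lj_rmin_factor = 0.90,
                             barrier = 18, delta0 = 3,
                             charge_coupling = 4, kappa = 1, kappa_rxn = 6,
                             k_sigma = 150, k_proton = 150,
                             couple_proton = TRUE, proton_span = 0.9) {
  structure(as.list(environment()), class = "surrogate_params")
}

#' Build the surrogate backend for a system
#'
#' Assembles the term tables (bond/1-3 harmonics, metal-donor Morse wells,
#' 12-6 nonbonded, the coupled two-well transfer term, proton-coupling wells)
#' from the system's topology and reference geometry. Nonbonded pairs closer
#' than the 12-6 minimum at the reference geometry are excluded: they are
#' declared native contacts (coordination and hydrogen bonds), not clashes.
#'
#' @param system a `qmdmd_system`.
#' @param params a [surrogate_params()] list.
#' @param coordination_cutoff cutoff used to identify metal donors when the
#'   system carries no recorded donor table, Angstrom.
#' @return object of class `qmdmd_backend`.
#' @export
surrogate_backend <- function(system, params = surrogate_params(),
                              coordination_cutoff = 2.6) {
  a <- system$atoms
  id2row <- function(ids) match(ids, a$atom_id)
  xyz <- coords(system)
  key <- system$key_atoms
  mp <- system$metal_params

  special_bond <- function(i, j) {
    has <- function(nm) nm %in% names(key)
    (has("s_donor") && has("methyl_c") &&
       setequal(c(i, j), key[c("s_donor", "methyl_c")])) ||
    (has("o_acceptor") && has("h_acceptor") &&
       setequal(c(i, j), key[c("o_acceptor", "h_acceptor")]))
  }
  b <- system$bonds
  keep <- !mapply(special_bond, b$i, b$j)
  harm <- tibble::tibble(i = b$i[keep], j = b$j[keep],
                         r0 = b$ref_length[keep], k = params$k_bond)
  # atoms that travel during the reaction are excluded from stiff geometric
  # reference terms; their own coupled wells govern them instead
  mobile <- key[names(key) %in% c("methyl_c", "h_acceptor")]
  if (nrow(system$aux_pairs) > 0) {
    ax <- system$aux_pairs
    ax <- ax[!(ax$i %in% mobile | ax$j %in% mobile), ]
    harm <- dplyr::bind_rows(
      harm,
      tibble::tibble(i = ax$i, j = ax$j, r0 = ax$ref_length, k = params$k_aux)
    )
  }
  if (!is.null(system$frame_pairs) && nrow(system$frame_pairs) > 0) {
    fp <- system$frame_pairs
    harm <- dplyr::bind_rows(
      harm, tibble::tibble(i = fp$i, j = fp$j, r0 = fp$ref_length, k = fp$k)
    )
  }

  # metal-donor Morse wells
  morse <- NULL
  if (!is.null(system$roles$metal)) {
    metal <- system$roles$metal
    if (!is.null(mp$donor_base_eq)) {
      donors <- as.integer(names(mp$donor_base_eq))
      base_eq <- unname(mp$donor_base_eq)
      ref_radius <- mp$reference_radius
    } else {
      donors <- donor_atoms(system, coordination_cutoff)
      base_eq <- vapply(donors, function(d) atom_distance(system, metal, d), numeric(1))
      ref_radius <- mp$radius %||% 0.72
    }
    if (length(donors) > 0) {
      morse <- tibble::tibble(
        i = metal, j = donors,
        r0 = base_eq + (mp$radius - ref_radius),
        D = params$morse_depth * mp$charge / 2,
        a = params$morse_a
      )
    }
  }

  # 12-6 pairs: heavy atoms at graph distance >= 3, no metal, no
  # frozen-frozen, and not a declared native contact (closer than rmin at the
  # reference geometry). Hydrogens and the transferring methyl carbon are
  # excluded: their interactions are owned by bonded and coupled terms.
  lj <- build_lj_pairs(system, params$lj_eps, params$lj_rmin_factor,
                       drop_atoms = key[names(key) %in% c("methyl_c")])

  # transfer + proton coupling reference values
  ref <- system$surrogate_ref
  transfer <- NULL
  proton <- NULL
  if (all(c("s_donor", "methyl_c", "o_acceptor") %in% names(key))) {
    s <- key[["s_donor"]]; cm <- key[["methyl_c"]]; o <- key[["o_acceptor"]]
    r_oc <- atom_distance(system, o, cm)
    r_sc <- atom_distance(system, s, cm)
    w <- ref$xi_w %||% (r_oc - r_sc)
    sigma0 <- ref$sigma0 %||% (r_oc + r_sc)
    transfer <- list(
      s = s, cm = cm, o = o, w = w, sigma0 = sigma0,
      b = params$barrier, kappa = params$kappa, kappa_rxn = params$kappa_rxn,
      k_sigma = params$k_sigma,
      delta = params$delta0 + params$charge_coupling * (mp$charge - 2)
    )
    if (params$couple_proton &&
        all(c("h_acceptor", "n_base") %in% names(key))) {
      h <- key[["h_acceptor"]]; nb <- key[["n_base"]]
      r_oh0 <- ref$r_oh0 %||% atom_distance(system, o, h)
      r_on <- ref$r_on %||% atom_distance(system, o, nb)
      proton <- list(
        o = o, h = h, nb = nb, s = s, cm = cm,
        r_oh0 = r_oh0, r_on = r_on, span = params$proton_span,
        k = params$k_proton, k_frame = 20
      )
    } else if (all(c("h_acceptor", "n_base") %in% names(key))) {
      # coupling off: plain wells at the reference distances
      h <- key[["h_acceptor"]]; nb <- key[["n_base"]]
      proton <- list(
        o = key[["o_acceptor"]], h = h, nb = nb, s = s, cm = cm,
        r_oh0 = ref$r_oh0 %||% atom_distance(system, key[["o_acceptor"]], h),
        r_on = ref$r_on %||% atom_distance(system, key[["o_acceptor"]], nb),
        span = 0, k = params$k_proton, k_frame = 20
      )
    }
  }

  structure(
    list(params = params, harm = harm, morse = morse, lj = lj,
         transfer = transfer, proton = proton,
         atoms = a[, c("atom_id", "element", "mass")],
         metal_params = mp),
    class = "qmdmd_backend"
  )
}

build_lj_pairs <- function(system, eps, rmin_factor, drop_atoms = integer()) {
  a <- system$atoms
  n <- nrow(a)
  if (n < 2) return(tibble::tibble(i = integer(), j = integer(),
                                   eps = numeric(), rmin = numeric()))
  # graph distance <= 2 exclusion via bonds + aux pairs
  excl <- paste(pmin(c(system$bonds$i, system$aux_pairs$i),
                     c(system$bonds$j, system$aux_pairs$j)),
                pmax(c(system$bonds$i, system$aux_pairs$i),
                     c(system$bonds$j, system$aux_pairs$j)))
  metal <- system$roles$metal
  xyz <- cbind(a$x, a$y, a$z)
  vdw <- element_vdw_radius(a$element)
  cmb <- utils::combn(a$atom_id, 2)
  i <- cmb[1, ]; j <- cmb[2, ]
  keypair <- paste(pmin(i, j), pmax(i, j))
  ri <- match(i, a$atom_id); rj <- match(j, a$atom_id)
  rmin <- rmin_factor * (vdw[ri] + vdw[rj])
  d0 <- sqrt(rowSums((xyz[ri, , drop = FALSE] - xyz[rj, , drop = FALSE])^2))
  hyd <- a$atom_id[toupper(a$element) == "H"]
  drop <- keypair %in% excl |
    (a$frozen[ri] & a$frozen[rj]) |
    d0 < rmin |
    i %in% c(hyd, drop_atoms) | j %in% c(hyd, drop_atoms)
  if (!is.null(metal)) drop <- drop | i == metal | j == metal
  tibble::tibble(i = i[!drop], j = j[!drop], eps = eps, rmin = rmin[!drop])
}

smootherstep <- function(s) {
  s <- pmin(1, pmax(0, s))
  s^3 * (10 - 15 * s + 6 * s^2)
}

smootherstep_d <- function(s) {
  inside <- s > 0 & s < 1
  s <- pmin(1, pmax(0, s))
  ifelse(inside, 30 * s^2 * (1 - s)^2, 0)
}

# Energy and gradient over an id-indexed coordinate matrix. Terms whose atoms
# are not all present (subset evaluation) are skipped.
surrogate_eval <- function(backend, xyz, ids, want_gradient = TRUE) {
  row_of <- integer(0)
  row_of[ids] <- seq_along(ids)
  present <- function(v) all(v <= length(row_of) & v > 0) && all(row_of[v] > 0, na.rm = TRUE) &&
    !anyNA(row_of[v])
  E <- 0
  G <- if (want_gradient) matrix(0, nrow(xyz), 3) else NULL

  pair_accum <- function(i, j, dEdr) {
    ri <- row_of[i]; rj <- row_of[j]
    dvec <- xyz[ri, , drop = FALSE] - xyz[rj, , drop = FALSE]
    r <- sqrt(rowSums(dvec^2))
    u <- dvec / r
    gi <- u * dEdr
    contrib <- rowsum(rbind(gi, -gi), group = c(ri, rj))
    rows <- as.integer(rownames(contrib))
    G[rows, ] <<- G[rows, ] + contrib
  }
  pair_r <- function(i, j) {
    dvec <- xyz[row_of[i], , drop = FALSE] - xyz[row_of[j], , drop = FALSE]
    sqrt(rowSums(dvec^2))
  }

  # harmonics
  h <- backend$harm
  if (nrow(h) > 0) {
    ok <- !is.na(row_of[h$i]) & !is.na(row_of[h$j])
    hh <- h[ok, , drop = FALSE]
    if (nrow(hh) > 0) {
      r <- pair_r(hh$i, hh$j)
      E <- E + sum(hh$k * (r - hh$r0)^2)
      if (want_gradient) pair_accum(hh$i, hh$j, 2 * hh$k * (r - hh$r0))
    }
  }
  # Morse
  m <- backend$morse
  if (!is.null(m) && nrow(m) > 0) {
    ok <- !is.na(row_of[m$i]) & !is.na(row_of[m$j])
    mm <- m[ok, , drop = FALSE]
    if (nrow(mm) > 0) {
      r <- pair_r(mm$i, mm$j)
      ex <- exp(-mm$a * (r - mm$r0))
      E <- E + sum(mm$D * ((1 - ex)^2 - 1))
      if (want_gradient) pair_accum(mm$i, mm$j, 2 * mm$D * mm$a * ex * (1 - ex))
    }
  }
  # 12-6
  l <- backend$lj
  if (!is.null(l) && nrow(l) > 0) {
    ok <- !is.na(row_of[l$i]) & !is.na(row_of[l$j])
    ll <- l[ok, , drop = FALSE]
    if (nrow(ll) > 0) {
      r <- pair_r(ll$i, ll$j)
      x6 <- (ll$rmin / r)^6
      E <- E + sum(ll$eps * (x6^2 - 2 * x6))
      if (want_gradient) {
        pair_accum(ll$i, ll$j, ll$eps * 12 * (x6 - x6^2) / r)
      }
    }
  }
  # transfer term
  tr <- backend$transfer
  xi <- NULL
  if (!is.null(tr) && !anyNA(row_of[c(tr$s, tr$cm, tr$o)]) &&
      all(row_of[c(tr$s, tr$cm, tr$o)] > 0)) {
    ps <- xyz[row_of[tr$s], ]; pc <- xyz[row_of[tr$cm], ]; po <- xyz[row_of[tr$o], ]
    v_oc <- po - pc; v_sc <- ps - pc
    r_oc <- sqrt(sum(v_oc^2)); r_sc <- sqrt(sum(v_sc^2))
    xi <- r_oc - r_sc
    sigma <- r_oc + r_sc
    u <- xi / tr$w
    # two-well along u with minima pinned at u = +/-1 regardless of the
    # asymmetry: the cubic switch (2 - 3u + u^3)/4 is 0 at u=1, 1 at u=-1,
    # with zero slope at both ends; barrier ~ b + delta/2 at u ~ 0.
    # Collinearity scales the barrier instantaneously (kappa); the
    # asymmetry's collinearity response (kappa_rxn) is applied per ensemble
    # member from the reactant's near-attack angle by reaction_profile().
    Vq <- tr$b * (u^2 - 1)^2
    Vd <- tr$delta * (2 - 3 * u + u^3) / 4
    dVq_du <- tr$b * 4 * u * (u^2 - 1)
    dVd_du <- tr$delta * 3 * (u^2 - 1) / 4
    cosa <- sum(v_oc * v_sc) / (r_oc * r_sc)
    Ab <- 1 + tr$kappa * (1 + cosa)
    E <- E + Ab * Vq + Vd + tr$k_sigma * (sigma - tr$sigma0)^2
    if (want_gradient) {
      u_oc <- v_oc / r_oc; u_sc <- v_sc / r_sc
      dV_dxi <- (Ab * dVq_du + dVd_du) / tr$w
      dsig <- 2 * tr$k_sigma * (sigma - tr$sigma0)
      # d xi: +1 wrt r_oc, -1 wrt r_sc; d sigma: +1, +1
      g_o <- (dV_dxi + dsig) * u_oc
      g_s <- (-dV_dxi + dsig) * u_sc
      # angle part: grad of cos(alpha)
      dV_dcos <- tr$kappa * Vq
      dcos_do <- (u_sc - cosa * u_oc) / r_oc
      dcos_ds <- (u_oc - cosa * u_sc) / r_sc
      g_o <- g_o + dV_dcos * dcos_do
      g_s <- g_s + dV_dcos * dcos_ds
      g_c <- -(g_o + g_s)
      G[row_of[tr$o], ] <- G[row_of[tr$o], ] + g_o
      G[row_of[tr$s], ] <- G[row_of[tr$s], ] + g_s
      G[row_of[tr$cm], ] <- G[row_of[tr$cm], ] + g_c
    }
  }
  # proton coupling: the abstractable H is tethered to a point a fraction
  # lambda(xi) of the way along the acceptor-O -> base-N axis, so it slides
  # from O toward the base as the transfer coordinate advances; built from
  # relative vectors only, hence rotation/translation invariant
  pr <- backend$proton
  if (!is.null(pr) && !anyNA(row_of[c(pr$o, pr$h, pr$nb)]) &&
      all(row_of[c(pr$o, pr$h, pr$nb)] > 0)) {
    g_val <- 0; dg_dxi <- 0
    if (pr$span > 0 && !is.null(xi)) {
      tr <- backend$transfer
      s_arg <- (tr$w - xi) / (2 * tr$w)
      g_val <- smootherstep(s_arg)
      dg_dxi <- -smootherstep_d(s_arg) / (2 * tr$w)
    }
    lam <- (pr$r_oh0 + pr$span * g_val) / pr$r_on
    po <- xyz[row_of[pr$o], ]; ph <- xyz[row_of[pr$h], ]; pn <- xyz[row_of[pr$nb], ]
    dvec <- ph - po - lam * (pn - po)
    r_on <- sqrt(sum((pn - po)^2))
    E <- E + pr$k * sum(dvec^2) + pr$k_frame * (r_on - pr$r_on)^2
    if (want_gradient) {
      G[row_of[pr$h], ] <- G[row_of[pr$h], ] + 2 * pr$k * dvec
      G[row_of[pr$o], ] <- G[row_of[pr$o], ] - 2 * pr$k * dvec * (1 - lam)
      G[row_of[pr$nb], ] <- G[row_of[pr$nb], ] - 2 * pr$k * dvec * lam
      pair_accum(pr$o, pr$nb, 2 * pr$k_frame * (r_on - pr$r_on))
      if (pr$span > 0 && !is.null(xi) && dg_dxi != 0) {
        tr <- backend$transfer
        dE_dlam <- -2 * pr$k * sum(dvec * (pn - po))
        dE_dxi <- dE_dlam * (pr$span * dg_dxi) / pr$r_on
        ps <- xyz[row_of[tr$s], ]; pc <- xyz[row_of[tr$cm], ]; po2 <- xyz[row_of[tr$o], ]
        v_oc <- po2 - pc; v_sc <- ps - pc
        u_oc <- v_oc / sqrt(sum(v_oc^2)); u_sc <- v_sc / sqrt(sum(v_sc^2))
        G[row_of[tr$o], ] <- G[row_of[tr$o], ] + dE_dxi * u_oc
        G[row_of[tr$s], ] <- G[row_of[tr$s], ] - dE_dxi * u_sc
        G[row_of[tr$cm], ] <- G[row_of[tr$cm], ] - dE_dxi * (u_oc - u_sc)
      }
    }
  }
  list(energy = E, gradient = G)
}

#' Backend energy of a geometry
#'
#' @param backend a `qmdmd_backend`.
#' @param object a `qmdmd_system`, `qmdmd_cluster`, or coordinate matrix.
#' @param ids atom ids labelling the rows when `object` is a matrix.
#' @return energy in kcal/mol.
#' @export
backend_energy <- function(backend, object, ids = NULL) {
  xi <- as_xyz_ids(object, ids)
  surrogate_eval(backend, xi$xyz, xi$ids, want_gradient = FALSE)$energy
}

#' @rdname backend_energy
#' @export
backend_gradient <- function(backend, object, ids = NULL) {
  xi <- as_xyz_ids(object, ids)
  surrogate_eval(backend, xi$xyz, xi$ids, want_gradient = TRUE)$gradient
}

as_xyz_ids <- function(object, ids = NULL) {
  if (inherits(object, "qmdmd_system")) {
    list(xyz = coords(object), ids = object$atoms$atom_id)
  } else if (inherits(object, "qmdmd_cluster")) {
    list(xyz = cluster_coords(object), ids = object$atoms$atom_id)
  } else {
    if (is.null(ids)) stop("ids required for a bare coordinate matrix")
    list(xyz = object, ids = ids)
  }
}

#' Partially optimize a geometry on the backend surface
#'
#' Frozen atoms stay exactly in place; free atoms are relaxed with L-BFGS-B
#' using the analytic gradient until the largest free-atom gradient component
#' is below `tol`.
#'
#' @param object a `qmdmd_cluster` or `qmdmd_system`.
#' @param backend a `qmdmd_backend`.
#' @param frozen atom ids to hold fixed (defaults to the object's frozen set).
#' @param tol gradient convergence threshold, kcal/mol/A.
#' @param max_restarts L-BFGS-B restarts before giving up.
#' @return the optimized object, with attributes `converged`, `energy`,
#'   `max_gradient`.
#' @export
partial_optimize <- function(object, backend, frozen = NULL, tol = 1e-4,
                             max_restarts = 6) {
  xi <- as_xyz_ids(object)
  xyz <- xi$xyz; ids <- xi$ids
  if (is.null(frozen)) {
    frozen <- if (inherits(object, "qmdmd_cluster")) object$frozen_in_qm
              else object$atoms$atom_id[object$atoms$frozen]
  }
  free_rows <- which(!(ids %in% frozen))
  if (length(free_rows) == 0) {
    attr(object, "converged") <- TRUE
    attr(object, "nothing_to_optimize") <- TRUE
    attr(object, "energy") <- backend_energy(backend, xyz, ids)
    return(object)
  }
  pack <- function(m) as.numeric(m[free_rows, ])
  unpack <- function(p) {
    xyz[free_rows, ] <- matrix(p, ncol = 3)
    xyz
  }
  fn <- function(p) surrogate_eval(backend, unpack(p), ids, FALSE)$energy
  gr <- function(p) {
    g <- surrogate_eval(backend, unpack(p), ids, TRUE)$gradient
    as.numeric(g[free_rows, ])
  }
  p <- pack(xyz)
  converged <- FALSE
  for (r in seq_len(max_restarts)) {
    opt <- stats::optim(p, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = 500, factr = 10, pgtol = tol / 10))
    p <- opt$par
    g <- gr(p)
    if (max(abs(g)) <= tol) { converged <- TRUE; break }
  }
  xyz_new <- unpack(p)
  out <- set_object_coords(object, xyz_new)
  attr(out, "converged") <- converged
  attr(out, "energy") <- fn(p)
  attr(out, "max_gradient") <- max(abs(gr(p)))
  out
}

set_object_coords <- function(object, xyz) {
  if (inherits(object, "qmdmd_cluster")) {
    object$atoms$x <- xyz[, 1]; object$atoms$y <- xyz[, 2]; object$atoms$z <- xyz[, 3]
    object
  } else {
    set_coords(object, xyz)
  }
}

#' Mass-weighted Hessian, harmonic frequencies and ZPE
#'
#' Central finite differences (step 1e-3 A) of the analytic gradient over the
#' free atoms, mass-weighted and diagonalized. Frequencies are reported in
#' internal angular units; the zero-point energy sums 1/2 hbar omega over the
#' positive modes only (the imaginary mode of a saddle is excluded by
#' construction).
#'
#' @param object a `qmdmd_cluster` or `qmdmd_system` at (or near) a
#'   stationary point.
#' @param backend a `qmdmd_backend`.
#' @param free_atoms atom ids allowed to move (defaults to non-frozen).
#' @param step finite-difference step, Angstrom.
#' @param stationarity_tol gradient norm above which a warning attribute is
#'   attached.
#' @return list with `hessian` (mass-weighted), `eigenvalues`, `frequencies`
#'   (sqrt of positive eigenvalues), `n_imaginary`, `zpe` (kcal/mol), and
#'   `stationary` flag.
#' @export
cluster_hessian <- function(object, backend, free_atoms = NULL, step = 1e-3,
                            stationarity_tol = 1e-3) {
  xi <- as_xyz_ids(object)
  xyz <- xi$xyz; ids <- xi$ids
  if (is.null(free_atoms)) {
    frozen <- if (inherits(object, "qmdmd_cluster")) object$frozen_in_qm
              else object$atoms$atom_id[object$atoms$frozen]
    free_atoms <- setdiff(ids, frozen)
  }
  free_rows <- which(ids %in% free_atoms)
  nf <- length(free_rows)
  grad_free <- function(m) {
    g <- surrogate_eval(backend, m, ids, TRUE)$gradient
    as.numeric(t(g[free_rows, , drop = FALSE]))
  }
  g0 <- grad_free(xyz)
  stationary <- max(abs(g0)) <= stationarity_tol
  if (!stationary) {
    warning("hessian requested at a non-stationary geometry (max |g| = ",
            signif(max(abs(g0)), 3), ")")
  }
  n <- 3 * nf
  H <- matrix(0, n, n)
  for (kk in seq_len(n)) {
    at <- free_rows[(kk - 1) %/% 3 + 1]
    comp <- (kk - 1) %% 3 + 1
    xp <- xyz; xp[at, comp] <- xp[at, comp] + step
    xm <- xyz; xm[at, comp] <- xm[at, comp] - step
    H[, kk] <- (grad_free(xp) - grad_free(xm)) / (2 * step)
  }
  H <- (H + t(H)) / 2
  masses <- if (inherits(object, "qmdmd_cluster")) object$atoms$mass[free_rows]
            else object$atoms$mass[free_rows]
  invsqrt <- 1 / sqrt(rep(masses, each = 3))
  Hmw <- H * outer(invsqrt, invsqrt)
  ev <- eigen(Hmw, symmetric = TRUE)$values
  neg_tol <- 1e-5
  n_imag <- sum(ev < -neg_tol)
  pos <- ev[ev > neg_tol]
  freqs <- sqrt(pos)
  zpe <- 0.5 * .hbar_internal * sum(freqs)
  list(hessian = Hmw, eigenvalues = ev, frequencies = freqs,
       n_imaginary = n_imag, zpe = zpe, stationary = stationary)
}
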