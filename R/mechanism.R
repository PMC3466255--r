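# Stationary-point analysis of the methyl-transfer step on the backend
# surface: reactant/product minima, the constrained-scan + Newton-polished
# transition state, frequency confirmation, and ZPE-corrected ensemble
# reaction profiles.
#
# Reaction coordinate: xi = R(O-C) - R(S-C). The reactant (methyl on S) has
# xi > 0, the product (methyl on O) xi < 0; xi decreases as the methyl moves
# from the sulfur donor to the acceptor oxygen.

transfer_atoms <- function(backend) {
  tr <- backend$transfer
  if (is.null(tr)) stop("backend has no transfer term (no donor/acceptor atoms)")
  tr
}

xi_of <- function(backend, object) {
  tr <- transfer_atoms(backend)
  xyz <- as_xyz_ids(object)
  rows <- match(c(tr$o, tr$cm, tr$s), xyz$ids)
  p <- xyz$xyz[rows, ]
  sqrt(sum((p[1, ] - p[2, ])^2)) - sqrt(sum((p[3, ] - p[2, ])^2))
}

point_metrics <- function(backend, object) {
  tr <- transfer_atoms(backend)
  xyz <- as_xyz_ids(object)
  rows <- match(c(tr$o, tr$cm, tr$s), xyz$ids)
  p <- xyz$xyz[rows, ]
  r_oc <- sqrt(sum((p[1, ] - p[2, ])^2))
  r_sc <- sqrt(sum((p[3, ] - p[2, ])^2))
  ang <- interior_angle(p[1, ], p[2, ], p[3, ])
  r_oh <- NA_real_
  pr <- backend$proton
  if (!is.null(pr)) {
    ro <- match(pr$o, xyz$ids); rh <- match(pr$h, xyz$ids)
    if (!anyNA(c(ro, rh))) {
      r_oh <- sqrt(sum((xyz$xyz[ro, ] - xyz$xyz[rh, ])^2))
    }
  }
  list(r_oc = r_oc, r_sc = r_sc, angle_ocs = ang, r_oh_base = r_oh,
       xi = r_oc - r_sc)
}

new_stationary_point <- function(cluster, backend, hess, kind) {
  m <- point_metrics(backend, cluster)
  structure(
    list(geometry = cluster,
         energy = attr(cluster, "energy"),
         zpe = hess$zpe,
         n_imaginary = hess$n_imaginary,
         kind = kind,
         metrics = m,
         stationary = hess$stationary),
    class = "stationary_point"
  )
}

#' @export
print.stationary_point <- function(x, ...) {
  cat("<stationary_point> ", x$kind, ": E = ", round(x$energy, 4),
      " kcal/mol, ZPE = ", round(x$zpe, 4), ", ", x$n_imaginary,
      " imaginary mode(s)\n", sep = "")
  invisible(x)
}

#' Locate and confirm a minimum
#'
#' Partial optimization to `tol` followed by a frequency calculation; the
#' kind (reactant/product) is assigned from the sign of the transfer
#' coordinate. Converging onto a saddle (imaginary modes present) is flagged,
#' never silently accepted.
#'
#' @param start a `qmdmd_cluster` (or system) to relax.
#' @param backend a `qmdmd_backend` with a transfer term.
#' @param frozen atom ids held fixed (default: the cluster's QM-frozen set).
#' @param tol gradient tolerance, kcal/mol/A.
#' @return a `stationary_point`.
#' @export
find_minimum <- function(start, backend, frozen = NULL, tol = 1e-5) {
  opt <- partial_optimize(start, backend, frozen = frozen, tol = tol)
  hess <- suppressWarnings(cluster_hessian(opt, backend, free_atoms = free_of(opt, frozen)))
  xi <- xi_of(backend, opt)
  kind <- if (xi >= 0) "reactant" else "product"
  sp <- new_stationary_point(opt, backend, hess, kind)
  if (hess$n_imaginary > 0) {
    warning("optimization converged to a stationary point with ",
            hess$n_imaginary, " imaginary mode(s); flagged, not a minimum")
    sp$flagged_saddle <- TRUE
  }
  sp
}

free_of <- function(object, frozen = NULL) {
  ids <- if (inherits(object, "qmdmd_cluster")) object$atoms$atom_id
         else object$atoms$atom_id
  if (is.null(frozen)) {
    frozen <- if (inherits(object, "qmdmd_cluster")) object$frozen_in_qm
              else object$atoms$atom_id[object$atoms$frozen]
  }
  setdiff(ids, frozen)
}

# relaxes all free coordinates under an added harmonic restraint on xi
optimize_restrained_xi <- function(object, backend, xi0, k_r = 500,
                                   frozen = NULL, tol = 1e-4) {
  tr <- transfer_atoms(backend)
  xi <- as_xyz_ids(object)
  xyz <- xi$xyz; ids <- xi$ids
  if (is.null(frozen)) {
    frozen <- if (inherits(object, "qmdmd_cluster")) object$frozen_in_qm
              else object$atoms$atom_id[object$atoms$frozen]
  }
  free_rows <- which(!(ids %in% frozen))
  rows <- match(c(tr$o, tr$cm, tr$s), ids)
  en <- function(m) {
    base <- surrogate_eval(backend, m, ids, FALSE)$energy
    p <- m[rows, ]
    x <- sqrt(sum((p[1, ] - p[2, ])^2)) - sqrt(sum((p[3, ] - p[2, ])^2))
    base + k_r * (x - xi0)^2
  }
  gr <- function(m) {
    ev <- surrogate_eval(backend, m, ids, TRUE)
    p <- m[rows, ]
    v_oc <- p[1, ] - p[2, ]; v_sc <- p[3, ] - p[2, ]
    r_oc <- sqrt(sum(v_oc^2)); r_sc <- sqrt(sum(v_sc^2))
    x <- r_oc - r_sc
    d <- 2 * k_r * (x - xi0)
    u_oc <- v_oc / r_oc; u_sc <- v_sc / r_sc
    g <- ev$gradient
    g[rows[1], ] <- g[rows[1], ] + d * u_oc
    g[rows[3], ] <- g[rows[3], ] - d * u_sc
    g[rows[2], ] <- g[rows[2], ] - d * (u_oc - u_sc)
    g
  }
  p0 <- as.numeric(xyz[free_rows, ])
  fn_p <- function(par) { xyz[free_rows, ] <- matrix(par, ncol = 3); en(xyz) }
  gr_p <- function(par) {
    xyz[free_rows, ] <- matrix(par, ncol = 3)
    as.numeric(gr(xyz)[free_rows, ])
  }
  opt <- stats::optim(p0, fn_p, gr_p, method = "L-BFGS-B",
                      control = list(maxit = 400, factr = 10, pgtol = tol))
  xyz[free_rows, ] <- matrix(opt$par, ncol = 3)
  out <- set_object_coords(object, xyz)
  attr(out, "energy") <- surrogate_eval(backend, xyz, ids, FALSE)$energy
  out
}

#' Transition-state search for the methyl transfer
#'
#' Constrained scan over the transfer coordinate between the reactant and
#' product (relaxing all other free coordinates at each of `n_scan` points),
#' followed by Newton polishing of the highest interior point on the full
#' free-space Hessian. The result must carry exactly one imaginary mode; its
#' eigenvector is checked to lie mainly on the transferring group.
#'
#' @param reactant,product `stationary_point`s with reactant xi > product xi.
#' @param backend a `qmdmd_backend`.
#' @param frozen atom ids held fixed.
#' @param n_scan scan points (default 41).
#' @param tol gradient tolerance for the polish.
#' @return a `stationary_point` of kind "ts"; attribute `polished` FALSE when
#'   the Newton polish diverged and the scan maximum is returned instead.
#' @export
find_ts <- function(reactant, product, backend, frozen = NULL,
                    n_scan = 41, tol = 1e-5) {
  xi_r <- reactant$metrics$xi
  xi_p <- product$metrics$xi
  if (xi_r <= xi_p) stop("need reactant xi > product xi (transfer runs S -> O)")
  grid <- seq(xi_r, xi_p, length.out = n_scan)
  cur <- reactant$geometry
  energies <- numeric(n_scan)
  geoms <- vector("list", n_scan)
  for (q in seq_along(grid)) {
    cur <- optimize_restrained_xi(cur, backend, grid[q], frozen = frozen)
    energies[q] <- attr(cur, "energy")
    geoms[[q]] <- cur
  }
  imax <- which.max(energies)
  if (imax == 1 || imax == n_scan) {
    stop("no barrier on path: scan maximum is not interior")
  }

  # Newton polish on the free-space Hessian
  start <- geoms[[imax]]
  xyzids <- as_xyz_ids(start)
  ids <- xyzids$ids
  if (is.null(frozen)) {
    frozen_eff <- if (inherits(start, "qmdmd_cluster")) start$frozen_in_qm
                  else start$atoms$atom_id[start$atoms$frozen]
  } else frozen_eff <- frozen
  free_rows <- which(!(ids %in% frozen_eff))
  xyz <- xyzids$xyz
  polished <- TRUE
  for (iter in 1:60) {
    g <- surrogate_eval(backend, xyz, ids, TRUE)$gradient
    gv <- as.numeric(t(g[free_rows, , drop = FALSE]))
    if (max(abs(gv)) <= tol) break
    H <- fd_hessian(backend, xyz, ids, free_rows)
    step <- tryCatch(-solve(H, gv), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step)) ||
        max(abs(step)) > 1.0) {
      if (is.null(step) || !all(is.finite(step))) { polished <- FALSE; break }
      step <- step * (0.3 / max(abs(step)))
    }
    if (iter == 60) polished <- FALSE
    m <- matrix(step, ncol = 3, byrow = TRUE)
    xyz[free_rows, ] <- xyz[free_rows, ] + m
  }
  g <- surrogate_eval(backend, xyz, ids, TRUE)$gradient
  if (max(abs(g[free_rows, ])) > 10 * tol) polished <- FALSE
  if (!polished) {
    warning("TS polish did not converge; returning scan maximum (unpolished)")
    xyz <- as_xyz_ids(geoms[[imax]])$xyz
  }
  ts_geom <- set_object_coords(start, xyz)
  attr(ts_geom, "energy") <- surrogate_eval(backend, xyz, ids, FALSE)$energy
  hess <- suppressWarnings(
    cluster_hessian(ts_geom, backend, free_atoms = ids[free_rows])
  )
  sp <- new_stationary_point(ts_geom, backend, hess, "ts")
  attr(sp, "polished") <- polished

  # imaginary-mode localization on the transferring group
  if (hess$n_imaginary >= 1) {
    ev <- eigen(hess$hessian, symmetric = TRUE)
    vec <- ev$vectors[, which.min(ev$values)]
    per_atom <- sqrt(colSums(matrix(vec^2, nrow = 3)))
    tr <- transfer_atoms(backend)
    local_rows <- match(intersect(c(tr$cm, tr$o, tr$s), ids[free_rows]),
                        ids[free_rows])
    sp$mode_on_transfer_group <-
      sum(per_atom[local_rows]) >= max(per_atom) - 1e-9 ||
      which.max(per_atom) %in% local_rows
  }
  sp
}

fd_hessian <- function(backend, xyz, ids, free_rows, step = 1e-4) {
  nf <- length(free_rows)
  n <- 3 * nf
  H <- matrix(0, n, n)
  grad_free <- function(m) {
    g <- surrogate_eval(backend, m, ids, TRUE)$gradient
    as.numeric(t(g[free_rows, , drop = FALSE]))
  }
  for (kk in seq_len(n)) {
    at <- free_rows[(kk - 1) %/% 3 + 1]
    comp <- (kk - 1) %% 3 + 1
    xp <- xyz; xp[at, comp] <- xp[at, comp] + step
    xm <- xyz; xm[at, comp] <- xm[at, comp] - step
    H[, kk] <- (grad_free(xp) - grad_free(xm)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Locate the product by downhill relaxation past the barrier
#'
#' Scans the transfer coordinate from the reactant to the product-side well
#' and relaxes the last scan point without restraint.
#'
#' @param reactant a `stationary_point` of kind "reactant".
#' @param backend a `qmdmd_backend`.
#' @param frozen atom ids held fixed.
#' @param n_scan scan points.
#' @return a `stationary_point` of kind "product".
#' @export
find_product <- function(reactant, backend, frozen = NULL, n_scan = 21) {
  tr <- transfer_atoms(backend)
  xi_r <- reactant$metrics$xi
  xi_target <- -abs(tr$w)
  grid <- seq(xi_r, xi_target, length.out = n_scan)
  cur <- reactant$geometry
  for (x in grid) {
    cur <- optimize_restrained_xi(cur, backend, x, frozen = frozen)
  }
  find_minimum(cur, backend, frozen = frozen)
}

#' ZPE-corrected ensemble reaction profile
#'
#' For every ensemble member: locate the reactant, product and transition
#' state, apply the zero-point correction, and report barriers and reaction
#' energies relative to the reactant, with ensemble mean and standard
#' deviation plus the key structural parameters at each stationary point.
#' Members whose TS search fails are excluded and counted.
#'
#' @param ensemble list of reactant structures (`qmdmd_cluster`s or systems).
#' @param backend a `qmdmd_backend`.
#' @param frozen atom ids held fixed during optimizations.
#' @param n_scan scan points for the TS search.
#' @return a `reaction_profile`: `members` tibble (one row per member),
#'   `summary` tibble (mean/sd per column), `n_excluded`.
#' @export
reaction_profile <- function(ensemble, backend, frozen = NULL, n_scan = 41) {
  if (length(ensemble) < 2) stop("need at least 2 ensemble members")
  rows <- list(); excluded <- 0L
  for (m in seq_along(ensemble)) {
    res <- tryCatch({
      rea <- find_minimum(ensemble[[m]], backend, frozen = frozen)
      # the quality of this member's near-attack conformation sets its
      # reaction asymmetry: misalignment of S-CH3-O destabilizes the product
      be_m <- backend
      if (!is.null(backend$transfer) && !is.null(backend$transfer$kappa_rxn)) {
        nac <- 1 + backend$transfer$kappa_rxn *
          (1 + cos(rea$metrics$angle_ocs * pi / 180))
        be_m$transfer$delta <- backend$transfer$delta * nac
      }
      rea <- find_minimum(rea$geometry, be_m, frozen = frozen)
      prod <- find_product(rea, be_m, frozen = frozen)
      ts <- find_ts(rea, prod, be_m, frozen = frozen, n_scan = n_scan)
      e0 <- rea$energy + rea$zpe
      tibble::tibble(
        member = m,
        dE_ts = (ts$energy + ts$zpe) - e0,
        dE_rxn = (prod$energy + prod$zpe) - e0,
        r_oh_react = rea$metrics$r_oh_base,
        r_oh_ts = ts$metrics$r_oh_base,
        r_oh_prod = prod$metrics$r_oh_base,
        r_oc_ts = ts$metrics$r_oc,
        r_sc_ts = ts$metrics$r_sc,
        xi_ts = ts$metrics$xi,
        angle_ocs_react = rea$metrics$angle_ocs,
        n_imag_ts = ts$n_imaginary
      )
    }, error = function(e) NULL)
    if (is.null(res)) excluded <- excluded + 1L else rows[[length(rows) + 1]] <- res
  }
  members <- dplyr::bind_rows(rows)
  num_cols <- setdiff(names(members), c("member"))
  summary <- tidyr::pivot_longer(members, dplyr::all_of(num_cols),
                                 names_to = "quantity") |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  structure(list(members = members, summary = summary, n_excluded = excluded),
            class = "reaction_profile")
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat("<reaction_profile> ", nrow(x$members), " members (",
      x$n_excluded, " excluded)\n", sep = "")
  bar <- x$summary[x$summary$quantity %in% c("dE_ts", "dE_rxn"), ]
  for (r in seq_len(nrow(bar))) {
    cat("  ", bar$quantity[r], ": ", sprintf("%.1f (%.1f)", bar$mean[r], bar$sd[r]),
        " kcal/mol\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.reaction_profile <- function(x, ...) x$members

#' @export
glance.reaction_profile <- function(x, ...) {
  s <- x$summary
  g <- function(q, w) s[[w]][s$quantity == q]
  tibble::tibble(
    mean_dE_ts = g("dE_ts", "mean"), sd_dE_ts = g("dE_ts", "sd"),
    mean_dE_rxn = g("dE_rxn", "mean"), sd_dE_rxn = g("dE_rxn", "sd"),
    n_members = nrow(x$members), n_excluded = x$n_excluded
  )
}

#' Proton-abstraction distance along the reaction
#'
#' Reports R(O-H) toward the base for each stationary point and whether the
#' elongation is monotone from reactant through TS to product. With no base
#' site present the metric is reported as absent, not zero.
#'
#' @param points list of `stationary_point`s (any order; sorted
#'   reactant/ts/product internally).
#' @return tibble with kind, r_oh_base, plus attribute `monotone`.
#' @export
base_proton_track <- function(points) {
  kinds <- vapply(points, function(p) p$kind, character(1))
  ord <- order(match(kinds, c("reactant", "ts", "product")))
  tab <- tibble::tibble(
    kind = kinds[ord],
    r_oh_base = vapply(points[ord], function(p) p$metrics$r_oh_base, numeric(1))
  )
  if (all(is.na(tab$r_oh_base))) {
    attr(tab, "monotone") <- NA
    attr(tab, "note") <- "base site absent"
  } else {
    attr(tab, "monotone") <- !is.unsorted(tab$r_oh_base, strictly = FALSE)
  }
  tab
}
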