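# Named active-site geometry observables and their ensemble statistics,
# reported "mean (sd)" the way structural tables are printed, plus
# metal-variant comparison reports.

#' Define a geometry metric
#'
#' @param label row label, e.g. "Metal-O1(Sub)".
#' @param kind "distance" (2 selectors) or "angle" (3 selectors; the angle is
#'   the interior angle at the middle atom).
#' @param selectors list of atom selectors; each selector is a list with
#'   `atom` (atom name) and one of `role` (role label; "metal" may omit
#'   `atom`) or `residue` (residue name).
#' @return a `metric_spec`.
#' @export
metric_spec <- function(label, kind = c("distance", "angle"), selectors) {
  kind <- match.arg(kind)
  need <- if (kind == "distance") 2L else 3L
  if (length(selectors) != need) {
    stop("metric '", label, "': ", kind, " needs ", need, " selectors")
  }
  structure(list(label = label, kind = kind, selectors = selectors),
            class = "metric_spec")
}

resolve_selector <- function(system, sel, label) {
  a <- system$atoms
  if (!is.null(sel$role)) {
    ids <- system$roles[[sel$role]]
    if (is.null(ids)) stop("metric '", label, "': unknown role '", sel$role, "'")
    if (!is.null(sel$atom)) {
      ids <- ids[a$atom_name[match(ids, a$atom_id)] == sel$atom]
    }
  } else if (!is.null(sel$residue)) {
    ids <- a$atom_id[a$residue_name == sel$residue]
    if (!is.null(sel$atom)) {
      ids <- ids[a$atom_name[match(ids, a$atom_id)] == sel$atom]
    }
  } else stop("metric '", label, "': selector needs a role or residue")
  if (length(ids) == 0) {
    stop("metric '", label, "': selector matches no atom (",
         paste(unlist(sel), collapse = "/"), ")")
  }
  if (length(ids) > 1) {
    stop("metric '", label, "': ambiguous selector matches atoms ",
         paste(ids, collapse = ", "))
  }
  ids
}

#' Measure a metric on a structure
#'
#' @param structure a `qmdmd_system`.
#' @param spec a [metric_spec()].
#' @return distance in Angstrom or interior angle in degrees.
#' @export
measure <- function(structure, spec) {
  ids <- vapply(spec$selectors, resolve_selector, integer(1),
                system = structure, label = spec$label)
  p <- coords(structure, ids)
  if (spec$kind == "distance") {
    sqrt(sum((p[1, ] - p[2, ])^2))
  } else {
    interior_angle(p[1, ], p[2, ], p[3, ])
  }
}

#' Default metric set for toy metal sites
#'
#' The coordination-sphere distances, the donor-acceptor geometry, and the
#' near-attack collinearity angle.
#'
#' @param system optional system used to drop metrics whose atoms are absent.
#' @return list of `metric_spec`s.
#' @export
default_metric_specs <- function(system = NULL) {
  rsel <- function(residue, atom) list(residue = residue, atom = atom)
  metal <- list(role = "metal")
  specs <- list(
    metric_spec("Metal-O1(Arm1)", "distance", list(metal, rsel("AR1", "O1"))),
    metric_spec("Metal-O2(Arm1)", "distance", list(metal, rsel("AR1", "O2"))),
    metric_spec("Metal-O(Arm2)", "distance", list(metal, rsel("AR2", "O1"))),
    metric_spec("Metal-O1(Arm3)", "distance", list(metal, rsel("AR3", "O1"))),
    metric_spec("Metal-O(water)", "distance", list(metal, rsel("HOH", "OW"))),
    metric_spec("Metal-O1(Sub)", "distance", list(metal, rsel("SUB", "O1"))),
    metric_spec("Metal-O2(Sub)", "distance", list(metal, rsel("SUB", "O2"))),
    metric_spec("O2(Sub)-C(Don)", "distance",
                list(rsel("SUB", "O2"), rsel("DON", "CM"))),
    metric_spec("O2(Sub)-S(Don)", "distance",
                list(rsel("SUB", "O2"), rsel("DON", "SD"))),
    metric_spec("O2(Sub)-C(Don)-S(Don)", "angle",
                list(rsel("SUB", "O2"), rsel("DON", "CM"), rsel("DON", "SD"))),
    metric_spec("O(Arm1)-O(water)", "distance",
                list(rsel("AR1", "O1"), rsel("HOH", "OW"))),
    metric_spec("O2(Sub)-N(Base)", "distance",
                list(rsel("SUB", "O2"), rsel("BAS", "NB")))
  )
  if (!is.null(system)) {
    ok <- vapply(specs, function(sp) {
      !inherits(try(measure(system, sp), silent = TRUE), "try-error")
    }, logical(1))
    specs <- specs[ok]
  }
  specs
}

#' Ensemble statistics of metrics, Table-style
#'
#' Mean and sample standard deviation (n-1 denominator) per metric over a set
#' of snapshots, rendered "mean (sd)" with 2 decimals for distances and 0 for
#' angles. Values more than 4 sd from the mean are counted as outliers in a
#' note -- never removed.
#'
#' @param snapshots list of `qmdmd_system`s, or a `qmdmd_trajectory`.
#' @param specs list of [metric_spec()]s.
#' @return tibble: label, units, mean, sd, n, rendered, n_outliers.
#' @export
ensemble_table <- function(snapshots, specs) {
  if (inherits(snapshots, "qmdmd_trajectory")) {
    traj <- snapshots
    base <- set_coords_template(traj)
    snapshots <- lapply(seq_len(dim(traj$positions)[3]),
                        function(f) set_coords(base, traj$positions[, , f]))
  }
  if (length(snapshots) < 1) stop("need at least one snapshot")
  rows <- lapply(specs, function(sp) {
    vals <- vapply(snapshots, measure, numeric(1), spec = sp)
    n <- length(vals)
    mu <- mean(vals)
    sdev <- if (n > 1) stats::sd(vals) else 0
    units <- if (sp$kind == "distance") "Angstrom" else "degrees"
    digits <- if (sp$kind == "distance") 2L else 0L
    rendered <- sprintf(paste0("%.", digits, "f (%.", digits, "f)"), mu, sdev)
    n_out <- if (sdev > 0) sum(abs(vals - mu) > 4 * sdev) else 0L
    tibble::tibble(label = sp$label, units = units, mean = mu, sd = sdev,
                   n = n, rendered = rendered, n_outliers = n_out)
  })
  out <- dplyr::bind_rows(rows)
  if (length(snapshots) == 1) attr(out, "note") <- "single snapshot (n = 1)"
  out
}

set_coords_template <- function(traj) {
  structure(list(atoms = traj$atoms, bonds = tibble::tibble(),
                 roles = traj$roles %||% list()),
            class = "qmdmd_system")
}

#' Compare metric tables across metal variants
#'
#' Side-by-side means with per-metric direction flags relative to the first
#' (reference) variant.
#'
#' @param tables named list of [ensemble_table()] outputs (first = reference).
#' @param tol equality tolerance.
#' @return tibble with one row per metric: label, one mean column per
#'   variant, and one direction column (longer/shorter/equal) per non-reference
#'   variant.
#' @export
compare_variants <- function(tables, tol = 1e-6) {
  stopifnot(length(tables) >= 2)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("variant", seq_along(tables))
  }
  ref <- tables[[1]]
  for (nm in names(tables)[-1]) {
    if (!identical(tables[[nm]]$label, ref$label)) {
      stop("variant '", nm, "' reports different metrics than the reference")
    }
  }
  out <- tibble::tibble(label = ref$label, units = ref$units)
  for (nm in names(tables)) out[[paste0("mean_", nm)]] <- tables[[nm]]$mean
  for (nm in names(tables)[-1]) {
    d <- tables[[nm]]$mean - ref$mean
    out[[paste0("vs_ref_", nm)]] <-
      ifelse(abs(d) <= tol, "equal", ifelse(d > 0, "longer", "shorter"))
  }
  out
}
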