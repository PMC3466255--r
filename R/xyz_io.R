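#' Write a multi-frame XYZ trajectory with a TSV energy sidecar
#'
#' All snapshots must share one atom ordering. The sidecar (same path with a
#' `.tsv` extension appended) holds one row per frame: frame index, DMD time
#' in t.u., and potential energy in kcal/mol.
#'
#' @param snapshots list of `qmdmd_system` objects, or a `qmdmd_trajectory`.
#' @param path output XYZ file.
#' @param energies numeric potential energies, one per frame (kcal/mol).
#' @param times numeric frame times in t.u. (defaults to the frame index).
#' @return invisibly, a list with the two file paths written.
#' @export
write_trajectory <- function(snapshots, path, energies = NULL, times = NULL) {
  if (inherits(snapshots, "qmdmd_trajectory")) {
    traj <- snapshots
    if (is.null(energies)) energies <- traj$frames$potential_energy
    if (is.null(times)) times <- traj$frames$time
    labels <- traj$atoms$element
    frames <- lapply(seq_len(dim(traj$positions)[3]),
                     function(k) traj$positions[, , k])
  } else {
    if (length(snapshots) == 0) stop("empty snapshot list")
    counts <- vapply(snapshots, function(s) nrow(s$atoms), integer(1))
    if (length(unique(counts)) != 1) {
      stop("snapshots differ in atom count: ", paste(unique(counts), collapse = ", "))
    }
    labels <- snapshots[[1]]$atoms$element
    frames <- lapply(snapshots, coords)
  }
  n_frame <- length(frames)
  if (is.null(times)) times <- seq_len(n_frame)
  if (is.null(energies)) energies <- rep(NA_real_, n_frame)
  if (length(energies) != n_frame) stop("need one energy per frame")

  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frame)) {
    m <- frames[[k]]
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf("frame %d time %.6g energy %.10g", k, times[k], energies[k]), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", labels, m[, 1], m[, 2], m[, 3]), con)
  }
  sidecar <- paste0(path, ".tsv")
  utils::write.table(
    data.frame(frame = seq_len(n_frame), time_tu = times, potential_energy = energies),
    sidecar, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(list(xyz = path, sidecar = sidecar))
}

#' Read a multi-frame XYZ file written by [write_trajectory()]
#'
#' @param path XYZ file path.
#' @return list with `labels` (element symbols) and `frames` (list of n x 3
#'   coordinate matrices).
#' @export
read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); labels <- NULL; pos <- 1L
  while (pos <= length(lines)) {
    n <- as.integer(lines[pos])
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    labels <- vapply(parts, `[[`, character(1), 1L)
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- m
    pos <- pos + 2L + n
  }
  list(labels = labels, frames = frames)
}
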