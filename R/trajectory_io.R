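#' Write a trajectory as extended XYZ
#'
#' One block per frame: an atom-count line, a comment line
#' `time=<t> box="Lx Ly Lz"`, then one line per atom with columns
#' `species x y z vx vy vz`. Numbers carry >= 9 significant digits.
#'
#' @param traj a `glyco_trajectory`.
#' @param path output file path.
#' @param topology_path optional path for the plain-text topology sidecar
#'   (TSV: index, role, chain_id, chain_pos, anchor, mass).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, topology_path = NULL) {
  stopifnot(inherits(traj, "glyco_trajectory"))
  if (length(traj$frames) == 0) stop("cannot write an empty trajectory")
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(traj$frames[[1]]$pos)
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    writeLines(as.character(n), con)
    writeLines(sprintf('time=%.10g box="%.10g %.10g %.10g"', traj$times[k],
                       traj$box[1], traj$box[2], traj$box[3]), con)
    writeLines(sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
                       traj$species, fr$pos[, 1], fr$pos[, 2], fr$pos[, 3],
                       fr$vel[, 1], fr$vel[, 2], fr$vel[, 3]), con)
  }
  if (!is.null(topology_path)) write_topology(traj$topology, topology_path)
  invisible(path)
}

#' Write / read a topology sidecar
#'
#' @param topology data.frame with columns index, role, chain_id, chain_pos,
#'   anchor, mass.
#' @param path file path.
#' @return `path` / the topology data.frame.
#' @export
write_topology <- function(topology, path) {
  utils::write.table(topology, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read an extended-XYZ trajectory
#'
#' Validates a constant particle count across frames, strictly increasing
#' times, and the presence of velocity columns (the analyses require
#' velocities).
#'
#' @param path extended-XYZ file written by [write_trajectory()] (or any
#'   compatible file).
#' @param topology_path optional topology sidecar; when absent, all
#'   particles are treated as solvent.
#' @param units unit-scale map attached to the trajectory.
#' @return a `glyco_trajectory`.
#' @export
read_trajectory <- function(path, topology_path = NULL,
                            units = c(length_nm = 1, time_ps = 1)) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a valid extended-XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("bad atom count on line 1")
  stride <- n + 2L
  if (length(lines) %% stride != 0) {
    # locate the first broken frame for the error message
    off <- 1L; fr <- 1L
    while (off <= length(lines)) {
      nk <- suppressWarnings(as.integer(trimws(lines[off])))
      if (is.na(nk) || nk != n)
        stop(sprintf("frame %d has %s atoms, expected %d", fr,
                     ifelse(is.na(nk), "a malformed count", nk), n))
      if (off + nk + 1L > length(lines))
        stop(sprintf("frame %d is truncated (expected %d atoms)", fr, n))
      off <- off + nk + 2L; fr <- fr + 1L
    }
    stop("inconsistent frame structure in ", path)
  }
  nfr <- length(lines) %/% stride
  counts <- suppressWarnings(as.integer(trimws(lines[(seq_len(nfr) - 1L) * stride + 1L])))
  bad <- which(counts != n)
  if (length(bad))
    stop(sprintf("frame %d has %d atoms, expected %d", bad[1], counts[bad[1]], n))
  comments <- lines[(seq_len(nfr) - 1L) * stride + 2L]
  times <- as.numeric(sub('.*time=([-0-9.eE+]+).*', '\\1', comments))
  if (any(is.na(times))) stop("missing time= field in a frame comment line")
  if (any(diff(times) <= 0))
    stop(sprintf("frame times not strictly increasing at frame %d",
                 which(diff(times) <= 0)[1] + 1L))
  boxm <- regmatches(comments[1],
                     regexec('box="([-0-9.eE+ ]+)"', comments[1]))[[1]]
  if (length(boxm) < 2) stop("missing box= field in frame comment line")
  box <- as.numeric(strsplit(trimws(boxm[2]), "\\s+")[[1]])
  if (length(box) != 3 || any(box <= 0)) stop("box must be three positive lengths")

  atom_rows <- unlist(lapply(seq_len(nfr), function(k)
    (k - 1L) * stride + 2L + seq_len(n)))
  toks <- strsplit(trimws(lines[atom_rows]), "\\s+")
  ncols <- lengths(toks)
  short <- which(ncols < 7)
  if (length(short)) {
    fr <- (short[1] - 1L) %/% n + 1L
    stop(sprintf("frame %d: atom line has %d columns; velocity columns (vx vy vz) required",
                 fr, ncols[short[1]]))
  }
  tm <- matrix(unlist(toks), ncol = ncols[1], byrow = TRUE)
  species <- tm[seq_len(n), 1]
  num <- matrix(as.numeric(tm[, 2:7]), ncol = 6)
  if (anyNA(num)) stop("non-numeric coordinate/velocity field in ", path)
  frames <- lapply(seq_len(nfr), function(k) {
    rows <- (k - 1L) * n + seq_len(n)
    list(pos = num[rows, 1:3, drop = FALSE], vel = num[rows, 4:6, drop = FALSE])
  })
  topology <- if (!is.null(topology_path)) read_topology(topology_path)
  else data.frame(index = seq_len(n), role = "solvent",
                  chain_id = NA_integer_, chain_pos = NA_integer_,
                  anchor = NA_integer_, mass = 1)
  if (nrow(topology) != n)
    stop(sprintf("topology has %d particles, trajectory has %d",
                 nrow(topology), n))
  traj <- list(times = times, frames = frames, species = species,
               topology = topology, box = box, units = units, log = NULL)
  class(traj) <- "glyco_trajectory"
  traj
}

#' Write a delimited analysis table
#'
#' All numeric analysis outputs (profiles, PDFs, shear series, segment
#' tracks) are written as TSV with a self-describing header. `schema` is the
#' required column-name vector; a mismatch in names or arity is an error.
#'
#' @param rows a data.frame.
#' @param schema character vector of required column names, in order.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, schema, path) {
  if (!is.data.frame(rows)) stop("rows must be a data.frame")
  if (!identical(names(rows), as.character(schema))) {
    off <- setdiff(union(names(rows), schema),
                   intersect(names(rows), schema))
    stop("schema mismatch: offending column(s) ",
         paste(if (length(off)) off else "(order)", collapse = ", "))
  }
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.10g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Export one frame as PDB (coordinates only)
#'
#' Coordinates are converted to Angstrom through the trajectory's
#' `length_nm` unit scale (1 nm = 10 A). Intended for visualisation.
#'
#' @param traj a `glyco_trajectory`.
#' @param frame frame index.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_frame <- function(traj, frame, path) {
  stopifnot(frame >= 1, frame <= length(traj$frames))
  p <- traj$frames[[frame]]$pos * traj$units[["length_nm"]] * 10
  el <- substr(traj$species, 1, 1)
  lines <- sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                   seq_len(nrow(p)) %% 100000, el, "BEA",
                   seq_len(nrow(p)) %% 10000, p[, 1], p[, 2], p[, 3], el)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
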