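#' Read a multi-frame trajectory
#'
#' Reads a Cartesian trajectory into a tidy frame-by-atom table. Supported
#' formats are multi-frame XYZ (atom-count line, comment line, atom lines) and
#' PDB (`ATOM`/`HETATM` records, one frame per `MODEL`). Element symbols are
#' normalised to title case. All frames must share the same atom count and
#' element sequence.
#'
#' @param path Path to the trajectory file.
#' @param format `"auto"` (from the file extension), `"xyz"` or `"pdb"`.
#' @return A tibble of class `mt_trajectory` with columns `frame`, `atom`,
#'   `element`, `x`, `y`, `z` (coordinates in Angstrom). Atom ids are 1-based
#'   and constant across frames.
#' @export
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("1", "a helium atom", "He 0 0 0"), f)
#' read_trajectory(f)
read_trajectory <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "ent")) "pdb" else "xyz"
  }
  traj <- switch(format, xyz = read_xyz_file(path), pdb = read_pdb_file(path))
  check_trajectory(traj)
  traj
}

read_xyz_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    frame <- frame + 1L
    if (is.na(n) || n < 0) {
      stop("malformed XYZ frame ", frame, ": expected atom count at line ", i, call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop("malformed XYZ frame ", frame, ": truncated at line ", length(lines), call. = FALSE)
    }
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    if (n == 0L) atom_lines <- character(0)
    parts <- strsplit(trimws(atom_lines), "[[:space:]]+")
    ok <- vapply(parts, length, 0L) >= 4L
    if (any(!ok)) {
      stop("malformed XYZ frame ", frame, ": bad atom line ", i + 1L + which(!ok)[1], call. = FALSE)
    }
    el <- vapply(parts, `[[`, "", 1L)
    xyz <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
    if (anyNA(xyz)) {
      stop("malformed XYZ frame ", frame, ": non-numeric coordinate near line ", i + 2L, call. = FALSE)
    }
    frames[[frame]] <- tibble::tibble(
      frame = frame, atom = seq_len(n), element = normalize_symbol(el),
      x = if (n) xyz[1, ] else numeric(0),
      y = if (n) xyz[2, ] else numeric(0),
      z = if (n) xyz[3, ] else numeric(0)
    )
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path, call. = FALSE)
  new_trajectory(dplyr::bind_rows(frames))
}

read_pdb_file <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  # first altloc wins
  keep <- !duplicated(paste(at$chain, at$resno, at$elety))
  el <- at$elesy[keep]
  if (is.null(el) || all(is.na(el)) || any(!nzchar(trimws(el)))) {
    el <- gsub("[^A-Za-z].*$", "", trimws(at$elety[keep]))
    el <- gsub("^[0-9]+", "", el)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  idx <- which(keep)
  frames <- lapply(seq_len(nrow(xyz)), function(f) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    tibble::tibble(
      frame = f, atom = seq_along(idx), element = normalize_symbol(el),
      x = m[, 1], y = m[, 2], z = m[, 3]
    )
  })
  new_trajectory(dplyr::bind_rows(frames))
}

new_trajectory <- function(df, timestep = NA_real_) {
  structure(df, class = c("mt_trajectory", class(tibble::tibble()))) |>
    (\(x) { attr(x, "timestep") <- timestep; x })()
}

check_trajectory <- function(traj) {
  per_frame <- split(traj$element, traj$frame)
  n0 <- length(per_frame[[1]])
  for (f in seq_along(per_frame)) {
    if (length(per_frame[[f]]) != n0) {
      stop("inconsistent atom count: frame ", f, " has ", length(per_frame[[f]]),
           " atoms vs ", n0, " in frame 1", call. = FALSE)
    }
    if (!identical(per_frame[[f]], per_frame[[1]])) {
      stop("inconsistent element sequence in frame ", f, call. = FALSE)
    }
  }
  if (!all(is.finite(traj$x) & is.finite(traj$y) & is.finite(traj$z))) {
    stop("non-finite coordinates in trajectory", call. = FALSE)
  }
  invisible(traj)
}

#' Number of frames in a trajectory
#' @param traj A trajectory tibble from [read_trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(unique(traj$frame))

#' Extract one snapshot from a trajectory
#' @param traj A trajectory tibble.
#' @param frame Frame number (1-based).
#' @return A snapshot tibble with columns `atom`, `element`, `x`, `y`, `z`.
#' @export
traj_snapshot <- function(traj, frame) {
  out <- traj[traj$frame == frame, c("atom", "element", "x", "y", "z")]
  if (!nrow(out)) stop("no frame ", frame, " in trajectory", call. = FALSE)
  tibble::as_tibble(out)
}

#' Write a structure (or trajectory) as XYZ
#'
#' @param structure A snapshot tibble (`atom`, `element`, `x`, `y`, `z`) or a
#'   trajectory tibble with a `frame` column (written as multi-frame XYZ).
#' @param path Output path.
#' @param comment Comment line (recycled across frames).
#' @return `path`, invisibly. Round-tripping through [read_trajectory()]
#'   preserves elements exactly and coordinates to 1e-4 Angstrom.
#' @export
write_xyz <- function(structure, path, comment = "written by moltopo") {
  if (!all(is.finite(structure$x) & is.finite(structure$y) & is.finite(structure$z))) {
    stop("refusing to write non-finite coordinates", call. = FALSE)
  }
  frames <- if ("frame" %in% names(structure)) {
    lapply(unique(structure$frame), function(f) structure[structure$frame == f, ])
  } else list(structure)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path, call. = FALSE)
  on.exit(close(con))
  for (s in frames) {
    writeLines(as.character(nrow(s)), con)
    writeLines(comment, con)
    if (nrow(s)) {
      writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", s$element, s$x, s$y, s$z), con)
    }
  }
  invisible(path)
}

#' Assemble a trajectory from a list of snapshots
#' @param snapshots List of snapshot tibbles with identical atom ordering.
#' @param timestep Optional timestep metadata (fs).
#' @return An `mt_trajectory` tibble.
#' @export
as_trajectory <- function(snapshots, timestep = NA_real_) {
  df <- dplyr::bind_rows(lapply(seq_along(snapshots), function(i) {
    dplyr::mutate(snapshots[[i]], frame = i, .before = 1)
  }))
  traj <- new_trajectory(df, timestep)
  check_trajectory(traj)
  traj
}
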