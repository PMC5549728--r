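#' Construct a trajectory handle
#'
#' Frames of coordinates (nm) over a reference structure, with per-frame
#' times (ps) and optional per-frame box.
#'
#' @param model reference `habind_structure`.
#' @param coords numeric array `frames x atoms x 3` (nm), or a list of
#'   `atoms x 3` matrices.
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param box optional `frames x 3` matrix of box vectors, or `NULL`.
#' @param stride integer metadata: simulation steps between saved frames.
#' @return object of class `habind_traj`.
#' @export
trajectory <- function(model, coords, times = NULL, box = NULL, stride = 1L) {
  stopifnot(inherits(model, "habind_structure"))
  if (is.list(coords)) {
    arr <- array(NA_real_, dim = c(length(coords), nrow(coords[[1]]), 3))
    for (i in seq_along(coords)) arr[i, , ] <- coords[[i]]
    coords <- arr
  }
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be frames x atoms x 3")
  if (dim(coords)[1] == 0L) stop("empty trajectory: zero frames")
  if (dim(coords)[2] != nrow(model$atoms))
    stop("topology mismatch: trajectory has ", dim(coords)[2],
         " atoms, model has ", nrow(model$atoms))
  nf <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(model = model, coords = coords, times = times,
                 box = box, stride = as.integer(stride)),
            class = "habind_traj")
}

#' @export
print.habind_traj <- function(x, ...) {
  cat("<habind_traj> ", n_frames(x), " frames x ", n_atoms(x), " atoms, t = ",
      x$times[1], " .. ", x$times[n_frames(x)], " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `habind_traj`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj a `habind_traj`.
#' @param i frame index (1-based).
#' @return `atoms x 3` matrix in nm.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range: ", i)
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Subset a trajectory by frames
#' @param traj a `habind_traj`.
#' @param frames integer frame indices to keep (in order).
#' @export
subset_frames <- function(traj, frames) {
  frames <- as.integer(frames)
  if (any(frames < 1 | frames > n_frames(traj))) stop("frame window out of range")
  trajectory(traj$model,
             traj$coords[frames, , , drop = FALSE],
             traj$times[frames],
             if (!is.null(traj$box)) traj$box[frames, , drop = FALSE],
             traj$stride)
}

#' Read a trajectory file
#'
#' Dispatches on file extension: `.dcd` binary trajectories are read through
#' bio3d (Angstrom converted to nm), anything else is treated as the
#' package's columnar text interchange.
#'
#' @param path trajectory file.
#' @param model reference `habind_structure` (atom counts must match).
#' @param format `"auto"`, `"cols"` or `"dcd"`.
#' @return a `habind_traj`.
#' @export
read_trajectory <- function(path, model, format = c("auto", "cols", "dcd")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "cols"
  if (format == "dcd") read_trajectory_dcd(path, model) else
    read_trajectory_cols(path, model)
}

read_trajectory_dcd <- function(path, model) {
  m <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                error = function(e) stop("cannot read DCD '", path, "': ",
                                         conditionMessage(e)))
  na <- ncol(m) / 3
  if (na != nrow(model$atoms))
    stop("topology mismatch: DCD has ", na, " atoms, model has ",
         nrow(model$atoms))
  nf <- nrow(m)
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(m[f, ], ncol = 3, byrow = TRUE) / 10
  trajectory(model, coords, times = as.numeric(seq_len(nf) - 1L))
}

#' Columnar text trajectory interchange
#'
#' Plain-text format: comment header (`# natoms`, `# nframes`), then one row
#' per atom per frame with columns `frame time atom x y z` (frame and atom
#' 0-based, time in ps, coordinates in nm).
#'
#' @param traj a `habind_traj`.
#' @param path output file.
#' @export
write_trajectory_cols <- function(traj, path) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# habind columnar trajectory v1"),
               sprintf("# natoms %d", na),
               sprintf("# nframes %d", nf),
               "# frame time atom x y z"), con)
  frame <- rep(seq_len(nf) - 1L, each = na)
  time <- rep(traj$times, each = na)
  atom <- rep(seq_len(na) - 1L, times = nf)
  xyz <- matrix(aperm(traj$coords, c(2, 1, 3)), ncol = 3)
  df <- data.frame(frame = frame, time = time, atom = atom,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_cols
#' @param model reference `habind_structure`.
#' @export
read_trajectory_cols <- function(path, model) {
  df <- tryCatch(read.table(path, header = FALSE, comment.char = "#",
                            col.names = c("frame", "time", "atom",
                                          "x", "y", "z")),
                 error = function(e) stop("cannot parse columnar trajectory '",
                                          path, "': ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty trajectory: no frames in ", path)
  na <- nrow(model$atoms)
  frames <- sort(unique(df$frame))
  if (nrow(df) != length(frames) * na)
    stop("truncated trajectory: expected ", length(frames) * na,
         " rows (", length(frames), " frames x ", na, " atoms), found ",
         nrow(df))
  o <- order(df$frame, df$atom)
  df <- df[o, ]
  bad <- which(df$atom != rep(seq_len(na) - 1L, times = length(frames)))
  if (length(bad))
    stop("truncated or misordered frame near row ", bad[1])
  coords <- array(NA_real_, dim = c(length(frames), na, 3))
  coords[, , 1] <- matrix(df$x, nrow = length(frames), byrow = TRUE)
  coords[, , 2] <- matrix(df$y, nrow = length(frames), byrow = TRUE)
  coords[, , 3] <- matrix(df$z, nrow = length(frames), byrow = TRUE)
  times <- df$time[seq(1, nrow(df), by = na)]
  trajectory(model, coords, times = times)
}

#' Write a minimal DCD trajectory
#'
#' CHARMM-flavoured DCD without a unit-cell block; coordinates written in
#' Angstrom as single-precision floats. Intended for interchange tests with
#' independent DCD readers.
#'
#' @param traj a `habind_traj`.
#' @param path output file.
#' @export
write_dcd <- function(traj, path) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  con <- file(path, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  title <- formatC("habind minimal DCD writer", width = -80)
  writeBin(4L + 80L, con, size = 4)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(4L + 80L, con, size = 4)
  writeBin(4L, con, size = 4); writeBin(na, con, size = 4)
  writeBin(4L, con, size = 4)
  for (f in seq_len(nf)) {
    fc <- frame_coords(traj, f) * 10  # nm -> Angstrom
    for (d in 1:3) {
      writeBin(4L * na, con, size = 4)
      writeBin(as.numeric(fc[, d]), con, size = 4)
      writeBin(4L * na, con, size = 4)
    }
  }
  invisible(path)
}
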