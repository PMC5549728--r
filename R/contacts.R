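#' Contact parameters
#'
#' @param cutoff contact distance cutoff in nm (default 0.6). The boundary is
#'   inclusive: a pair exactly at the cutoff counts as a contact.
#' @param atoms `"heavy"` (default) or `"all"`.
#' @param pbc apply the minimum-image convention using the frame box.
#' @param stride frame stride used when scanning trajectories.
#' @export
contact_params <- function(cutoff = 0.6, atoms = c("heavy", "all"),
                           pbc = FALSE, stride = 1L) {
  atoms <- match.arg(atoms)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  structure(list(cutoff = cutoff, atoms = atoms, pbc = pbc,
                 stride = as.integer(stride)),
            class = "habind_contact_params")
}

# Squared distance matrix between two coordinate sets, optionally under the
# orthorhombic minimum-image convention.
dist2_matrix <- function(a, b, box = NULL) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

#' Minimum distance between two atom sets
#'
#' @param a,b coordinate matrices (`n x 3`, nm).
#' @param box optional length-3 box for the minimum-image convention.
#' @return minimum pairwise distance in nm.
#' @export
min_distance <- function(a, b, box = NULL) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty selection in min_distance")
  sqrt(min(dist2_matrix(a, b, box)))
}

frame_box <- function(traj, f, params) {
  if (!params$pbc) return(NULL)
  if (!is.null(traj$box)) as.numeric(traj$box[f, ]) else traj$model$box
}

restrict_heavy <- function(model, idx, params) {
  if (params$atoms == "heavy") idx[is_heavy(model)[idx]] else idx
}

#' Per-frame residue contact series
#'
#' For each protein residue, whether any of its atoms lies within the cutoff
#' of any ligand atom at each frame (the Table-1-style estimator).
#'
#' @param traj a `habind_traj`.
#' @param residues integer vector of protein residue numbers to score.
#' @param ligand_sel a `habind_selection` (or atom indices) for the ligand.
#' @param params a `habind_contact_params`.
#' @param protein_sel selection restricting the protein atoms (default: all
#'   atoms of chains tagged protein).
#' @return logical matrix `frames x residues` of class
#'   `habind_contact_series`, with frame times as an attribute.
#' @export
residue_contact_series <- function(traj, residues, ligand_sel,
                                   params = contact_params(),
                                   protein_sel = NULL) {
  model <- traj$model
  if (is.null(protein_sel))
    protein_sel <- selection_spec("protein", role = "protein", atoms = params$atoms)
  pidx <- restrict_heavy(model, resolve_selection(model, protein_sel), params)
  lidx <- restrict_heavy(model, resolve_selection(model, ligand_sel), params)
  pres <- model$atoms$resno[pidx]
  keep <- pres %in% residues
  pidx <- pidx[keep]; pres <- pres[keep]
  if (!length(pidx)) stop("no protein atoms found for requested residues")
  frames <- seq(1, n_frames(traj), by = params$stride)
  cut2 <- params$cutoff^2
  out <- matrix(FALSE, length(frames), length(residues),
                dimnames = list(NULL, as.character(residues)))
  grp <- split(seq_along(pidx), pres)
  for (fi in seq_along(frames)) {
    fc <- frame_coords(traj, frames[fi])
    d2 <- dist2_matrix(fc[pidx, , drop = FALSE], fc[lidx, , drop = FALSE],
                       frame_box(traj, frames[fi], params))
    mind <- vapply(grp, function(rows) min(d2[rows, ]), numeric(1))
    out[fi, names(grp)] <- mind <= cut2
  }
  structure(out, times = traj$times[frames], cutoff = params$cutoff,
            stride = params$stride, class = c("habind_contact_series", "matrix"))
}

#' Binding percentage of one residue
#'
#' 100 x (frames in contact) / (total frames).
#' @param series a `habind_contact_series`.
#' @param residue residue number.
#' @export
residue_binding_percent <- function(series, residue) {
  key <- as.character(residue)
  if (!key %in% colnames(series)) stop("unknown residue: ", residue)
  100 * sum(series[, key]) / nrow(series)
}

#' Aggregate binding percentages over replicas
#'
#' Mean binding percentage per residue across replicas with the standard
#' error of the mean (sample sd / sqrt(n)); with a single replica the SE is
#' reported as `NA` (the "not available" sentinel).
#'
#' @param series_list list of `habind_contact_series` with identical residue
#'   sets.
#' @return data.frame of class `habind_binding_table` with columns `residue`,
#'   `mean`, `se`, `n`, plus a `replicas` matrix attribute.
#' @export
replica_binding_table <- function(series_list) {
  if (!length(series_list)) stop("need at least one replica")
  cols <- colnames(series_list[[1]])
  for (s in series_list)
    if (!identical(colnames(s), cols))
      stop("replica residue sets differ")
  raw <- vapply(series_list, function(s) 100 * colSums(s) / nrow(s),
                numeric(length(cols)))
  reps <- if (length(cols) == 1) matrix(raw, ncol = 1,
                                        dimnames = list(NULL, cols))
  else t(raw)
  n <- length(series_list)
  m <- colMeans(reps)
  se <- if (n > 1) apply(reps, 2, sd) / sqrt(n) else rep(NA_real_, length(cols))
  out <- data.frame(residue = cols, mean = as.numeric(m), se = as.numeric(se),
                    n = n, stringsAsFactors = FALSE)
  attr(out, "replicas") <- reps
  class(out) <- c("habind_binding_table", "data.frame")
  out
}

#' Per-frame atom-pair contact counts between two selections
#'
#' @inheritParams residue_contact_series
#' @param sel_a,sel_b selections or atom indices.
#' @return integer vector per frame of class `habind_count_series`.
#' @export
contact_count_series <- function(traj, sel_a, sel_b, params = contact_params()) {
  model <- traj$model
  ia <- restrict_heavy(model, resolve_selection(model, sel_a), params)
  ib <- restrict_heavy(model, resolve_selection(model, sel_b), params)
  frames <- seq(1, n_frames(traj), by = params$stride)
  cut2 <- params$cutoff^2
  counts <- integer(length(frames))
  for (fi in seq_along(frames)) {
    fc <- frame_coords(traj, frames[fi])
    d2 <- dist2_matrix(fc[ia, , drop = FALSE], fc[ib, , drop = FALSE],
                       frame_box(traj, frames[fi], params))
    counts[fi] <- sum(d2 <= cut2)
  }
  structure(counts, times = traj$times[frames], stride = params$stride,
            class = "habind_count_series")
}

#' Mean atom-pair contact count per residue
#'
#' For each residue, the mean over frames of the number of
#' (residue atom, ligand atom) pairs within the cutoff (the per-arginine
#' profile estimator). Set `estimator = "ligand_atoms"` to instead count
#' distinct ligand atoms within the cutoff of the residue.
#'
#' @inheritParams residue_contact_series
#' @param estimator `"pairs"` (default) or `"ligand_atoms"`.
#' @return named numeric vector, one mean count per residue.
#' @export
contact_count_profile <- function(traj, residues, ligand_sel,
                                  params = contact_params(),
                                  estimator = c("pairs", "ligand_atoms"),
                                  protein_sel = NULL) {
  estimator <- match.arg(estimator)
  model <- traj$model
  if (is.null(protein_sel))
    protein_sel <- selection_spec("protein", role = "protein", atoms = params$atoms)
  pidx <- restrict_heavy(model, resolve_selection(model, protein_sel), params)
  lidx <- restrict_heavy(model, resolve_selection(model, ligand_sel), params)
  pres <- model$atoms$resno[pidx]
  keep <- pres %in% residues
  pidx <- pidx[keep]; pres <- pres[keep]
  if (!length(pidx)) stop("no protein atoms found for requested residues")
  frames <- seq(1, n_frames(traj), by = params$stride)
  cut2 <- params$cutoff^2
  grp <- split(seq_along(pidx), pres)
  acc <- setNames(numeric(length(residues)), as.character(residues))
  for (fi in seq_along(frames)) {
    fc <- frame_coords(traj, frames[fi])
    d2 <- dist2_matrix(fc[pidx, , drop = FALSE], fc[lidx, , drop = FALSE],
                       frame_box(traj, frames[fi], params))
    inc <- d2 <= cut2
    cnt <- vapply(grp, function(rows) {
      m <- inc[rows, , drop = FALSE]
      if (estimator == "pairs") sum(m) else sum(colSums(m) > 0)
    }, numeric(1))
    acc[names(grp)] <- acc[names(grp)] + cnt
  }
  acc / length(frames)
}

#' Contact contour: polymer residue x time contact counts
#'
#' Entry (i, t) is the atom-pair contact count between polymer
#' monosaccharide i (rows ordered from the reducing end) and the protein
#' selection at frame t.
#'
#' @inheritParams residue_contact_series
#' @param map a `habind_residue_map` for the polymer.
#' @return matrix of class `habind_contour` (`monosaccharides x frames`)
#'   with `mono_pos`, `disaccharide` and `times` attributes.
#' @export
contact_contour <- function(traj, map, protein_sel = NULL,
                            params = contact_params()) {
  stopifnot(inherits(map, "habind_residue_map"))
  model <- traj$model
  if (is.null(protein_sel))
    protein_sel <- selection_spec("protein", role = "protein", atoms = params$atoms)
  pidx <- restrict_heavy(model, resolve_selection(model, protein_sel), params)
  poly_chains <- names(model$roles)[model$roles == "polymer"]
  heavy_ok <- if (params$atoms == "heavy") is_heavy(model) else TRUE
  frames <- seq(1, n_frames(traj), by = params$stride)
  cut2 <- params$cutoff^2
  nres <- nrow(map)
  out <- matrix(0L, nres, length(frames))
  ridx <- lapply(seq_len(nres), function(i)
    which(model$atoms$chain %in% poly_chains &
            model$atoms$resno == map$resno[i] & heavy_ok))
  if (any(lengths(ridx) == 0))
    stop("residue map does not match the trajectory topology")
  lidx <- unlist(ridx)
  rgrp <- rep(seq_len(nres), lengths(ridx))
  for (fi in seq_along(frames)) {
    fc <- frame_coords(traj, frames[fi])
    d2 <- dist2_matrix(fc[lidx, , drop = FALSE], fc[pidx, , drop = FALSE],
                       frame_box(traj, frames[fi], params))
    out[, fi] <- as.integer(rowsum(rowSums(d2 <= cut2), rgrp))
  }
  structure(out, mono_pos = map$mono_pos, disaccharide = map$disaccharide,
            times = traj$times[frames], class = c("habind_contour", "matrix"))
}

#' Geometric hydrogen-bond detection in one frame
#'
#' Reports donor-acceptor pairs with distance at most `d_max`; when a
#' hydrogen is supplied for a donor, the donor-H-acceptor angle must also be
#' at least `angle_min` degrees.
#'
#' @param xyz `atoms x 3` coordinate matrix (nm).
#' @param donors integer atom indices of donor heavy atoms.
#' @param acceptors integer atom indices of acceptor heavy atoms.
#' @param hydrogens optional integer vector parallel to `donors` giving the
#'   donated hydrogen's atom index (`NA` = no hydrogen available).
#' @param d_max donor-acceptor distance criterion in nm (default 0.35).
#' @param angle_min donor-H-acceptor angle criterion in degrees (default 150).
#' @param box optional box for the minimum-image convention.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle` (NA when no hydrogen).
#' @export
hydrogen_bonds <- function(xyz, donors, acceptors, hydrogens = NULL,
                           d_max = 0.35, angle_min = 150, box = NULL) {
  if (!length(donors) || !length(acceptors))
    stop("empty donor or acceptor selection")
  if (!is.null(hydrogens) && length(hydrogens) != length(donors))
    stop("hydrogens must parallel donors")
  d2 <- dist2_matrix(xyz[donors, , drop = FALSE],
                     xyz[acceptors, , drop = FALSE], box)
  hits <- which(d2 <= d_max^2, arr.ind = TRUE)
  res <- data.frame(donor = integer(), hydrogen = integer(),
                    acceptor = integer(), distance = numeric(),
                    angle = numeric())
  for (r in seq_len(nrow(hits))) {
    di <- donors[hits[r, 1]]; ai <- acceptors[hits[r, 2]]
    if (di == ai) next
    hi <- if (!is.null(hydrogens)) hydrogens[hits[r, 1]] else NA_integer_
    ang <- NA_real_
    if (!is.na(hi)) {
      v1 <- xyz[di, ] - xyz[hi, ]; v2 <- xyz[ai, ] - xyz[hi, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < angle_min) next
    }
    res <- rbind(res, data.frame(donor = di, hydrogen = hi, acceptor = ai,
                                 distance = sqrt(d2[hits[r, 1], hits[r, 2]]),
                                 angle = ang))
  }
  res
}

#' Export a binding table as TSV
#'
#' One row per residue with the per-mode mean percentage and standard error,
#' mirroring the reference-table layout.
#' @param tables named list of `habind_binding_table` (one per mode) or a
#'   single table.
#' @param path output file.
#' @export
write_binding_table <- function(tables, path) {
  if (inherits(tables, "habind_binding_table")) tables <- list(value = tables)
  res <- tables[[1]]$residue
  out <- data.frame(residue = res, stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    stopifnot(identical(tables[[nm]]$residue, res))
    out[[paste0(nm, "_percent")]] <- round(tables[[nm]]$mean, 1)
    out[[paste0(nm, "_se")]] <- round(tables[[nm]]$se, 1)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a contact contour as long-format TSV
#'
#' One row per (polymer residue, frame): `mono_pos`, `disaccharide`,
#' `time`, `contacts`.
#' @param contour a `habind_contour`.
#' @param path output file.
#' @export
write_contour <- function(contour, path) {
  times <- attr(contour, "times")
  df <- data.frame(
    mono_pos = rep(attr(contour, "mono_pos"), times = ncol(contour)),
    disaccharide = rep(attr(contour, "disaccharide"), times = ncol(contour)),
    time = rep(times, each = nrow(contour)),
    contacts = as.integer(contour))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
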