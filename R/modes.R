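#' Reference binding-mode fingerprints
#'
#' The packaged per-residue contact percentages (with replica standard
#' errors) characterising the crystallographic, parallel and upright binding
#' modes over the canonical 39-residue reference set.
#'
#' @return data.frame with columns `residue`, one percentage and one `_se`
#'   column per mode; attribute `modes` lists the mode names.
#' @export
reference_fingerprints <- function() {
  path <- system.file("extdata", "reference_fingerprints.tsv",
                      package = "habind", mustWork = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  attr(df, "modes") <- c("crystallographic", "parallel", "upright")
  df
}

#' Residue numbers of the reference fingerprint set
#' @return integer vector (canonical numbering).
#' @export
reference_residues <- function() {
  as.integer(sub("^[A-Z]", "", reference_fingerprints()$residue))
}

#' Contact fingerprint of a trajectory window
#'
#' Binding percentage over the window for each residue of the reference set
#' (or a caller-supplied set).
#'
#' @param traj a `habind_traj`.
#' @param ligand_sel ligand selection (default: chains tagged polymer).
#' @param window integer frame indices (default: all frames).
#' @param params a `habind_contact_params`.
#' @param residues residue numbers scored (default the reference set).
#' @return object of class `habind_fingerprint`: named numeric vector of
#'   percentages with `frames` attribute.
#' @export
fingerprint <- function(traj, ligand_sel = NULL, window = NULL,
                        params = contact_params(),
                        residues = reference_residues()) {
  if (is.null(ligand_sel))
    ligand_sel <- selection_spec("ligand", role = "polymer", atoms = params$atoms)
  if (!is.null(window)) {
    if (!length(window)) stop("empty window")
    traj <- subset_frames(traj, window)
  }
  series <- residue_contact_series(traj, residues, ligand_sel, params)
  pct <- 100 * colSums(series) / nrow(series)
  structure(setNames(as.numeric(pct), colnames(series)),
            frames = nrow(series), class = "habind_fingerprint")
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Classify a fingerprint against the reference modes
#'
#' Cosine similarity of the fingerprint against each reference mode column;
#' the label is the best mode when the best similarity reaches the
#' threshold, `"ambiguous"` otherwise and `"unbound"` for an all-zero
#' fingerprint. Cosine is scale-invariant, so the contact pattern (not its
#' magnitude) is the signature.
#'
#' @param fp a `habind_fingerprint` or named numeric vector (names =
#'   residues in reference order).
#' @param refs reference table from [reference_fingerprints()].
#' @param threshold minimum best similarity for an unambiguous label
#'   (default 0.80).
#' @return list of class `habind_mode`: `label`, `similarity` (named vector),
#'   `threshold`.
#' @export
classify <- function(fp, refs = reference_fingerprints(), threshold = 0.80) {
  modes <- attr(refs, "modes") %||% c("crystallographic", "parallel", "upright")
  res_nums <- as.character(sub("^[A-Z]", "", refs$residue))
  v <- as.numeric(fp)
  if (!is.null(names(fp))) {
    if (!identical(names(fp), res_nums) &&
        !identical(names(fp), as.character(refs$residue)))
      stop("fingerprint residue order does not match the reference set")
  } else if (length(v) != nrow(refs)) {
    stop("fingerprint length does not match the reference set")
  }
  sims <- vapply(modes, function(m) cosine_similarity(v, refs[[m]]), numeric(1))
  label <- if (all(v == 0)) "unbound"
  else if (max(sims) >= threshold) modes[which.max(sims)]
  else "ambiguous"
  structure(list(label = label, similarity = sims, threshold = threshold),
            class = "habind_mode")
}

#' @export
print.habind_mode <- function(x, ...) {
  cat("<habind_mode> ", x$label, " (",
      paste(sprintf("%s=%.3f", names(x$similarity), x$similarity),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Segment a label sequence into binding-mode episodes
#'
#' Run-length encodes time-ordered labels; runs shorter than `min_len` are
#' treated as flicker and absorbed into the preceding segment (or the
#' following one at the start of the sequence).
#'
#' @param labels character vector of window labels, time-ordered.
#' @param min_len minimum run length kept as its own segment (default 5).
#' @return data.frame with `start`, `end` (window indices) and `label`.
#' @export
detect_transitions <- function(labels, min_len = 5L) {
  if (!length(labels)) return(data.frame(start = integer(), end = integer(),
                                         label = character()))
  r <- rle(labels)
  keep <- r$lengths >= min_len
  if (!any(keep)) keep[which.max(r$lengths)] <- TRUE
  # absorb short runs into the previous kept segment
  lab <- character(length(labels))
  cur <- r$values[which(keep)[1]]
  pos <- 1L
  for (i in seq_along(r$lengths)) {
    if (keep[i]) cur <- r$values[i]
    lab[pos:(pos + r$lengths[i] - 1L)] <- cur
    pos <- pos + r$lengths[i]
  }
  r2 <- rle(lab)
  ends <- cumsum(r2$lengths)
  data.frame(start = c(1L, head(ends, -1) + 1L), end = ends,
             label = r2$values, stringsAsFactors = FALSE)
}

#' Dihedral angle of four points
#'
#' Standard atan2 formulation; returns degrees in (-180, 180].
#' @param p1,p2,p3,p4 numeric length-3 coordinates.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi  # IUPAC sign
  if (ang <= -180) ang <- ang + 360
  ang
}

#' A/B-form assignment of the key-arginine loop
#'
#' The backbone phi dihedral of the residue following the key arginine
#' (Y42-like, computed from C(i-1), N(i), CA(i), C(i)) acts as a bistable
#' switch. A frame is in the B form only when phi falls in the B basin AND
#' the key arginine's side chain donates at least one hydrogen bond to the
#' ligand; otherwise it is in the A form. The ligand-free A default encodes
#' that the B form requires the bound ligand.
#'
#' @param traj a `habind_traj` over an atomistic model with backbone atoms.
#' @param key_residue residue number of the key arginine (default 41).
#' @param ligand_sel selection for ligand acceptor atoms (default: heavy N/O
#'   atoms of chains tagged polymer).
#' @param b_basin length-2 numeric: phi interval (degrees) of the B basin,
#'   default `c(-180, 0)` (half-open on the right).
#' @param hb_dist,hb_angle hydrogen-bond criteria passed to
#'   [hydrogen_bonds()].
#' @return data.frame per frame: `time`, `phi`, `r41_hbonds`, `state`.
#' @export
ab_form <- function(traj, key_residue = 41L, ligand_sel = NULL,
                    b_basin = c(-180, 0), hb_dist = 0.35, hb_angle = 150) {
  model <- traj$model
  a <- model$atoms
  prot <- names(model$roles)[model$roles == "protein"]
  ip <- a$chain %in% prot
  idx <- function(resno, name) {
    i <- which(ip & a$resno == resno & a$name == name)
    if (length(i) != 1L)
      stop("backbone atom ", name, " of residue ", resno,
           " missing or ambiguous")
    i
  }
  iC0 <- idx(key_residue, "C")
  iN <- idx(key_residue + 1L, "N")
  iCA <- idx(key_residue + 1L, "CA")
  iC <- idx(key_residue + 1L, "C")
  # donor atoms of the key arginine side chain (guanidinium N)
  don <- which(ip & a$resno == key_residue &
                 a$name %in% c("NE", "NH1", "NH2"))
  if (!length(don))
    don <- which(ip & a$resno == key_residue & toupper(a$element) == "N" &
                   a$name != "N")
  acc <- integer(0)
  if (is.null(ligand_sel)) {
    poly <- names(model$roles)[model$roles == "polymer"]
    acc <- which(a$chain %in% poly & toupper(a$element) %in% c("N", "O"))
  } else acc <- resolve_selection(model, ligand_sel)
  nf <- n_frames(traj)
  phi <- numeric(nf); nhb <- integer(nf)
  for (f in seq_len(nf)) {
    fc <- frame_coords(traj, f)
    phi[f] <- dihedral(fc[iC0, ], fc[iN, ], fc[iCA, ], fc[iC, ])
    nhb[f] <- if (length(don) && length(acc))
      nrow(hydrogen_bonds(fc, don, acc, d_max = hb_dist, angle_min = hb_angle))
    else 0L
  }
  in_b <- phi >= b_basin[1] & phi < b_basin[2]
  state <- ifelse(in_b & nhb >= 1L, "B", "A")
  data.frame(time = traj$times, phi = phi, r41_hbonds = nhb, state = state,
             stringsAsFactors = FALSE)
}
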