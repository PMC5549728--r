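# Coarse-grained Brownian-dynamics toy generator.
#
# A rigid pseudo-residue cluster ("receptor") interacts with a linear
# alternating GlcUA/GlcNAc bead polymer through Gaussian attraction wells
# planted on one of three disjoint surface patches (crystallographic /
# upright / parallel, with ordered well depths) plus a shared key-site
# cluster around the R41-like bead. Scenario presets freeze one side:
# binding/sliding/umbrella runs freeze the polymer (as a restrained HA
# strand), the electric-field assay freezes the receptor (the receptor is
# fixed, the charged polymer is pulled away). Dynamics are overdamped
# Langevin; the attraction prefactor is calibrated at construction so the
# nominal well depth equals the true minimum of the bound-pose potential
# along the umbrella coordinate.

AA3 <- c(N = "ASN", R = "ARG", K = "LYS", G = "GLY", Y = "TYR", S = "SER",
         I = "ILE", T = "THR", C = "CYS", A = "ALA", L = "LEU", D = "ASP",
         E = "GLU", H = "HIS")

#' Patch-to-residue mapping used by the toy system
#'
#' Derived from the packaged reference fingerprints: the shared key-site
#' cluster holds the residues above 60% contact in every mode (R41-like core
#' plus its groove neighbours); each mode's patch holds the remaining
#' residues at or above 50% in that mode. Patches are spatially disjoint
#' bead clusters but may map to overlapping residue labels, exactly as the
#' reference table shows for groove residues contacted by several modes.
#' @return list with `shared`, `crystallographic`, `parallel`, `upright`,
#'   `back` character vectors of residue labels.
#' @export
toy_patch_map <- function() {
  ref <- reference_fingerprints()
  modes <- attr(ref, "modes")
  M <- as.matrix(ref[modes])
  shared <- ref$residue[apply(M, 1, min) >= 60]
  patches <- lapply(modes, function(m)
    ref$residue[ref[[m]] >= 50 & !(ref$residue %in% shared)])
  names(patches) <- modes
  back <- setdiff(ref$residue, c(shared, unlist(patches)))
  c(list(shared = shared), patches, list(back = back))
}

#' Configuration of the synthetic Brownian system
#'
#' Defaults define the package's standard study conditions: a 32-bead
#' (16-disaccharide) HA-like polymer with unit negative charges on the
#' GlcUA beads, well depths 28 / 21 / 14 kJ/mol for the crystallographic /
#' upright / parallel modes (ordering and gap structure of the reference
#' analysis, deep enough for bound states to persist at 310 K on the
#' coarse-grained timescale), 310 K, and a timestep validated so the
#' per-step RMS displacement stays below a tenth of the well width.
#'
#' @param polymer_beads number of monosaccharide beads (even).
#' @param bond_length polymer bond length (nm).
#' @param bond_k polymer bond spring constant (kJ mol^-1 nm^-2).
#' @param depths named numeric: well depth per mode (kJ/mol), ordered
#'   crystallographic > upright > parallel in the standard preset.
#' @param well_width Gaussian attraction width (nm): a scalar, or a named
#'   per-mode vector. The default widths narrow with binding strength (the
#'   crystallographic groove is the most shape-complementary, the parallel
#'   mode the loosest), which makes the bound registry corrugation scale
#'   with mode strength.
#' @param rep_strength,rep_width Gaussian excluded-volume prefactor (kJ/mol)
#'   and width (nm).
#' @param temperature heat-bath temperature (K).
#' @param diffusion diffusion coefficient for receptor body and polymer
#'   beads (nm^2/ps).
#' @param dt timestep (ps).
#' @param stride steps between saved frames.
#' @param charge charge on each GlcUA bead (e).
#' @param field uniform electric field vector, force per unit charge
#'   (kJ mol^-1 nm^-1 e^-1).
#' @param planted_mode one of "crystallographic", "parallel", "upright" or
#'   `NULL` (no attractive patch).
#' @param scenario mobility preset: `"binding"`, `"sliding"` (polymer
#'   frozen, receptor free), `"efield"` (receptor frozen, polymer free),
#'   `"umbrella"` (polymer frozen, receptor laterally tethered), `"free"`.
#' @param umbrella `NULL` or `list(center =, k =)` spring on the
#'   core-to-anchor distance (nm, kJ mol^-1 nm^-2).
#' @param box box lengths (nm); default fits the polymer with margin.
#' @return object of class `habind_toy_config`.
#' @export
toy_config <- function(polymer_beads = 32L, bond_length = 0.5, bond_k = 1000,
                       depths = c(crystallographic = 28, upright = 21,
                                  parallel = 14),
                       well_width = c(crystallographic = 0.18,
                                      upright = 0.22, parallel = 0.28),
                       rep_strength = 60, rep_width = 0.12,
                       temperature = 310, diffusion = 0.015, dt = 0.002,
                       stride = 500L, charge = -1, field = c(0, 0, 0),
                       planted_mode = NULL,
                       scenario = c("binding", "sliding", "efield",
                                    "umbrella", "free"),
                       umbrella = NULL, box = NULL) {
  scenario <- match.arg(scenario)
  if (polymer_beads < 4 || polymer_beads %% 2 != 0)
    stop("polymer_beads must be an even number >= 4")
  need <- c("crystallographic", "upright", "parallel")
  if (!all(need %in% names(depths)))
    stop("depths must name crystallographic, upright and parallel")
  if (!(depths["crystallographic"] >= depths["upright"] &&
        depths["upright"] >= depths["parallel"]))
    stop("well depths must be ordered crystallographic >= upright >= parallel")
  if (length(well_width) > 1 && !all(need %in% names(well_width)))
    stop("per-mode well widths must name crystallographic, upright and parallel")
  rms <- sqrt(2 * diffusion * dt)
  if (rms >= 0.1 * min(well_width))
    stop(sprintf(
      "timestep too large: per-step RMS displacement %.3g nm >= 0.1 x well width %.3g nm",
      rms, min(well_width)))
  if (!is.null(planted_mode))
    planted_mode <- match.arg(planted_mode,
                              c("crystallographic", "parallel", "upright"))
  if (is.null(box))
    box <- c(polymer_beads * bond_length + 6, 8, 8)
  cfg <- list(polymer_beads = as.integer(polymer_beads),
              bond_length = bond_length, bond_k = bond_k,
              depths = depths, well_width = well_width,
              rep_strength = rep_strength, rep_width = rep_width,
              temperature = temperature, diffusion = diffusion, dt = dt,
              stride = as.integer(stride), charge = charge, field = field,
              planted_mode = planted_mode, scenario = scenario,
              umbrella = umbrella, box = box,
              patch_map = toy_patch_map())
  class(cfg) <- "habind_toy_config"
  cfg
}

#' Plant a binding mode
#'
#' Makes the chosen patch (plus the shared key-site cluster) the attractive
#' surface and marks the receptor to start pre-bound at that patch.
#' @param config a `habind_toy_config`.
#' @param mode `"crystallographic"`, `"parallel"` or `"upright"`.
#' @export
plant_mode <- function(config, mode) {
  mode <- match.arg(mode, c("crystallographic", "parallel", "upright"))
  config$planted_mode <- mode
  config
}

# two-row bead layout for a patch: columns one polymer bond apart (kept
# commensurate with the 0.5 nm bead lattice so the bound registry is well
# defined), rows at +/- dy
patch_layout <- function(k, dy = 0.22, dx = 0.5) {
  col <- (seq_len(k) + 1L) %/% 2L
  ncol <- max(col)
  x <- (col - (ncol + 1L) %/% 2L) * dx  # integer lattice steps
  y <- ifelse(seq_len(k) %% 2 == 1, dy, -dy)
  cbind(x, y)
}

# attraction width for the planted mode (scalar configs apply everywhere)
mode_width <- function(config) {
  w <- config$well_width
  if (length(w) == 1) return(unname(w))
  if (is.null(config$planted_mode)) return(unname(min(w)))
  unname(w[[config$planted_mode]])
}

res_label_parts <- function(lab) {
  list(aa = AA3[substr(lab, 1, 1)], resno = as.integer(sub("^[A-Z]", "", lab)))
}

#' Build the toy structure
#'
#' Deterministic initial geometry: the polymer lies along x (reducing GlcNAc
#' end at negative x), the rigid receptor sits above it with the planted
#' patch and the shared key-site cluster in the contact plane and all other
#' pseudo-residues parked on the back side. The same config always yields a
#' bit-identical structure.
#'
#' @param config a `habind_toy_config`.
#' @return `habind_structure` with a `toy` attribute carrying bead roles,
#'   charges, the calibrated attraction prefactor and the bound pose.
#' @export
build_system <- function(config) {
  stopifnot(inherits(config, "habind_toy_config"))
  n <- config$polymer_beads
  b <- config$bond_length
  # polymer: bead 1 = GlcNAc (reducing end) at most-negative x
  px <- (seq_len(n) - (n + 1) / 2) * b
  poly <- data.frame(
    name = "C1", element = "C", resno = seq_len(n),
    resname = rep(c("NAG", "GCU"), length.out = n),
    chain = "H", stringsAsFactors = FALSE)
  poly_xyz <- cbind(px, 0, 0)

  pm <- config$patch_map
  modes <- c("crystallographic", "parallel", "upright")
  planted <- config$planted_mode
  beads <- list(); xyz <- list()
  add <- function(labels, coords, tag) {
    p <- res_label_parts(labels)
    beads[[length(beads) + 1]] <<- data.frame(
      name = tag, element = "C", resno = p$resno,
      resname = unname(p$aa), chain = "P", stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1]] <<- coords
  }
  # shared key-site cluster in the contact plane, R41-like bead central
  sh <- setdiff(pm$shared, "R41")
  mid <- ceiling((length(sh) + 1) / 2)
  sh <- append(sh, "R41", after = mid - 1)
  shx <- (seq_along(sh) - mid) * 0.5
  add(sh, cbind(shx, 0, 0), "S1")
  for (i in seq_along(modes)) {
    m <- modes[i]
    lay <- patch_layout(length(pm[[m]]))
    if (!is.null(planted) && m == planted) {
      add(pm[[m]], cbind(lay[, 1], lay[, 2], 0), "P1")
    } else {
      add(pm[[m]], cbind(lay[, 1], (i - 2) * 1.6 + lay[, 2], 1.5), "P1")
    }
  }
  if (length(pm$back)) {
    lay <- patch_layout(length(pm$back), dy = 0.15)
    add(pm$back, cbind(lay[, 1], lay[, 2], 2.2), "B1")
  }
  core <- data.frame(name = "CA", element = "C", resno = 1L, resname = "COR",
                     chain = "P", stringsAsFactors = FALSE)
  prot <- do.call(rbind, beads)
  prot_xyz <- do.call(rbind, xyz)
  prot <- rbind(prot, core)
  prot_xyz <- rbind(prot_xyz, c(0, 0, 0.9))
  d2 <- dist2_matrix(prot_xyz, prot_xyz)
  diag(d2) <- Inf
  if (min(d2) < 0.05^2) stop("geometry error: overlapping beads at construction")

  atoms <- rbind(prot, poly)
  # calibrate attraction and bound pose, then place the receptor
  sticky_local <- prot_xyz[prot_xyz[, 3] == 0, , drop = FALSE]
  calib <- if (!is.null(planted)) {
    calibrate_attraction(sticky_local, px, config)
  } else list(att_c = 0, h = 2.5, s = 0)
  z0 <- if (!is.null(planted)) calib$h else 2.5
  prot_xyz_glob <- cbind(prot_xyz[, 1] + calib$s, prot_xyz[, 2],
                         prot_xyz[, 3] + z0)
  allxyz <- rbind(prot_xyz_glob, poly_xyz)
  model <- structure_model(atoms, allxyz, box = config$box,
                           roles = c(P = "protein", H = "polymer"))
  np <- nrow(prot)
  contact_rows <- which(prot_xyz[, 3] == 0)
  attr(model, "toy") <- list(
    core_row = np, poly_rows = np + seq_len(n),
    sticky_rows = contact_rows, contact_rows = contact_rows,
    charges = c(rep(0, np), ifelse(poly$resname == "GCU", config$charge, 0)),
    att_c = calib$att_c, h_star = calib$h, s_star = calib$s,
    anchor = c(calib$s, 0, 0), planted_mode = planted)
  model
}

# lateral spring holding the receptor above the bound registry during
# umbrella scans (kJ mol^-1 nm^-2); the depth calibration integrates the
# transverse degrees of freedom under the same restraint
UMBRELLA_LATERAL_K <- 2000

.calibration_cache <- new.env(parent = emptyenv())

# Calibrate the attraction prefactor so the free-energy depth of the bound
# well along the vertical approach - with the transverse (x, y) motion of
# the restrained receptor integrated out - equals the requested well depth.
# This makes the nominal depth the ground truth for what an umbrella scan
# over the planted well measures, not just a potential-energy minimum.
calibrate_attraction <- function(sticky_local, poly_x, config) {
  eps <- unname(config$depths[config$planted_mode])
  if (eps <= 0)  # no well planted: keep the pose but switch attraction off
    return(list(att_c = 0, h = 1.0, s = 0, depth = 0))
  w <- mode_width(config); A <- config$rep_strength; s2 <- config$rep_width
  key <- paste(config$planted_mode, eps, w, A, s2, config$bond_length,
               length(poly_x), config$temperature, sep = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  kbt <- kB * config$temperature

  # coarse pass on the raw potential: registry s* and pose height h*
  hs <- seq(0.05, 2.5, by = 0.01)
  ss <- seq(0, config$bond_length, length.out = 11)[-11]
  u_att <- matrix(0, length(ss), length(hs))
  u_rep <- matrix(0, length(ss), length(hs))
  for (si in seq_along(ss)) {
    for (hi in seq_along(hs)) {
      dx <- outer(sticky_local[, 1] + ss[si], poly_x, "-")
      d2 <- dx^2 + sticky_local[, 2]^2 + hs[hi]^2
      u_att[si, hi] <- -sum(exp(-d2 / (2 * w^2)))
      u_rep[si, hi] <- A * sum(exp(-d2 / (2 * s2^2)))
    }
  }
  cc0 <- uniroot(function(cc) -min(cc * u_att + u_rep) - eps,
                 c(1e-6, 1e4), tol = 1e-8)$root
  tot <- cc0 * u_att + u_rep
  i <- which(tot == min(tot), arr.ind = TRUE)[1, ]
  s_star <- ss[i[1]]; h_star <- hs[i[2]]

  # transverse free-energy integral: the lattice sum over polymer beads
  # separates into 1D profiles along x, so each (x, y, h) evaluation is a
  # sum over the sticky beads only
  g1d <- function(width) {
    xg <- seq(min(poly_x) - 2, max(poly_x) + 2, by = 0.01)
    vals <- rowSums(exp(-outer(xg, poly_x, "-")^2 / (2 * width^2)))
    approxfun(xg, vals)
  }
  ga <- g1d(w); gr <- g1d(s2)
  xg <- seq(s_star - 0.4, s_star + 0.4, by = 0.02)
  yg <- seq(-0.4, 0.4, by = 0.02)
  hg <- c(seq(max(0.05, h_star - 0.3), h_star + 0.5, by = 0.02), 2.5)
  nb <- nrow(sticky_local)
  # per h: matrices of the attraction/repulsion sums over (x, y)
  ua <- array(0, c(length(xg), length(yg), length(hg)))
  ur <- array(0, c(length(xg), length(yg), length(hg)))
  for (hi in seq_along(hg)) {
    for (b in seq_len(nb)) {
      ax <- ga(sticky_local[b, 1] + xg)          # length x
      rx <- gr(sticky_local[b, 1] + xg)
      ay <- exp(-((sticky_local[b, 2] + yg)^2 + hg[hi]^2) / (2 * w^2))
      ry <- exp(-((sticky_local[b, 2] + yg)^2 + hg[hi]^2) / (2 * s2^2))
      ua[, , hi] <- ua[, , hi] - outer(ax, ay)
      ur[, , hi] <- ur[, , hi] + A * outer(rx, ry)
    }
  }
  teth <- 0.5 * UMBRELLA_LATERAL_K *
    (outer((xg - s_star)^2, yg^2, "+"))
  free_depth <- function(cc) {
    gh <- vapply(seq_along(hg), function(hi)
      -kbt * log(mean(exp(-(cc * ua[, , hi] + ur[, , hi] + teth) / kbt))),
      numeric(1))
    gh[length(gh)] - min(gh)   # bulk (last h) minus well
  }
  cc <- uniroot(function(cc) free_depth(cc) - eps,
                c(0.2 * cc0, 5 * cc0), tol = 1e-8, extendInt = "upX")$root
  out <- list(att_c = cc, h = h_star, s = s_star, depth = eps)
  .calibration_cache[[key]] <- out
  out
}

#' Run the toy Brownian dynamics
#'
#' Overdamped Langevin dynamics of the toy system under the config's
#' scenario preset. Identical `(config, seed)` pairs give identical
#' trajectories.
#'
#' @param config a `habind_toy_config`.
#' @param n_steps number of integration steps (>= 1).
#' @param seed RNG seed.
#' @return a `habind_traj` with an extra `ground_truth` element: planted
#'   mode, per-frame bound flag, applied field, umbrella parameters, seed
#'   and the umbrella coordinate xi per frame.
#' @export
simulate_toy <- function(config, n_steps, seed = 1L) {
  stopifnot(inherits(config, "habind_toy_config"), n_steps >= 1)
  set.seed(seed)
  model <- build_system(config)
  toy <- attr(model, "toy")
  np <- toy$core_row
  n_all <- nrow(model$atoms)
  scen <- config$scenario
  mobile <- integer(n_all)
  if (scen %in% c("binding", "sliding", "umbrella")) {
    mobile[seq_len(np)] <- 2L
  } else if (scen == "efield") {
    # short oligomer pulled off as a rigid body: detachment is a collective
    # barrier crossing, preserving the planted depth ordering
    mobile[toy$poly_rows] <- 3L
  } else { # free
    mobile[seq_len(np)] <- 2L
    mobile[toy$poly_rows] <- 1L
  }
  teth_idx <- integer(0); teth_k <- teth_ref <- matrix(0, 0, 3)
  kbt <- kB * config$temperature
  if (scen == "efield") {
    # the receptor is immobilised and the field acts perpendicular to the
    # strand; restrain the oligomer's lateral registry so detachment means
    # crossing the full planted well, not sliding out of the groove
    b1 <- toy$poly_rows[1]
    teth_idx <- b1
    teth_k <- matrix(c(500, 0, 0), 1, 3)
    teth_ref <- matrix(model$xyz[b1, ], 1, 3)
  }
  if (scen == "umbrella") {
    teth_idx <- toy$core_row
    teth_k <- matrix(c(UMBRELLA_LATERAL_K, UMBRELLA_LATERAL_K, 0), 1, 3)
    teth_ref <- matrix(c(toy$anchor[1], 0, 0), 1, 3)
  }
  if (scen == "sliding") {
    # the receptor is restrained transverse to the strand but free along it,
    # as in the long-polymer co-diffusion setup this scenario emulates
    teth_idx <- toy$core_row
    teth_k <- matrix(c(0, 30, 30), 1, 3)
    teth_ref <- matrix(c(0, 0, toy$h_star + 0.9), 1, 3)
  }
  if (scen == "free") {
    ends <- toy$poly_rows[c(1, length(toy$poly_rows))]
    teth_idx <- c(teth_idx, ends)
    teth_k <- rbind(teth_k, matrix(200, 2, 3))
    teth_ref <- rbind(teth_ref, model$xyz[ends, , drop = FALSE])
  }
  umb <- config$umbrella
  res <- langevin_run(
    pos0 = model$xyz, mobile = mobile,
    poly_idx = toy$poly_rows - 1L,
    bond_k = config$bond_k, bond_r0 = config$bond_length,
    sticky_idx = toy$sticky_rows - 1L, contact_idx = toy$contact_rows - 1L,
    att_c = toy$att_c, att_w = mode_width(config),
    rep_A = config$rep_strength, rep_w = config$rep_width,
    charges = toy$charges, efield = as.numeric(config$field),
    teth_idx = teth_idx - 1L, teth_k = teth_k, teth_ref = teth_ref,
    umb_on = !is.null(umb), umb_k = if (is.null(umb)) 0 else umb$k,
    umb_center = if (is.null(umb)) 0 else umb$center,
    umb_anchor = toy$anchor, core_idx = toy$core_row - 1L,
    kbt = kbt, D_protein = config$diffusion, D_polymer = config$diffusion,
    dt = config$dt, n_steps = as.integer(n_steps),
    stride = config$stride, max_step = min(config$box) / 2)
  traj <- trajectory(model, res$coords, times = res$times,
                     stride = config$stride)
  bound <- toy_bound_flags(traj, toy)
  traj$ground_truth <- list(planted_mode = config$planted_mode,
                            scenario = scen, seed = seed,
                            field = config$field, umbrella = umb,
                            bound = bound, xi = res$xi)
  class(traj) <- c("habind_toy_traj", class(traj))
  traj
}

toy_bound_flags <- function(traj, toy, cutoff = 0.6) {
  nf <- n_frames(traj)
  out <- logical(nf)
  for (f in seq_len(nf)) {
    fc <- frame_coords(traj, f)
    out[f] <- min(dist2_matrix(fc[toy$sticky_rows, , drop = FALSE],
                               fc[toy$poly_rows, , drop = FALSE])) <= cutoff^2
  }
  out
}

#' Umbrella scan over the toy binding well
#'
#' One restrained run per window centre along the core-to-anchor distance,
#' with the receptor laterally tethered above the bound registry (pulling
#' geometry). Warns when the predicted window spread cannot bridge the
#' centre spacing.
#'
#' @param config a planted `habind_toy_config`.
#' @param centers ordered window centres (nm).
#' @param k umbrella spring constant (kJ mol^-1 nm^-2).
#' @param steps_per_window integration steps per window.
#' @param seed top-level seed; per-window seeds are derived from it.
#' @param equil_frac fraction of each window discarded as equilibration.
#' @return list of `habind_window`.
#' @export
umbrella_scan <- function(config, centers, k, steps_per_window = 100000,
                          seed = 1L, equil_frac = 0.1) {
  stopifnot(inherits(config, "habind_toy_config"))
  # restrained sampling wants minimal integrator bias near the stiff bound
  # minimum: refine the step (and keep ~0.4 ps between samples)
  if (config$dt > 0.001) {
    steps_per_window <- round(steps_per_window * config$dt / 0.001)
    config$dt <- 0.001
  }
  config$stride <- 400L
  if (is.unsorted(centers)) stop("window centres must be ordered")
  kbt <- kB * config$temperature
  sdw <- sqrt(kbt / k)
  if (length(centers) > 1 && max(diff(centers)) > 4 * sdw)
    warning(sprintf(
      "window spacing %.3g nm exceeds 4 x predicted spread %.3g nm; histograms may not overlap",
      max(diff(centers)), sdw))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(centers))
  cfg <- config
  cfg$scenario <- "umbrella"
  out <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    cfg$umbrella <- list(center = centers[i], k = k)
    tr <- simulate_toy(cfg, steps_per_window, seed = seeds[i])
    xi <- tr$ground_truth$xi
    drop <- seq_len(max(1L, floor(equil_frac * length(xi))))
    out[[i]] <- umbrella_window(centers[i], k, xi[-drop],
                                temperature = config$temperature)
  }
  out
}
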