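# Independent oracles and small fixture builders shared by the tests.
# Every oracle here is written as a direct, naive enumeration so it stays
# independent of the package's optimised code paths.

# --- brute-force contact kernels ------------------------------------------

# minimum pairwise distance by full double loop; with a box, all 27 periodic
# images are enumerated explicitly
bf_min_distance <- function(a, b, box = NULL) {
  best <- Inf
  shifts <- if (is.null(box)) matrix(0, 1, 3) else
    as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1)) %*% diag(box)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    for (s in seq_len(nrow(shifts))) {
      d <- sqrt(sum((a[i, ] - b[j, ] - shifts[s, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# number of atom pairs within cutoff (inclusive), naive loop + 27 images
bf_pair_count <- function(a, b, cutoff, box = NULL) {
  cnt <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (is.null(box)) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
    } else {
      d <- Inf
      for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
        dd <- sqrt(sum((a[i, ] - b[j, ] - c(sx, sy, sz) * box)^2))
        if (dd < d) d <- dd
      }
    }
    if (d <= cutoff) cnt <- cnt + 1L
  }
  cnt
}

# exhaustive hydrogen-bond check
bf_hbonds <- function(xyz, donors, acceptors, hydrogens, d_max, angle_min) {
  hits <- list()
  for (di in seq_along(donors)) for (ai in seq_along(acceptors)) {
    d <- donors[di]; a <- acceptors[ai]
    if (d == a) next
    dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
    if (dist > d_max) next
    h <- hydrogens[di]
    if (!is.na(h)) {
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < angle_min) next
    }
    hits[[length(hits) + 1]] <- c(d, a)
  }
  hits
}

# --- independent dihedral (acos formulation with explicit sign) ------------

oracle_dihedral <- function(p1, p2, p3, p4) {
  crossp <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- crossp(b1, b2); n2 <- crossp(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosang))) * 180 / pi
  if (sum(crossp(n1, n2) * b2) < 0) ang <- -ang
  ang
}

# --- binless WHAM (MBAR-style self-consistent sample weights) ---------------
# Independent of the package's binned solver: iterates window free energies
# on the pooled samples directly, then bins the unbiased weights onto the
# requested grid.

oracle_wham <- function(windows, grid, kbt, tol = 1e-8, max_iter = 5e4) {
  x <- unlist(lapply(windows, `[[`, "xi"))
  N <- vapply(windows, function(w) length(w$xi), numeric(1))
  K <- length(windows)
  # bias energy of every sample in every window: K x n
  U <- vapply(seq_along(x), function(n)
    vapply(windows, function(w) 0.5 * w$k * (x[n] - w$center)^2, numeric(1)),
    numeric(K))
  U <- matrix(U, nrow = K)
  f <- numeric(K)
  for (it in seq_len(max_iter)) {
    # w_n = 1 / sum_k N_k exp((f_k - u_kn)/kbt)
    lw <- -log(colSums(N * exp((f - U) / kbt)))
    fnew <- -kbt * log(vapply(seq_len(K), function(k)
      sum(exp(lw - U[k, ] / kbt)), numeric(1)))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  wts <- exp(-log(colSums(N * exp((f - U) / kbt))))
  half <- diff(grid)[1] / 2
  G <- vapply(grid, function(g) {
    p <- sum(wts[x >= g - half & x < g + half])
    if (p <= 0) NA_real_ else -kbt * log(p)
  }, numeric(1))
  G - mean(G, na.rm = TRUE)
}

# --- tiny fixtures ----------------------------------------------------------

# hand-written three-atom PDB (coordinates in Angstrom)
write_tiny_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1      10.000  20.000  30.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.500  20.000  30.000  1.00  0.00           C",
    "ATOM      3  O   HOH B   2       0.000   5.000   2.500  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

# a minimal backbone frame around the key arginine whose phi dihedral for
# residue key+1 equals the requested angle (constructed via the independent
# oracle), with an optional ligand acceptor in hydrogen-bond range of the
# key side chain
make_ab_fixture <- function(phi_deg, with_ligand_hb = TRUE, key = 41L) {
  p1 <- c(0.15, 0, 0)        # C(key)
  p2 <- c(0, 0, 0)           # N(key+1)
  p3 <- c(0, 0.15, 0)        # CA(key+1)
  cand <- function(a) c(0.12 * cos(a), 0.2, 0.12 * sin(a))
  phi_of <- function(a) oracle_dihedral(p1, p2, p3, cand(a))
  grid <- seq(-pi, pi, length.out = 721)
  a <- grid[which.min(abs(((vapply(grid, phi_of, numeric(1)) - phi_deg + 180) %% 360) - 180))]
  p4 <- cand(a)
  nh1 <- c(0.5, 0, 0)        # key-residue side-chain donor
  lig <- nh1 + c(if (with_ligand_hb) 0.29 else 1.0, 0, 0)
  atoms <- data.frame(
    name    = c("C", "NH1", "N", "CA", "C", "O1"),
    element = c("C", "N", "N", "C", "C", "O"),
    resno   = c(key, key, key + 1L, key + 1L, key + 1L, 1L),
    resname = c("ARG", "ARG", "TYR", "TYR", "TYR", "NAG"),
    chain   = c("P", "P", "P", "P", "P", "H"),
    stringsAsFactors = FALSE)
  xyz <- rbind(p1, nh1, p2, p3, p4, lig)
  m <- structure_model(atoms, xyz, roles = c(P = "protein", H = "polymer"))
  coords <- array(0, dim = c(1, nrow(xyz), 3))
  coords[1, , ] <- xyz
  trajectory(m, coords, times = 0)
}

# planted toy trajectory cache so expensive simulations are shared between
# tests in one file
toy_cache <- new.env(parent = emptyenv())
cached_toy <- function(mode, n_steps = 20000, seed = 1) {
  key <- paste(mode, n_steps, seed, sep = "_")
  if (is.null(toy_cache[[key]]))
    toy_cache[[key]] <- simulate_toy(plant_mode(toy_config(), mode),
                                     n_steps, seed = seed)
  toy_cache[[key]]
}
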