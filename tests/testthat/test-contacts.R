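test_that("min_distance handles direct and minimum-image geometry", {
  expect_equal(min_distance(matrix(c(0, 0, 0), 1), matrix(c(0, 0, 0.5), 1)), 0.5)
  # minimum image across the boundary of a 4 nm box
  expect_equal(min_distance(matrix(c(0, 0, 0.1), 1), matrix(c(0, 0, 3.9), 1),
                            box = c(4, 4, 4)), 0.2)
  expect_error(min_distance(matrix(numeric(0), 0, 3), matrix(0, 1, 3)),
               "empty selection")
})

test_that("min_distance equals the 27-image brute-force oracle", {
  set.seed(11)
  box <- c(3, 3, 3)
  for (rep in 1:5) {
    a <- matrix(runif(150, 0, 3), ncol = 3)
    b <- matrix(runif(150, 0, 3), ncol = 3)
    expect_equal(min_distance(a, b), bf_min_distance(a, b), tolerance = 1e-12)
    expect_equal(min_distance(a, b, box), bf_min_distance(a, b, box),
                 tolerance = 1e-12)
  }
})

test_that("binding percentages follow the frame-fraction definition with inclusive boundary", {
  s <- structure(matrix(c(TRUE, TRUE, TRUE, FALSE), 4, 1,
                        dimnames = list(NULL, "41")),
                 class = c("habind_contact_series", "matrix"))
  expect_equal(residue_binding_percent(s, 41), 75)
  s0 <- structure(matrix(FALSE, 4, 1, dimnames = list(NULL, "41")),
                  class = c("habind_contact_series", "matrix"))
  expect_equal(residue_binding_percent(s0, 41), 0)
  s1 <- structure(matrix(TRUE, 4, 1, dimnames = list(NULL, "41")),
                  class = c("habind_contact_series", "matrix"))
  expect_equal(residue_binding_percent(s1, 41), 100)
  expect_error(residue_binding_percent(s1, 99), "unknown residue")

  # residue exactly at the cutoff counts (boundary is inclusive)
  atoms <- data.frame(name = c("CA", "C1"), element = "C", resno = c(41, 1),
                      resname = c("ARG", "NAG"), chain = c("P", "H"))
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0.6))
  m <- structure_model(atoms, xyz, roles = c(P = "protein", H = "polymer"))
  coords <- array(0, c(2, 2, 3)); coords[1, , ] <- xyz; coords[2, , ] <- xyz
  tr <- trajectory(m, coords, times = 0:1)
  s2 <- residue_contact_series(tr, 41, selection_spec("l", role = "polymer"))
  expect_equal(residue_binding_percent(s2, 41), 100)
})

test_that("replica tables aggregate with standard errors and sentinels", {
  mk <- function(frac, n = 1000) {
    v <- rep(FALSE, n); v[seq_len(round(frac * n / 100))] <- TRUE
    structure(matrix(v, n, 1, dimnames = list(NULL, "25")),
              class = c("habind_contact_series", "matrix"))
  }
  tab <- replica_binding_table(list(mk(100), mk(100), mk(100)))
  expect_equal(tab$mean, 100)
  expect_equal(tab$se, 0)
  # the reference-table arithmetic: {51.9, 52.7} -> 52.3 +- 0.4
  tab2 <- replica_binding_table(list(mk(51.9), mk(52.7)))
  expect_equal(tab2$mean, 52.3)
  expect_equal(round(tab2$se, 1), 0.4)
  # single replica: SE is the undefined sentinel
  tab3 <- replica_binding_table(list(mk(40)))
  expect_true(is.na(tab3$se))
  expect_equal(tab3$mean, 40)
  # residue-set mismatch
  bad <- mk(10); colnames(bad) <- "26"
  expect_error(replica_binding_table(list(mk(10), bad)), "differ")
})

make_random_traj <- function(n_frames, na, nb, box = NULL, seed = 1) {
  set.seed(seed)
  atoms <- data.frame(
    name = "C1", element = "C",
    resno = c(rep(41, na), rep(1, nb)),
    resname = c(rep("ARG", na), rep("NAG", nb)),
    chain = c(rep("P", na), rep("H", nb)))
  coords <- array(runif(n_frames * (na + nb) * 3, 0, 2.5),
                  c(n_frames, na + nb, 3))
  m <- structure_model(atoms, coords[1, , ], box = box,
                       roles = c(P = "protein", H = "polymer"))
  trajectory(m, coords, times = seq_len(n_frames) - 1)
}

test_that("pair-count statistics equal brute-force enumeration per frame", {
  tr <- make_random_traj(20, 8, 10, seed = 4)
  params <- contact_params(cutoff = 0.6)
  counts <- contact_count_series(tr, selection_spec("p", role = "protein"),
                                 selection_spec("l", role = "polymer"), params)
  for (f in seq_len(20)) {
    fc <- frame_coords(tr, f)
    expect_equal(as.numeric(counts)[f], bf_pair_count(fc[1:8, ], fc[9:18, ], 0.6))
  }
  # per-residue mean profile equals averaged brute force
  prof <- contact_count_profile(tr, 41, selection_spec("l", role = "polymer"),
                                params)
  bf <- mean(vapply(seq_len(20), function(f) {
    fc <- frame_coords(tr, f)
    bf_pair_count(fc[1:8, ], fc[9:18, ], 0.6)
  }, numeric(1)))
  expect_equal(unname(prof["41"]), bf)
})

test_that("pair counts respect periodic boundaries like the image-enumerating oracle", {
  tr <- make_random_traj(10, 6, 6, box = c(2.5, 2.5, 2.5), seed = 9)
  params <- contact_params(cutoff = 0.6, pbc = TRUE)
  counts <- contact_count_series(tr, selection_spec("p", role = "protein"),
                                 selection_spec("l", role = "polymer"), params)
  for (f in seq_len(10)) {
    fc <- frame_coords(tr, f)
    expect_equal(as.numeric(counts)[f],
                 bf_pair_count(fc[1:6, ], fc[7:12, ], 0.6, box = c(2.5, 2.5, 2.5)))
  }
})

test_that("enlarging the cutoff never decreases any contact statistic", {
  tr <- make_random_traj(15, 8, 10, seed = 6)
  cuts <- c(0.3, 0.5, 0.7, 0.9)
  prev_counts <- NULL; prev_pct <- NULL
  for (ct in cuts) {
    p <- contact_params(cutoff = ct)
    counts <- as.numeric(contact_count_series(
      tr, selection_spec("p", role = "protein"),
      selection_spec("l", role = "polymer"), p))
    s <- residue_contact_series(tr, 41, selection_spec("l", role = "polymer"), p)
    pct <- residue_binding_percent(s, 41)
    if (!is.null(prev_counts)) {
      expect_true(all(counts >= prev_counts))
      expect_gte(pct, prev_pct)
    }
    prev_counts <- counts; prev_pct <- pct
  }
})

test_that("time-independent summaries are invariant to frame reordering", {
  tr <- make_random_traj(12, 5, 7, seed = 8)
  perm <- sample(12)
  tr2 <- trajectory(tr$model, tr$coords[perm, , , drop = FALSE],
                    times = seq_len(12) - 1)
  sel <- selection_spec("l", role = "polymer")
  s1 <- residue_contact_series(tr, 41, sel)
  s2 <- residue_contact_series(tr2, 41, sel)
  expect_equal(residue_binding_percent(s1, 41), residue_binding_percent(s2, 41))
  p1 <- contact_count_profile(tr, 41, sel)
  p2 <- contact_count_profile(tr2, 41, sel)
  expect_equal(p1, p2)
})

test_that("contact contours localise to touched polymer residues and sum consistently", {
  tr <- cached_toy("crystallographic", n_steps = 2000)
  map <- assign_ha_numbering(tr$model, coords = frame_coords(tr, 1))
  contour <- contact_contour(tr, map)
  counts <- contact_count_series(tr, selection_spec("p", role = "protein"),
                                 selection_spec("l", role = "polymer"))
  # per-frame column sums equal the total pair count series
  expect_equal(unname(colSums(contour)), as.numeric(counts))
  # contacts concentrate around the bound registry, ends stay clear
  touched <- which(rowSums(contour) > 0)
  expect_lt(diff(range(touched)), nrow(contour) - 4)
})

test_that("a laterally shifted pose shifts the contour band by the same offset", {
  tr <- cached_toy("crystallographic", n_steps = 500)
  m <- tr$model
  map <- assign_ha_numbering(m, coords = frame_coords(tr, 1))
  prot <- which(m$atoms$chain == "P")
  fc1 <- frame_coords(tr, 1)
  fc2 <- fc1; fc2[prot, 1] <- fc2[prot, 1] + 4 * 0.5  # +4 beads along the chain
  coords <- array(0, c(2, nrow(fc1), 3))
  coords[1, , ] <- fc1; coords[2, , ] <- fc2
  tr2 <- trajectory(m, coords, times = 0:1)
  contour <- contact_contour(tr2, map)
  expect_equal(contour[5:nrow(contour), 2], contour[1:(nrow(contour) - 4), 1])
})

test_that("hydrogen-bond detection applies distance and angle criteria", {
  # N-H...O collinear at 0.29 nm donor-acceptor
  xyz <- rbind(c(0, 0, 0),      # donor N
               c(0, 0, 0.10),   # H
               c(0, 0, 0.29))   # acceptor O
  hb <- hydrogen_bonds(xyz, donors = 1L, acceptors = 3L, hydrogens = 2L)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 0.29)
  expect_equal(hb$angle, 180)
  # same geometry stretched to 0.40 nm: rejected
  xyz2 <- xyz; xyz2[3, 3] <- 0.40
  expect_equal(nrow(hydrogen_bonds(xyz2, 1L, 3L, 2L)), 0)
  # bent below the angle criterion: rejected
  xyz3 <- rbind(c(0, 0, 0), c(0, 0, 0.10), c(0, 0.28, 0.12))
  expect_equal(nrow(hydrogen_bonds(xyz3, 1L, 3L, 2L)), 0)
})

test_that("hydrogen-bond detection equals exhaustive enumeration on random geometry", {
  set.seed(13)
  for (rep in 1:3) {
    xyz <- matrix(runif(90, 0, 1.2), ncol = 3)
    donors <- 1:10; acceptors <- 16:30
    hydrogens <- c(11:15, rep(NA_integer_, 5))
    hb <- hydrogen_bonds(xyz, donors, acceptors, hydrogens)
    bf <- bf_hbonds(xyz, donors, acceptors, hydrogens, 0.35, 150)
    got <- if (nrow(hb)) paste(hb$donor, hb$acceptor) else character(0)
    want <- vapply(bf, function(p) paste(p[1], p[2]), character(1))
    expect_setequal(got, want)
  }
})

test_that("binding tables and contours export as TSV", {
  tr <- cached_toy("crystallographic", n_steps = 1000)
  s <- residue_contact_series(tr, reference_residues(),
                              selection_spec("l", role = "polymer"))
  tab <- replica_binding_table(list(s))
  f <- tempfile(fileext = ".tsv")
  write_binding_table(list(crystallographic = tab), f)
  re <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(re), 39)
  expect_true("crystallographic_percent" %in% names(re))
  map <- assign_ha_numbering(tr$model)
  contour <- contact_contour(tr, map)
  f2 <- tempfile(fileext = ".tsv")
  write_contour(contour, f2)
  re2 <- read.table(f2, header = TRUE, sep = "\t")
  expect_equal(nrow(re2), nrow(contour) * ncol(contour))
})
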