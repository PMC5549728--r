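test_that("detachment is the first zero-contact frame, censored otherwise", {
  r <- detect_detachment(c(5, 3, 0, 2), dt = 1, t_end = 4)
  expect_true(r$detached)
  expect_equal(r$time, 2)          # re-binding afterwards is ignored
  r2 <- detect_detachment(c(5, 3, 2, 2), dt = 1, t_end = 4)
  expect_false(r2$detached)
  expect_true(is.na(r2$time))
  expect_equal(r2$censored_at, 4)
  r3 <- detect_detachment(c(0, 5, 5), dt = 1, t_end = 3)
  expect_true(r3$detached)
  expect_equal(r3$time, 0)
  expect_error(detect_detachment(c(1, -2), dt = 1, t_end = 2), "negative")
  expect_error(detect_detachment(c(1, 0), dt = 1), "required")
})

test_that("detachment detection is idempotent under appending frames after the first zero", {
  base <- c(4, 2, 0)
  r1 <- detect_detachment(base, dt = 0.5, t_end = 1.5)
  r2 <- detect_detachment(c(base, 3, 0, 7), dt = 0.5, t_end = 3)
  expect_equal(r1$time, r2$time)
  expect_equal(r1$detached, r2$detached)
})

test_that("optional persistence requires consecutive zero frames", {
  x <- c(3, 0, 2, 0, 0, 0, 1)
  expect_equal(detect_detachment(x, dt = 1, t_end = 7)$time, 1)
  expect_equal(detect_detachment(x, dt = 1, t_end = 7, persistence = 3)$time, 3)
  expect_false(detect_detachment(x, dt = 1, t_end = 7, persistence = 4)$detached)
})

mk_records <- function(times, n_total, field = "strong") {
  recs <- lapply(seq_len(n_total), function(i) {
    if (i <= length(times))
      detect_detachment(c(rep(3, times[i]), 0), dt = 1, t_end = n_total,
                        field_tag = field, replica = i)
    else
      detect_detachment(rep(3, 50), dt = 1, t_end = n_total,
                        field_tag = field, replica = i)
  })
  do.call(rbind, recs)
}

test_that("detachment summaries reproduce the reported table arithmetic", {
  # 1 of 20: 5% with the SE sentinel on the time
  s1 <- summarize_detachments(mk_records(times = 8, n_total = 20))
  expect_equal(s1$fraction, 5)
  expect_equal(s1$mean_time, 8)
  expect_true(is.na(s1$se_time))
  # 19 of 20: 95%
  s2 <- summarize_detachments(mk_records(times = rep(c(4, 6), c(10, 9)),
                                         n_total = 20))
  expect_equal(s2$fraction, 95)
  expect_false(is.na(s2$se_time))
  # 0 of 20: 0%, undefined mean time
  s3 <- summarize_detachments(mk_records(times = integer(0), n_total = 20))
  expect_equal(s3$fraction, 0)
  expect_true(is.na(s3$mean_time))
  # replica-order invariance
  rec <- mk_records(times = c(3, 9, 12), n_total = 10)
  s4 <- summarize_detachments(rec)
  s5 <- summarize_detachments(rec[sample(nrow(rec)), ])
  expect_equal(s4$fraction, s5$fraction)
  expect_equal(s4$mean_time, s5$mean_time)
  # mixed field tags are rejected
  mixed <- rbind(mk_records(3, 2, "strong"), mk_records(3, 2, "weak"))
  expect_error(summarize_detachments(mixed), "field tags")
})

mk_contour <- function(mat) {
  structure(mat, mono_pos = seq_len(nrow(mat)),
            disaccharide = seq_len(nrow(mat)) - 1L,
            times = seq_len(ncol(mat)) - 1,
            class = c("habind_contour", "matrix"))
}

test_that("contact centroids are count-weighted polymer positions", {
  m <- matrix(0L, 16, 3)
  m[10, 1] <- 2; m[12, 1] <- 2    # equal weights at 10 and 12 -> 11
  m[7, 2] <- 5                    # all at 7 -> 7
  m[10, 3] <- 3; m[11, 3] <- 1    # weighted -> 10.25
  ct <- mk_contour(m)
  expect_equal(contact_centroid(ct, 1), 11)
  expect_equal(contact_centroid(ct, 2), 7)
  expect_equal(contact_centroid(ct, 3), 10.25)
  # no contacts: undefined sentinel, not an error
  m0 <- mk_contour(matrix(0L, 4, 1))
  expect_true(is.na(contact_centroid(m0, 1)))
})

test_that("sliding tracks report net displacement and bridge short gaps", {
  # centroid drifts 30 -> 50 over the track
  nf <- 21
  m <- matrix(0L, 60, nf)
  pos <- round(seq(30, 50, length.out = nf))
  for (f in seq_len(nf)) m[pos[f], f] <- 4L
  tk <- sliding_track(mk_contour(m), dt = 1)
  expect_equal(tk$net_displacement, 20)
  expect_equal(tk$max_excursion, 20)
  # a short zero-contact gap is interpolated, a long one is not
  m2 <- m; m2[, 5:8] <- 0L
  tk2 <- sliding_track(mk_contour(m2), dt = 1, max_gap = 10)
  expect_false(anyNA(tk2$centroid[5:8]))
  tk3 <- sliding_track(mk_contour(m2), dt = 1, max_gap = 2)
  expect_true(all(is.na(tk3$centroid[5:8])))
  expect_equal(tk3$net_displacement, 20)
})

test_that("partial detachments need the retained band to persist through the dip", {
  nf <- 100
  residues <- c(41, 78, 108:114)
  series <- matrix(TRUE, nf, length(residues),
                   dimnames = list(NULL, as.character(residues)))
  counts <- rep(40, nf)
  # groove contacts vanish for frames 30..79 while residue 110 persists
  series[30:79, colnames(series) %in% c("41", "78")] <- FALSE
  series[30:79, colnames(series) %in% as.character(c(108, 109, 111:114))] <- FALSE
  counts[30:79] <- 3
  ev <- detect_partial_detachment(series, counts)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$length, 50)
  expect_match(ev$retained, "110")
  # full detachment (every residue lost) is not a partial event
  series2 <- series; series2[30:79, ] <- FALSE; counts2 <- counts
  counts2[30:79] <- 0
  expect_equal(nrow(detect_partial_detachment(series2, counts2)), 0)
  # no dip below the watermark: no events
  expect_equal(nrow(detect_partial_detachment(
    matrix(TRUE, 10, 9, dimnames = list(NULL, as.character(residues))),
    rep(40, 10))), 0)
  expect_error(detect_partial_detachment(series, counts, retained_set = c()),
               "empty")
})

test_that("one-dimensional MSD matches closed forms", {
  # linear drift: MSD(tau) = (v tau)^2
  v <- 0.7
  tk <- list(time = 0:49, centroid = v * (0:49), total_contacts = rep(1, 50))
  class(tk) <- "habind_sliding_track"
  msd <- msd_1d(tk, 10)
  expect_equal(msd$msd, (v * (1:10))^2, tolerance = 1e-12)
  # constant centroid: identically zero
  tk0 <- tk; tk0$centroid <- rep(3, 50)
  expect_true(all(msd_1d(tk0, 10)$msd == 0))
  expect_error(msd_1d(tk, 50), "smaller")
})

test_that("random-walk MSD grows linearly with the step variance", {
  set.seed(55)
  s <- 0.8
  reps <- replicate(40, {
    x <- cumsum(rnorm(400, 0, s))
    tk <- list(time = seq_along(x) - 1, centroid = x,
               total_contacts = rep(1, length(x)))
    class(tk) <- "habind_sliding_track"
    msd_1d(tk, 5)$msd
  })
  mmsd <- rowMeans(reps)
  expect_equal(mmsd, s^2 * (1:5), tolerance = 0.1)
})

test_that("detachment times lengthen with planted well depth at fixed field", {
  # Spearman correlation between depth and mean detachment time
  depth_grid <- c(10, 16, 22)
  times <- numeric(0); depths <- numeric(0)
  for (d in depth_grid) {
    cfg <- toy_config(depths = c(crystallographic = d, upright = d,
                                 parallel = d))
    cfg <- plant_mode(cfg, "crystallographic")
    cfg$scenario <- "efield"; cfg$field <- c(0, 0, 1.5)
    set.seed(202 + d); seeds <- sample.int(1e6, 7)
    for (r in seq_len(7)) {
      tr <- simulate_toy(cfg, 100000, seed = seeds[r])
      counts <- contact_count_series(
        tr, selection_spec("p", role = "protein"),
        selection_spec("l", role = "polymer"))
      rec <- detect_detachment(counts, dt = 0.001, t_end = 0.2)
      if (rec$detached) { times <- c(times, rec$time); depths <- c(depths, d) }
    }
  }
  ct <- cor.test(depths, times, method = "spearman", alternative = "greater",
                 exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})
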