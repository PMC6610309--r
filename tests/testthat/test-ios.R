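specs <- default_group_specs()

test_that("dT/T definition: arithmetic, zero case, invalid pixels", {
  fr <- array(100L, dim = c(4, 4, 12))
  d <- make_dtt_stack(fr)
  expect_true(all(d$dtt == 0))

  fr2 <- fr
  fr2[1, 1, 6:12] <- 102L   # C = 100, value 102 -> 2%
  d2 <- make_dtt_stack(fr2)
  expect_equal(d2$dtt[1, 1, 6], 2)
  expect_equal(d2$dtt[2, 2, 6], 0)

  fr3 <- fr; fr3[2, 2, 1:5] <- 0L  # zero control intensity -> invalid
  d3 <- make_dtt_stack(fr3)
  expect_true(d3$invalid[2, 2])
  expect_true(all(is.na(d3$dtt[2, 2, ])))
  # saturated frames are excluded
  fr4 <- fr; fr4[3, 3, 7] <- 255L
  expect_true(is.na(make_dtt_stack(fr4)$dtt[3, 3, 7]))

  expect_error(ios_series(fr, seq_len(12) - 20, n_control_frames = 15),
               "control")
})

test_that("dT/T is invariant under global illumination scaling", {
  fr <- array(80L, dim = c(3, 3, 10))
  fr[1, , 6:10] <- 88L
  scaled <- fr * 2L
  expect_equal(make_dtt_stack(fr)$dtt, make_dtt_stack(scaled)$dtt)
})

test_that("involvement threshold-persistence boundaries", {
  base <- array(100L, dim = c(3, 3, 30))
  nc <- 5L
  # exactly 9 consecutive frames at 1%: NOT involved (>9 required)
  f9 <- base; f9[1, 1, 6:14] <- 101L
  # 10 consecutive frames: involved
  f10 <- base; f10[2, 2, 6:15] <- 101L
  d9 <- make_dtt_stack(f9, nc); d10 <- make_dtt_stack(f10, nc)
  expect_false(involvement_map(d9)[1, 1])
  expect_true(involvement_map(d10)[2, 2])
  # interrupted run never accumulates
  f_gap <- base; f_gap[1, 2, c(6:10, 12:16)] <- 102L
  expect_false(involvement_map(make_dtt_stack(f_gap, nc))[1, 2])
  # 0.99% forever: below threshold (fractional frames are fine upstream)
  f_low <- array(100, dim = c(3, 3, 30)); f_low[3, 3, 6:30] <- 100.99
  dl <- make_dtt_stack(f_low, nc)
  expect_false(involvement_map(dl, threshold_pct = 1)[3, 3])
  expect_warning(res <- involvement_map(d9, persistence_frames = 31),
                 "persistence")
  expect_false(any(res))
})

test_that("involvement_map matches the brute-force pixel/run oracle", {
  set.seed(7)
  for (rep in 1:3) {
    h <- 24; w <- 24; n <- 50; nc <- 10L
    fr <- array(100L, dim = c(h, w, n))
    sig <- array(sample(c(0L, 1L, 2L), h * w * n, replace = TRUE,
                        prob = c(0.55, 0.25, 0.2)), dim = dim(fr))
    sig[, , 1:nc] <- 0L
    fr <- fr + sig
    d <- make_dtt_stack(fr, nc)
    got <- involvement_map(d, 1, 10)
    # oracle: explicit loop over pixels and consecutive runs
    want <- matrix(FALSE, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      run <- 0L
      for (f in seq_len(n)) {
        run <- if (!is.na(d$dtt[i, j, f]) && d$dtt[i, j, f] >= 1) run + 1L else 0L
        if (run >= 10L) { want[i, j] <- TRUE; break }
      }
    }
    expect_identical(got, want)
  }
})

test_that("sle_area is an exact pixel count", {
  h <- 40; w <- 40
  m1 <- matrix(FALSE, h, w); m1[1:20, ] <- TRUE
  m2 <- matrix(FALSE, h, w); m2[21:40, ] <- TRUE
  masks <- as_mask_set(list(EC = m1, TC = m2))
  inv <- matrix(FALSE, h, w)
  expect_equal(sle_area(inv, masks), c(EC = 0, TC = 0))
  expect_equal(sle_area(m1 | m2, masks), c(EC = 100, TC = 100))
  set.seed(1)
  pick <- sample(which(m1), round(0.3 * sum(m1)))
  inv[pick] <- TRUE
  a <- sle_area(inv, masks)
  expect_equal(unname(a["EC"]), 100 * length(pick) / sum(m1))
  expect_close(unname(a["EC"]), 30, abs = 100 / sum(m1) + 1e-9)
})

test_that("roi_intensity summarises the ROI time course peak", {
  h <- 60; w <- 60
  m <- matrix(FALSE, h, w); m[10:50, 10:50] <- TRUE
  masks <- as_mask_set(list(EC = m))
  fr <- array(100L, dim = c(h, w, 20))
  expect_equal(unname(roi_intensity(make_dtt_stack(fr, 5), masks)$peak_pct), 0)
  fr[, , 10:14] <- 102L  # uniform 2% plateau
  expect_equal(unname(roi_intensity(make_dtt_stack(fr, 5), masks)$peak_pct), 2)
  # undersized mask shrinks the ROI with a warning
  tiny <- matrix(FALSE, h, w); tiny[1:8, 1:8] <- TRUE
  expect_warning(roi_rect(tiny, 20), "shrunk")
})

test_that("onset_region picks the first-crossing region with tie-breaks", {
  h <- 40; w <- 80
  mE <- matrix(FALSE, h, w); mE[, 1:40] <- TRUE
  mT <- matrix(FALSE, h, w); mT[, 41:80] <- TRUE
  masks <- as_mask_set(list(EC = mE, TC = mT))
  fr <- array(100L, dim = c(h, w, 30))
  fr[, 1:40, 8:20] <- 102L    # EC rises at frame 8
  fr[, 41:80, 10:20] <- 102L  # TC two frames later
  d <- make_dtt_stack(fr, 5, masks)
  expect_identical(onset_region(d, masks), "EC")
  # simultaneous equal rise: fixed region order applies (EC before TC)
  fr2 <- array(100L, dim = c(h, w, 30)); fr2[, , 10:20] <- 102L
  expect_identical(onset_region(make_dtt_stack(fr2, 5, masks), masks), "EC")
  # sub-threshold stack: no onset region
  fr3 <- array(100L, dim = c(h, w, 30))
  expect_identical(onset_region(make_dtt_stack(fr3, 5, masks), masks),
                   NA_character_)
})

test_that("area_pct is monotone in stack amplitude", {
  h <- 30; w <- 30; nc <- 5L
  m <- matrix(TRUE, h, w)
  masks <- as_mask_set(list(EC = m))
  set.seed(3)
  base <- array(100 + rnorm(h * w * 40, 0, 0.4), dim = c(h, w, 40))
  bump <- array(0, dim = dim(base)); bump[, , 10:25] <- 1.1
  areas <- vapply(c(0.5, 0.9, 1.1, 1.5), function(sc) {
    fr <- round(base + sc * bump)
    sle_area(involvement_map(make_dtt_stack(fr, nc, masks)), masks)[["EC"]]
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("IOS generator recovers spec parameters by construction", {
  masks <- region_masks()
  ev <- list(onset_region = "EC", duration_s = 55, phase = "intervention")
  ser <- generate_ios_series(ev, masks, specs$LAC_33, seed = 11,
                             jitter = FALSE)
  expect_s3_class(ser, "ios_series")
  expect_gte(ser$n_control_frames, 20L)
  d <- compute_dtt(ser)
  inv <- involvement_map(d)
  areas <- sle_area(inv, masks)
  # noiseless design involves an exact pixel count; noise may drop a few
  quantum <- 100 / sum(masks$SUB)
  expect_close(areas[["SUB"]], 37.8, abs = max(1, 10 * quantum))
  # ROI dT/T calibrated to the spec's regional amplitude
  pk <- roi_intensity(d, masks)$peak_pct
  expect_close(pk[["SUB"]], 0.38, rel = 0.10)
  # ground-truth pixel sets satisfy the involvement rule almost surely
  gtidx <- ser$ground_truth$SUB$involved_idx
  expect_gt(mean(inv[gtidx]), 0.99)
  # uninvolved pixels stay out
  expect_lt(sum(inv & masks$SUB & !seq_along(inv) %in% gtidx) / sum(masks$SUB),
            0.01)
  # onset region rises first
  expect_identical(onset_region(d, masks), "EC")
})

test_that("IOS noise floor stays below 0.1% per ROI", {
  masks <- region_masks()
  silent <- group_spec("quiet",
                       ios_peak_dtt_pct = apseize:::region_phase_matrix(rep(0, 12)),
                       area_fraction_pct = apseize:::region_phase_matrix(rep(0, 12)))
  ev <- list(onset_region = "EC", duration_s = 50, phase = "baseline")
  ser <- generate_ios_series(ev, masks, silent, seed = 3)
  d <- compute_dtt(ser)
  tc <- roi_intensity(d, masks)$time_course
  expect_lt(max(abs(tc), na.rm = TRUE), 0.1)
  # and downstream area is exactly zero
  expect_equal(unname(sle_area(involvement_map(d), masks)),
               rep(0, 4))
})

test_that("control frames self-normalise to ~0", {
  masks <- region_masks()
  ev <- list(onset_region = "EC", duration_s = 55, phase = "baseline")
  ser <- generate_ios_series(ev, masks, specs$control, seed = 5)
  d <- compute_dtt(ser)
  ctrl <- d$dtt[, , seq_len(ser$n_control_frames)]
  expect_lt(abs(mean(ctrl, na.rm = TRUE)), 0.01)
})

test_that("pseudocolor rendering is deterministic", {
  fr <- array(100L, dim = c(8, 8, 4)); fr[2, 2, 3:4] <- 120L
  d <- make_dtt_stack(fr, 2)
  out1 <- file.path(tempdir(), "pc1"); out2 <- file.path(tempdir(), "pc2")
  p1 <- render_pseudocolor(d, out1)
  p2 <- render_pseudocolor(d, out2)
  expect_length(p1, 4L)
  expect_identical(readBin(p1[3], "raw", 1e5), readBin(p2[3], "raw", 1e5))
  # zero stack renders a uniform frame (plus the fixed scale bar)
  d0 <- make_dtt_stack(array(100L, dim = c(8, 8, 4)), 2)
  p0 <- render_pseudocolor(d0, file.path(tempdir(), "pc0"))
  raw0 <- readBin(p0[1], "raw", 1e5)
  hdr_end <- which(raw0 == as.raw(10))[3]    # end of the P6 text header
  pix <- matrix(as.integer(raw0[-seq_len(hdr_end)]), nrow = 3)
  in_image <- ((seq_len(ncol(pix)) - 1) %% (8 + 12)) < 8  # bar excluded
  expect_identical(nrow(unique(t(pix[, in_image, drop = FALSE]))), 1L)
})
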