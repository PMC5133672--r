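test_that("segmentation recovers a rasterized disk and rejects blanks", {
  ev <- simulate_event(viscoelastic_cell_spec(initial_diameter = 16,
                                              max_strain = 0),
                       quiet_render())
  seg <- segment_frame(ev$frames[[1L]])
  r_px <- 16 / 2 / 0.4
  expect_lt(abs(seg$area_px / (pi * r_px^2) - 1), 0.02)
  expect_lt(abs(sum(seg$mask) / (pi * r_px^2) - 1), 0.02)
  # blank image signals no cell, distinctly from an error
  blank <- segment_frame(matrix(1, 32L, 32L))
  expect_false(blank$ok)
  expect_identical(blank$reason, "no_cell")
})

test_that("only the largest connected component is retained", {
  img <- matrix(1, 64L, 64L)
  big <- ellipse_polygon(12, 12, center = c(24, 24))
  for (i in seq_len(64)) for (j in seq_len(64)) {
    if ((i - 24)^2 + (j - 24)^2 <= 12^2) img[i, j] <- 0.2
    if ((i - 52)^2 + (j - 52)^2 <= 4^2) img[i, j] <- 0.2
  }
  seg <- segment_frame(img, method = "fixed", threshold = 0.6)
  expect_true(seg$ok)
  expect_lt(abs(seg$centroid[1L] - 24), 1)   # the big blob, not the 4-px one
  expect_lt(abs(seg$area_px / (pi * 12^2) - 1), 0.1)
})

test_that("boundary trace reproduces analytic radii and areas", {
  circ <- ellipse_polygon(20, 20, center = c(40, 40))
  tr <- contour_to_trace(circ, n_angles = 360L)
  expect_true(all(abs(tr$radii - 20) < 0.5))
  ell <- ellipse_polygon(15, 8, center = c(30, 30))
  tr2 <- contour_to_trace(ell, n_angles = 360L)
  expect_lt(abs(tr2$radii[1L] - 15), 0.5)                 # theta = 0
  expect_lt(abs(tr2$radii[91L] - 8), 0.5)                 # theta = pi/2
  # polar-form area (1/2 sum r^2 dtheta) vs shoelace oracle, odd polygon
  poly <- withr::with_seed(7, {
    th <- sort(stats::runif(40, 0, 2 * pi))
    r <- 10 + stats::rnorm(40, 0, 1.2)
    cbind(50 + r * cos(th), 50 + r * sin(th))
  })
  tr3 <- contour_to_trace(poly, n_angles = 720L)
  polar_area <- 0.5 * sum(tr3$radii^2) * (2 * pi / 720)
  shoelace <- abs(defcyto:::polygon_area(poly))
  expect_lt(abs(polar_area / shoelace - 1), 0.01)
  # round trip trace -> polygon preserves area within 1%
  rt_area <- abs(defcyto:::polygon_area(trace_to_polygon(tr3)))
  expect_lt(abs(rt_area / shoelace - 1), 0.01)
})

test_that("deformability is the moment-ellipse axis ratio, rotation invariant", {
  expect_lt(abs(deformability(ellipse_polygon(10, 10)) - 1), 0.02)
  expect_lt(abs(deformability(ellipse_polygon(16, 8)) - 2), 0.05)
  d0 <- deformability(ellipse_polygon(16, 8))
  d37 <- deformability(ellipse_polygon(16, 8, angle = 37 * pi / 180))
  expect_lt(abs(d0 - d37), 1e-3)
  expect_error(deformability(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
})

test_that("morphology metrics match their analytic and brute-force oracles", {
  th <- seq(0, 2 * pi, length.out = 361L)[-361L]
  flat <- morphology_metrics(rep(10, 360), window = 31L)
  expect_identical(unname(flat), c(0, 0))
  lobed <- morphology_metrics(10 * (1 + 0.05 * sin(6 * th)), window = 9L)
  expect_identical(lobed[["intersections"]], 12)
  expect_gt(lobed[["roughness"]], 0)
  # brute-force circular crossing count on random traces
  withr::with_seed(21, {
    for (rep in 1:10) {
      r <- 10 + as.numeric(stats::filter(stats::rnorm(360), rep(0.2, 5),
                                         circular = TRUE))
      got <- morphology_metrics(r, window = 31L)
      half <- 15L
      ma <- vapply(seq_len(360), function(k) {
        idx <- ((k - 1L - half):(k - 1L + half)) %% 360L + 1L
        mean(r[idx])
      }, 0)
      resid <- r - ma
      s <- sign(resid); s <- s[s != 0]
      cross <- sum(s != c(s[-1L], s[1L]))
      expect_equal(got[["intersections"]], cross)
      expect_equal(got[["roughness"]], stats::sd(resid) / mean(r),
                   tolerance = 1e-12)
    }
  })
  # invariance to the starting angle
  r <- 10 * (1 + 0.04 * sin(3 * th) + 0.02 * cos(8 * th))
  m1 <- morphology_metrics(r, 31L)
  m2 <- morphology_metrics(r[c(100:360, 1:99)], 31L)
  expect_equal(m1[["roughness"]], m2[["roughness"]], tolerance = 1e-12)
  expect_identical(m1[["intersections"]], m2[["intersections"]])
  expect_error(morphology_metrics(r, 30L), "odd")
})

test_that("extract_profile recovers the analytic profile of a stretch event", {
  ev <- simulate_event(viscoelastic_cell_spec(max_strain = 0.5,
                                              creep_time = 0.5),
                       quiet_render())
  prof <- extract_profile(ev)
  expect_lt(abs(prof[["D3"]] / 2.25 - 1), 0.03)    # (1 + 0.5)^2, saturated
  expect_lt(abs(prof[["S1"]] / 0.5 - 1), 0.05)
  expect_gt(prof[["T2"]], 0)
  expect_lt(abs(prof[["AR1"]] - 1), 0.02)
})

test_that("a zero-stretch event yields a null profile", {
  ev <- simulate_event(viscoelastic_cell_spec(max_strain = 0),
                       quiet_render())
  prof <- extract_profile(ev)
  expect_lt(abs(prof[["D1"]] - 1), 0.02)
  expect_lt(abs(prof[["D3"]] - 1), 0.02)
  expect_lt(abs(prof[["S1"]]), 0.02)
  expect_lt(abs(prof[["T2"]]), 0.02)
})

test_that("maximum deformability at the arrival frame gives T1 = 0", {
  # creep saturates within a tiny fraction of a frame: D3 is at arrival + 1
  # frame; with the arrival frame itself at strain 0 the peak lands on the
  # first post-arrival frame, so T1 equals one frame interval; a literal
  # peak-at-arrival happens for zero stretch
  ev <- simulate_event(viscoelastic_cell_spec(max_strain = 0),
                       quiet_render())
  prof <- extract_profile(ev)
  expect_identical(prof[["T1"]], 0)
})

test_that("scale covariance: halving the resolution leaves the profile", {
  spec <- viscoelastic_cell_spec(max_strain = 0.4,
                                 boundary_modes = list(c(5, 0.04)))
  p1 <- extract_profile(simulate_event(spec, quiet_render(pixel_size = 0.3)))
  p2 <- extract_profile(simulate_event(spec, quiet_render(pixel_size = 0.6)))
  expect_lt(abs(p1[["A"]] / p2[["A"]] - 1), 0.02)
  expect_lt(abs(p1[["D3"]] - p2[["D3"]]), 0.05)
  expect_lt(abs(p1[["S1"]] - p2[["S1"]]), 0.05)
  expect_lte(abs(p1[["M4"]] - p2[["M4"]]), 2)
})

test_that("extracted D3 and S1 increase strictly with max strain", {
  strains <- c(0.1, 0.25, 0.4, 0.55, 0.7)
  profs <- vapply(strains, function(s) {
    ev <- simulate_event(viscoelastic_cell_spec(max_strain = s,
                                                creep_time = 0.5),
                         quiet_render())
    extract_profile(ev)[c("D3", "S1")]
  }, numeric(2))
  expect_true(all(diff(profs["D3", ]) > 0))
  expect_true(all(diff(profs["S1", ]) > 0))
})

test_that("batch extraction filters failures and keeps order", {
  ev <- simulate_event(viscoelastic_cell_spec(max_strain = 0.3),
                       quiet_render(), event_id = "good")
  blank <- ev
  blank$event_id <- "blank"
  blank$frames <- lapply(blank$frames, function(f) matrix(1, 32L, 32L))
  tab <- batch_extract(list(ev, blank, ev))
  expect_equal(nrow(tab), 2L)
  rej <- attr(tab, "rejections")
  expect_identical(rej$event_id, "blank")
  expect_identical(unlist(tab[1L, DC_PARAMETERS]),
                   unlist(tab[2L, DC_PARAMETERS]))
  expect_warning(batch_extract(list(blank)), "rejected")
})
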