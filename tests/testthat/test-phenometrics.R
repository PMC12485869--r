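test_that("jump filter excludes exactly the tracks with a > threshold step", {
  ts <- make_track_set(list(
    ok   = cbind(c(0, 100, 300), c(0, 0, 0)),     # steps 100, 200: retained
    big  = cbind(c(0, 250, 260), c(0, 0, 0)),     # step 250: excluded
    gap  = rbind(c(0, 0), c(10, 0), c(500, 0))))
  # give 'gap' a non-consecutive jump: frames 0,1,5 with a 490 px span
  tr <- ts$tracks
  tr$frame[tr$track_id == "gap"] <- c(0L, 1L, 5L)
  ts <- track_set(tr, frame_interval = 30)
  res <- qc_filter_tracks(ts, metric_params(jump_threshold = 200))
  expect_equal(res$excluded, "big")  # 200 exactly is retained; gap span ignored
  expect_setequal(unique(res$trackset$tracks$track_id), c("ok", "gap"))
})

test_that("jump filter recovers the simulator's injected-jump ids exactly", {
  cfg <- sim_config(n_cells_t0 = 200L, n_frames = 48L,
                    diffusion_coefficient = 10, jump_fraction = 0.1, seed = 19L)
  ts <- simulate_tracks(cfg)
  res <- qc_filter_tracks(ts)
  expect_setequal(res$excluded, attr(ts, "jump_track_ids"))
})

test_that("normalized cell count tracks the division branching process", {
  const <- make_track_set(list(a = cbind(1:5, 1:5), b = cbind(2:6, 2:6)))
  cc <- normalized_cell_count(const)
  expect_equal(cc$count_norm, rep(1, 5))

  lambda <- 0.05  # divisions/cell/hour
  cfg <- sim_config(n_cells_t0 = 300L, n_frames = 97L,
                    diffusion_coefficient = 0, division_rate = lambda, seed = 2L)
  ts <- simulate_tracks(cfg)
  cc2 <- normalized_cell_count(ts)
  final <- cc2$count_norm[nrow(cc2)]
  p <- lambda * 30 / 60
  expected <- (1 + p)^96  # per-frame Bernoulli branching expectation
  # Monte-Carlo tolerance: supercritical branching sd/mean ~ sqrt((1-p)/(n0*p))
  tol <- 3 * expected * sqrt((1 - p) / (300 * p))
  expect_lt(abs(final - expected), tol)

  empty0 <- track_set(data.frame(track_id = "a", frame = 1:3, x = 1:3, y = 1:3))
  expect_error(normalized_cell_count(empty0), "frame 0")
})

test_that("nearest-neighbor index matches lattice and Poisson closed forms", {
  lat <- simulate_point_pattern("square_lattice", 100, 100, 100)
  area <- 100 * 100
  expect_equal(nn_distance_index(lat, area,
               metric_params(nn_order = 1, nn_expectation_order = "matched")), 2)
  expect_equal(nn_distance_index(lat, area,
               metric_params(nn_order = 2, nn_expectation_order = "matched")), 4 / 3)
  # first-mode denominator is E[r1] = s/2 regardless of order
  expect_equal(nn_distance_index(lat, area,
               metric_params(nn_order = 2, nn_expectation_order = "first")), 2)

  expect_equal(expected_nn_distance(1, 0.01), 1 / (2 * sqrt(0.01)))
  expect_equal(expected_nn_distance(2, 0.01), 3 / (4 * sqrt(0.01)))

  expect_warning(
    out <- nn_distance_index(cbind(c(0, 1), c(0, 0)), 100,
                             metric_params(nn_order = 2)),
    "undefined")
  expect_true(is.na(out))
})

test_that("nearest-neighbor index converges to its CSR limits", {
  idx <- vapply(1:8, function(s) {
    pts <- simulate_point_pattern("CSR", 2000, 1000, 1000, seed = s)
    c(nn_distance_index(pts, 1e6, metric_params(nn_order = 2,
                                                nn_expectation_order = "matched")),
      nn_distance_index(pts, 1e6, metric_params(nn_order = 2,
                                                nn_expectation_order = "first")))
  }, numeric(2))
  expect_lt(abs(mean(idx[1, ]) - 1), 0.03)
  expect_lt(abs(mean(idx[2, ]) - 1.5), 0.05)
})

test_that("MSD slope: stationary zero, Brownian 4D, invariances", {
  still <- make_track_set(list(a = cbind(rep(5, 20), rep(5, 20)),
                               b = cbind(rep(9, 20), rep(9, 20))))
  expect_equal(msd_slope(still)$slope, 0)

  cfg <- sim_config(field_width = 20000, field_height = 20000,
                    n_cells_t0 = 400L, n_frames = 96L,
                    diffusion_coefficient = 25, seed = 31L)
  ts <- simulate_tracks(cfg)
  s <- msd_slope(ts)$slope
  expect_lt(abs(s - 100) / 100, 0.05)

  # invariance under global translation and rotation
  rot <- ts
  th <- 0.7
  xy <- cbind(rot$tracks$x, rot$tracks$y) %*%
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) +
    matrix(c(300, -150), nrow(rot$tracks), 2, byrow = TRUE)
  rot$tracks$x <- xy[, 1]; rot$tracks$y <- xy[, 2]
  expect_equal(msd_slope(rot)$slope, s, tolerance = 1e-10)

  # only consecutive-frame spans contribute: a gapped track errors out alone
  gap <- track_set(data.frame(track_id = "g", frame = c(0L, 5L, 10L),
                              x = c(0, 100, 200), y = 0))
  expect_error(msd_slope(gap, metric_params(msd_max_lag = 120)), "no usable lag")
})

test_that("MSD slope is linear in the diffusion coefficient", {
  slope_at <- function(D, seed) {
    cfg <- sim_config(field_width = 6000, field_height = 6000,
                      n_cells_t0 = 300L, n_frames = 60L,
                      diffusion_coefficient = D, seed = seed)
    msd_slope(simulate_tracks(cfg))$slope
  }
  s1 <- slope_at(10, 41); s2 <- slope_at(20, 42)
  expect_lt(abs(s2 / s1 - 2), 0.15)
})

test_that("cosine collectivity hits its exact bounds and null", {
  par <- drift_track_set(n = 25, dx = 5, dy = 3)
  expect_equal(collectivity_cosine(par)$mean_cosine, 1)

  anti <- make_track_set(list(
    a = cbind(seq(100, 190, 10), rep(100, 10)),
    b = cbind(seq(300, 210, -10), rep(100, 10))))
  expect_equal(collectivity_cosine(anti)$mean_cosine, -1)

  cfg <- sim_config(field_width = 2000, field_height = 2000,
                    n_cells_t0 = 200L, n_frames = 48L,
                    diffusion_coefficient = 10, seed = 13L)
  ts <- simulate_tracks(cfg)
  expect_lt(abs(collectivity_cosine(ts)$mean_cosine), 0.02)
})

test_that("cosine collectivity: rotation invariance and drift monotonicity", {
  cfg <- sim_config(field_width = 2000, field_height = 2000,
                    n_cells_t0 = 100L, n_frames = 30L,
                    diffusion_coefficient = 10, seed = 17L)
  ts <- simulate_tracks(cfg)
  base <- collectivity_cosine(ts)$mean_cosine
  rot <- ts
  th <- 1.1
  xy <- cbind(rot$tracks$x, rot$tracks$y) %*%
    matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot$tracks$x <- xy[, 1]; rot$tracks$y <- xy[, 2]
  expect_equal(collectivity_cosine(rot)$mean_cosine, base, tolerance = 1e-10)

  # adding a common drift to every cell pushes the mean cosine toward 1
  with_drift <- function(ts, v) {
    out <- ts
    out$tracks$x <- out$tracks$x + v * out$tracks$frame
    out
  }
  cs <- vapply(c(0, 10, 40, 200), function(v) {
    collectivity_cosine(with_drift(ts, v))$mean_cosine
  }, numeric(1))
  expect_true(all(diff(cs) > 0))
  expect_gt(cs[4], 0.9)

  # all-zero displacements are undefined, not zero
  still <- make_track_set(list(a = cbind(rep(1, 5), rep(1, 5)),
                               b = cbind(rep(2, 5), rep(2, 5))))
  expect_warning(out <- collectivity_cosine(still), "undefined")
  expect_true(is.na(out$mean_cosine))
})

test_that("phenotype table: metric scoping of the QC filter and regime directions", {
  # a sentinel track with a 1e6 px jump must change nothing but the
  # exclusion count and the position-based metrics it legitimately enters
  cfg <- sim_config(field_width = 3000, field_height = 3000,
                    n_cells_t0 = 80L, n_frames = 24L,
                    diffusion_coefficient = 10, seed = 23L)
  ts <- simulate_tracks(cfg)
  base <- compute_phenotype_table(list(ts))
  spiked <- ts
  extra <- data.frame(track_id = "sentinel", frame = 0:1,
                      t = c(0, 30), x = c(1, 2999), y = c(1, 2999))
  spiked$tracks <- rbind(spiked$tracks, extra)
  spk <- compute_phenotype_table(list(spiked))
  expect_equal(spk$msd_slope, base$msd_slope)
  expect_equal(spk$cosine_similarity, base$cosine_similarity)
  expect_equal(spk$n_tracks_excluded, base$n_tracks_excluded + 1L)
  expect_equal(spk$n_tracks_used, base$n_tracks_used)

  expect_equal(nrow(compute_phenotype_table(list())), 0L)
})

test_that("regime presets separate in the directions of the ligand phenotypes", {
  tab <- do.call(rbind, lapply(c("EGF_like", "IFNG_like", "OSM_like"), function(p) {
    ts <- simulate_tracks(regime_preset(p, seed = 29L, n_cells_t0 = 150L,
                                        n_frames = 48L), condition = p)
    compute_phenotype_table(list(ts))
  }))
  egf <- tab[tab$condition == "EGF_like", ]
  expect_lt(tab$nn_index[tab$condition == "OSM_like"], egf$nn_index)
  expect_gt(tab$cosine_similarity[tab$condition == "OSM_like"],
            egf$cosine_similarity)
  expect_gt(tab$msd_slope[tab$condition == "IFNG_like"], egf$msd_slope)
})

test_that("phenotype tables round-trip through the '#'-header writer", {
  ph <- data.frame(field_id = "f", condition = "EGF", knockdown = NA,
                   replicate = 1L, cell_count_norm = 1.2, msd_slope = 80,
                   nn_index = 1.4, nn_index_final = 1.3,
                   cosine_similarity = 0.01, n_cells_t0 = 100L,
                   n_tracks_used = 90L, n_tracks_excluded = 2L)
  f <- tempfile(fileext = ".csv")
  write_phenotypes(ph, f, metric_params())
  lines <- readLines(f)
  expect_true(any(grepl("^# jump_threshold: 200", lines)))
  back <- read.csv(f, comment.char = "#")
  expect_equal(back$msd_slope, 80)
})
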