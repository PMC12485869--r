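test_that("simulators are deterministic given a seed and reject bad parameters", {
  cfg <- sim_config(n_cells_t0 = 30L, n_frames = 20L, diffusion_coefficient = 10,
                    division_rate = 0.02, jump_fraction = 0.1, seed = 7L)
  a <- simulate_tracks(cfg)
  b <- simulate_tracks(cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(attr(a, "jump_track_ids"), attr(b, "jump_track_ids"))

  p1 <- simulate_point_pattern("CSR", 50, seed = 3L)
  p2 <- simulate_point_pattern("CSR", 50, seed = 3L)
  expect_identical(p1, p2)

  expect_error(sim_config(diffusion_coefficient = -1), "negative")
  expect_error(sim_config(diffusion_coefficient = NaN), "non-finite")
  expect_error(sim_config(n_frames = 1L), "n_frames")
  expect_error(simulate_point_pattern("square_lattice", 10), "perfect square")
})

test_that("degenerate dynamics give stationary tracks", {
  cfg <- sim_config(n_cells_t0 = 10L, n_frames = 15L,
                    diffusion_coefficient = 0, drift_speed = 0,
                    cohesion_strength = 0, division_rate = 0, seed = 1L)
  ts <- simulate_tracks(cfg)
  for (trk in split(ts$tracks, ts$tracks$track_id)) {
    expect_equal(diff(trk$x), rep(0, nrow(trk) - 1L))
    expect_equal(diff(trk$y), rep(0, nrow(trk) - 1L))
  }
})

test_that("Brownian tracks recover the per-axis step variance 2*D*dt", {
  D <- 12; dt <- 30
  cfg <- sim_config(field_width = 5000, field_height = 5000,
                    n_cells_t0 = 300L, n_frames = 40L,
                    diffusion_coefficient = D, seed = 21L)
  ts <- simulate_tracks(cfg)
  tr <- ts$tracks[order(ts$tracks$track_id, ts$tracks$frame), ]
  same <- tr$track_id[-1L] == tr$track_id[-nrow(tr)]
  steps <- c(diff(tr$x)[same], diff(tr$y)[same])
  v <- var(steps)
  se <- v * sqrt(2 / (length(steps) - 1))
  expect_lt(abs(v - 2 * D * dt), 3 * se)
})

test_that("tracks stay inside the field and cohesion contracts clusters", {
  cfg <- sim_config(field_width = 400, field_height = 400, n_cells_t0 = 60L,
                    n_frames = 30L, diffusion_coefficient = 50, seed = 5L)
  ts <- simulate_tracks(cfg)
  expect_true(all(ts$tracks$x >= 0 & ts$tracks$x <= 400))
  expect_true(all(ts$tracks$y >= 0 & ts$tracks$y <= 400))

  cfg2 <- sim_config(n_cells_t0 = 80L, n_frames = 12L,
                     diffusion_coefficient = 0, cohesion_strength = 2,
                     n_clusters = 3L, seed = 6L)
  ts2 <- simulate_tracks(cfg2)
  cl <- attr(ts2, "cluster")
  tr <- ts2$tracks
  mean_dist <- vapply(0:10, function(f) {
    at <- tr[tr$frame == f, ]
    cc <- cl[at$track_id]
    d <- 0
    for (k in unique(cc)) {
      sel <- cc == k
      d <- d + sum(sqrt((at$x[sel] - mean(at$x[sel]))^2 +
                        (at$y[sel] - mean(at$y[sel]))^2))
    }
    d / nrow(at)
  }, numeric(1))
  expect_true(all(diff(mean_dist) <= 1e-9))
})

test_that("divisions grow the population and daughters start at the parent", {
  cfg <- sim_config(n_cells_t0 = 50L, n_frames = 20L,
                    diffusion_coefficient = 0, division_rate = 0.3, seed = 8L)
  ts <- simulate_tracks(cfg)
  counts <- normalized_cell_count(ts)
  expect_gt(counts$count_norm[nrow(counts)], 1)
  # with D = 0, every daughter coincides with a stationary parent position
  daughters <- setdiff(unique(ts$tracks$track_id), as.character(1:50))
  expect_gt(length(daughters), 0L)
  origins <- ts$tracks[ts$tracks$track_id %in% daughters &
                       !duplicated(ts$tracks$track_id), ]
  parents0 <- ts$tracks[ts$tracks$frame == 0L, ]
  for (i in seq_len(nrow(origins))) {
    expect_true(any(abs(parents0$x - origins$x[i]) < 1e-9 &
                    abs(parents0$y - origins$y[i]) < 1e-9))
  }
})

test_that("point patterns: lattice geometry, CSR intensity, Thomas clustering", {
  lat <- simulate_point_pattern("square_lattice", 100, 100, 100)
  expect_equal(nrow(lat), 100L)
  D <- as.matrix(dist(lat))
  nn1 <- apply(D, 1, function(r) sort(r, partial = 2)[2])
  expect_equal(unname(nn1), rep(10, 100))

  csr <- simulate_point_pattern("CSR", 500, 200, 300, seed = 2L)
  expect_equal(nrow(csr), 500L)  # intensity exactly n/(width*height)
  expect_true(all(csr[, "x"] >= 0 & csr[, "x"] <= 200))
  expect_true(all(csr[, "y"] >= 0 & csr[, "y"] <= 300))

  # Monte-Carlo: clustered pattern has smaller mean NN distance than CSR
  mean_nn <- function(p) {
    D <- as.matrix(dist(p))
    mean(apply(D, 1, function(r) sort(r, partial = 2)[2]))
  }
  nn_th <- vapply(1:5, function(s) {
    mean_nn(simulate_point_pattern("Thomas_cluster", 400, 1000, 1000,
                                   params = list(sigma = 15), seed = s))
  }, numeric(1))
  nn_csr <- vapply(1:5, function(s) {
    mean_nn(simulate_point_pattern("CSR", 400, 1000, 1000, seed = 100 + s))
  }, numeric(1))
  expect_lt(mean(nn_th), mean(nn_csr))
})

test_that("regime presets satisfy their defining inequalities", {
  egf <- regime_preset("EGF_like")
  ifng <- regime_preset("IFNG_like")
  osm <- regime_preset("OSM_like")
  expect_equal(egf$cohesion_strength, 0)
  expect_equal(ifng$cohesion_strength, 0)
  expect_gt(osm$cohesion_strength, 0)
  expect_gte(osm$n_clusters, 2L)
  expect_gt(ifng$diffusion_coefficient, egf$diffusion_coefficient)
})

test_that("condition-network simulator returns exact per-node edit truth", {
  # rewired_fraction 0: identical networks, truth all zero
  z <- simulate_condition_networks(20, 0, seed = 1L)
  expect_identical(z$net_a$edges, z$net_b$edges)
  expect_true(all(z$truth$edits == 0L))

  # constructed case: 2 deletions + 1 addition incident to one node
  ea <- data.frame(source = c("A", "A", "B"),
                   relation = "phosphorylates",
                   target = c("B", "C", "C"))
  eb <- data.frame(source = c("B", "A"),
                   relation = "phosphorylates",
                   target = c("C", "D"))
  na <- condition_network(ea); nb <- condition_network(eb)
  expect_equal(rewiring_score(na, nb, "A")$raw_rewiring, 3L)

  # random instance vs brute-force oracle
  sim <- simulate_condition_networks(50, 0.3, seed = 11L)
  for (nd in sim$truth$node) {
    expect_equal(rewiring_score(sim$net_a, sim$net_b, nd)$raw_rewiring,
                 sim$truth$edits[sim$truth$node == nd],
                 info = nd)
  }
})

test_that("phenotype-table simulator follows its generative contract", {
  # zero effects, zero noise: every normalized score is exactly 1
  ph <- simulate_phenotype_table(4, NULL, noise_sd = 0, n_replicates = 2, seed = 1)
  nz <- normalize_to_control(ph)
  expect_equal(nz$norm_value, rep(1, nrow(nz)))

  # one OSM-only effect departs from 1 only under OSM
  eff <- array(0, dim = c(4, 3, 4))
  eff[2, 2, 3] <- 0.5  # knockdown 2, OSM, nn_index
  ph2 <- simulate_phenotype_table(4, eff, noise_sd = 0, n_replicates = 2, seed = 1)
  nz2 <- normalize_to_control(ph2)
  dev <- nz2[abs(nz2$norm_value - 1) > 1e-12, ]
  expect_true(all(dev$knockdown == "siKD02"))
  expect_true(all(dev$treatment == "OSM"))
  expect_true(all(dev$metric == "nn_index"))
  expect_equal(unique(dev$norm_value), 1.5)

  expect_error(simulate_phenotype_table(3, n_replicates = 1), "n_replicates")
})

test_that("simulator writers emit a complete parameter sidecar", {
  cfg <- sim_config(n_cells_t0 = 5L, n_frames = 3L, seed = 42L)
  f <- tempfile(fileext = ".yaml")
  write_sim_sidecar(cfg, f)
  back <- yaml::read_yaml(f)
  expect_equal(back$seed, 42L)
  expect_setequal(names(back), names(unclass(cfg)))
})
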