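# small in-code fixtures shared across test files

# a track set built from explicit per-track coordinate matrices:
# tracks = named list of n x 2 matrices (rows are consecutive frames from 0)
make_track_set <- function(tracks, frame_interval = 30, width = 1000,
                           height = 1000, ...) {
  df <- do.call(rbind, lapply(names(tracks), function(id) {
    m <- tracks[[id]]
    data.frame(track_id = id, frame = seq_len(nrow(m)) - 1L,
               x = m[, 1], y = m[, 2])
  }))
  track_set(df, field_width = width, field_height = height,
            frame_interval = frame_interval, ...)
}

# parallel-drift fixture: n cells on a grid, all stepping (dx, dy) per frame
drift_track_set <- function(n = 25, n_frames = 10, dx = 5, dy = 0,
                            spacing = 50) {
  m <- ceiling(sqrt(n))
  ox <- spacing * ((seq_len(n) - 1L) %% m) + 100
  oy <- spacing * ((seq_len(n) - 1L) %/% m) + 100
  tracks <- lapply(seq_len(n), function(i) {
    cbind(ox[i] + dx * (seq_len(n_frames) - 1L),
          oy[i] + dy * (seq_len(n_frames) - 1L))
  })
  names(tracks) <- sprintf("c%02d", seq_len(n))
  make_track_set(tracks)
}

# brute-force per-node incident-edge symmetric difference (rewiring oracle)
brute_rewiring <- function(net_a, net_b, node) {
  inc <- function(net) {
    e <- net$edges
    hit <- e$source == node | e$target == node
    paste(e$source[hit], e$relation[hit], e$target[hit])
  }
  a <- inc(net_a); b <- inc(net_b)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

# null-screen effect vectors with symmetric OSM/IFNG magnitudes
null_screen_effects <- function(n) {
  list(osm = abs(stats::rnorm(n)), ifng = abs(stats::rnorm(n)))
}

# a simulated knockdown screen with one planted OSM-specific disruptor
# (motility up, collectivity down under OSM only) in knockdown 1
planted_screen <- function(seed, n_kd = 14, effect = 0.8, noise_sd = 0.05) {
  eff <- array(0, dim = c(n_kd, 3, 4))
  # dims: knockdown x (EGF, OSM, IFNG) x (count, msd, nn, cosine)
  eff[1, 2, 2] <- effect
  eff[1, 2, 4] <- -effect
  ph <- simulate_phenotype_table(n_kd, eff, noise_sd = noise_sd,
                                 n_replicates = 3, seed = seed)
  normalize_to_control(ph)
}
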