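#' Simulation configuration for synthetic cell tracks
#'
#' Generative parameters for a 2D random-walk + cluster-drift + cohesion
#' track simulator emulating a 48 h live-cell imaging acquisition at
#' 30-minute intervals. Per-axis Gaussian step variance is `2 * D * dt`
#' (Brownian motion with diffusion coefficient `D`), each cluster shares a
#' fixed drift heading, and cohesion pulls cells toward their cluster
#' centroid. Boundaries reflect (confined imaging field).
#'
#' @param field_width,field_height field extent, px.
#' @param n_cells_t0 cells at frame 0.
#' @param n_frames number of frames (>= 2); 96 frames at 30 min = 47.5 h of motion.
#' @param frame_interval minutes between frames.
#' @param diffusion_coefficient `D`, px^2/min.
#' @param drift_speed shared per-cluster directed speed, px/min.
#' @param cohesion_strength attraction toward the cluster centroid; the
#'   cohesive displacement per frame is `cohesion_strength * frame_interval`
#'   px, capped at the distance to the centroid (no overshoot).
#' @param n_clusters number of clusters; cells are assigned to the nearest of
#'   `n_clusters` uniformly placed cluster centers at t0.
#' @param division_rate divisions per cell per hour; a daughter track starts
#'   at the parent's position on the following frame under a new id.
#' @param jump_fraction probability that a track receives one injected
#'   tracking-artifact jump of magnitude in (200, 400] px.
#' @param seed integer seed; identical seed + config gives identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(field_width = 1000, field_height = 1000,
                       n_cells_t0 = 200L, n_frames = 96L,
                       frame_interval = 30,
                       diffusion_coefficient = 5,
                       drift_speed = 0, cohesion_strength = 0,
                       n_clusters = 1L, division_rate = 0,
                       jump_fraction = 0, seed = 1L) {
  num <- c(field_width = field_width, field_height = field_height,
           n_cells_t0 = n_cells_t0, n_frames = n_frames,
           frame_interval = frame_interval,
           diffusion_coefficient = diffusion_coefficient,
           drift_speed = drift_speed, cohesion_strength = cohesion_strength,
           n_clusters = n_clusters, division_rate = division_rate,
           jump_fraction = jump_fraction)
  if (any(!is.finite(num))) {
    stop("non-finite parameter(s): ",
         paste(names(num)[!is.finite(num)], collapse = ", "))
  }
  if (any(num < 0)) {
    stop("negative parameter(s): ", paste(names(num)[num < 0], collapse = ", "))
  }
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (n_cells_t0 < 1) stop("n_cells_t0 must be >= 1")
  if (n_clusters < 1) stop("n_clusters must be >= 1")
  if (jump_fraction > 1) stop("jump_fraction must be <= 1")
  structure(list(field_width = field_width, field_height = field_height,
                 n_cells_t0 = as.integer(n_cells_t0),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 diffusion_coefficient = diffusion_coefficient,
                 drift_speed = drift_speed,
                 cohesion_strength = cohesion_strength,
                 n_clusters = as.integer(n_clusters),
                 division_rate = division_rate,
                 jump_fraction = jump_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Regime presets emulating the three ligand phenotypes
#'
#' `EGF_like`: dispersed Brownian baseline. `IFNG_like`: dispersed with a
#' fourfold higher diffusion coefficient (fast individual motility).
#' `OSM_like`: cohesive clustered co-drifting motion (collective migration):
#' several clusters, positive cohesion, shared per-cluster drift.
#'
#' @param name one of `"EGF_like"`, `"IFNG_like"`, `"OSM_like"`.
#' @param seed integer seed stored in the config.
#' @param ... overrides passed to [sim_config()] (e.g. `n_cells_t0`).
#' @return a `sim_config` with attribute `"regime"` set to `name`.
#' @export
regime_preset <- function(name = c("EGF_like", "IFNG_like", "OSM_like"),
                          seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    EGF_like  = list(diffusion_coefficient = 5, drift_speed = 0,
                     cohesion_strength = 0, n_clusters = 1L),
    IFNG_like = list(diffusion_coefficient = 20, drift_speed = 0,
                     cohesion_strength = 0, n_clusters = 1L),
    OSM_like  = list(diffusion_coefficient = 5, drift_speed = 0.5,
                     cohesion_strength = 0.4, n_clusters = 8L)
  )
  defaults <- list(field_width = 1000, field_height = 1000,
                   n_cells_t0 = 200L, n_frames = 96L, frame_interval = 30,
                   division_rate = 0.01, jump_fraction = 0, seed = seed)
  args <- utils::modifyList(c(defaults, base), list(...))
  cfg <- do.call(sim_config, args)
  attr(cfg, "regime") <- name
  cfg
}

# fold a coordinate into [0, L] by reflection (1-Lipschitz triangle map)
.reflect <- function(v, L) {
  v <- v %% (2 * L)
  ifelse(v > L, 2 * L - v, v)
}

#' Simulate cell tracks
#'
#' Generates a [track_set()] under the model in [sim_config()]: isotropic
#' Gaussian steps with per-axis variance `2*D*dt`, plus per-cluster fixed-
#' heading drift `drift_speed*dt`, plus a cohesive pull of
#' `cohesion_strength*dt` toward the cluster centroid (capped at the centroid
#' distance), with reflecting boundaries. Divisions spawn a daughter track at
#' the parent position starting the next frame. With `jump_fraction > 0`,
#' each track independently receives at most one artifact jump: a single
#' frame-to-frame displacement of magnitude in (200, 400] px, the signature
#' of a tracking error.
#'
#' @param config a [sim_config()].
#' @param field_id,condition,knockdown,replicate metadata for the returned set.
#' @return a `track_set`; attribute `"jump_track_ids"` lists tracks that
#'   received an injected jump, attribute `"cluster"` maps track id to cluster.
#' @export
simulate_tracks <- function(config, field_id = "sim", condition = NA_character_,
                            knockdown = NA_character_, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_tracks_impl(
    config, field_id, condition, knockdown, replicate))
}

.simulate_tracks_impl <- function(cfg, field_id, condition, knockdown, replicate) {
  W <- cfg$field_width; H <- cfg$field_height
  dt <- cfg$frame_interval
  nF <- cfg$n_frames
  sd_step <- sqrt(2 * cfg$diffusion_coefficient * dt)
  p_div <- cfg$division_rate * dt / 60

  n0 <- cfg$n_cells_t0
  x <- stats::runif(n0, 0, W)
  y <- stats::runif(n0, 0, H)

  # cluster centers and memberships (nearest center at t0)
  cx <- stats::runif(cfg$n_clusters, 0, W)
  cy <- stats::runif(cfg$n_clusters, 0, H)
  if (cfg$n_clusters == 1L) {
    cl <- rep(1L, n0)
  } else {
    d2 <- outer(x, cx, "-")^2 + outer(y, cy, "-")^2
    cl <- max.col(-d2)
  }
  theta <- stats::runif(cfg$n_clusters, 0, 2 * pi)
  hx <- cos(theta); hy <- sin(theta)

  ids <- seq_len(n0)
  next_id <- n0 + 1L
  # per-frame records accumulated as lists of equal-length vectors
  rec_id <- vector("list", nF); rec_x <- vector("list", nF)
  rec_y <- vector("list", nF); rec_f <- vector("list", nF)
  rec_id[[1]] <- ids; rec_x[[1]] <- x; rec_y[[1]] <- y
  rec_f[[1]] <- rep(0L, n0)
  parent_cl <- cl

  for (f in 2:nF) {
    n <- length(ids)
    ex <- stats::rnorm(n, 0, sd_step)
    ey <- stats::rnorm(n, 0, sd_step)
    dx <- ex + cfg$drift_speed * dt * hx[parent_cl]
    dy <- ey + cfg$drift_speed * dt * hy[parent_cl]
    if (cfg$cohesion_strength > 0) {
      mx <- tapply(x, parent_cl, mean)[as.character(parent_cl)]
      my <- tapply(y, parent_cl, mean)[as.character(parent_cl)]
      vx <- mx - x; vy <- my - y
      dcen <- sqrt(vx^2 + vy^2)
      pull <- pmin(cfg$cohesion_strength * dt, dcen)
      nz <- dcen > 0
      dx[nz] <- dx[nz] + pull[nz] * vx[nz] / dcen[nz]
      dy[nz] <- dy[nz] + pull[nz] * vy[nz] / dcen[nz]
    }
    x <- .reflect(x + dx, W)
    y <- .reflect(y + dy, H)

    # divisions decided on this transition; daughter appears at this frame,
    # co-located with the parent, then moves independently
    if (p_div > 0) {
      div <- stats::runif(n) < p_div
      if (any(div)) {
        k <- sum(div)
        ids <- c(ids, seq.int(next_id, length.out = k))
        next_id <- next_id + k
        x <- c(x, x[div]); y <- c(y, y[div])
        parent_cl <- c(parent_cl, parent_cl[div])
      }
    }
    rec_id[[f]] <- ids; rec_x[[f]] <- x; rec_y[[f]] <- y
    rec_f[[f]] <- rep(f - 1L, length(ids))
  }

  df <- data.frame(track_id = unlist(rec_id), frame = unlist(rec_f),
                   x = unlist(rec_x), y = unlist(rec_y))

  # inject tracking-artifact jumps: one per affected track, > 200 px
  jump_ids <- integer(0)
  if (cfg$jump_fraction > 0) {
    all_ids <- seq_len(next_id - 1L)
    lens <- tabulate(df$track_id, nbins = next_id - 1L)
    eligible <- all_ids[lens >= 2L]
    affected <- eligible[stats::runif(length(eligible)) < cfg$jump_fraction]
    ord <- order(df$track_id, df$frame)
    df <- df[ord, , drop = FALSE]
    for (id in affected) {
      idx <- which(df$track_id == id)
      j <- if (length(idx) == 2L) 1L else sample.int(length(idx) - 1L, 1L)
      p0 <- c(df$x[idx[j]], df$y[idx[j]])
      q <- .sample_jump_target(p0, W, H)
      shift <- q - c(df$x[idx[j + 1L]], df$y[idx[j + 1L]])
      tail_idx <- idx[(j + 1L):length(idx)]
      df$x[tail_idx] <- .reflect(df$x[tail_idx] + shift[1], W)
      df$y[tail_idx] <- .reflect(df$y[tail_idx] + shift[2], H)
    }
    jump_ids <- affected
  }

  ts <- track_set(df, field_id = field_id, condition = condition,
                  knockdown = knockdown, replicate = replicate,
                  field_width = W, field_height = H, frame_interval = dt)
  attr(ts, "jump_track_ids") <- as.character(jump_ids)
  attr(ts, "cluster") <- stats::setNames(parent_cl, as.character(ids))
  attr(ts, "config") <- cfg
  ts
}

# sample an in-bounds jump destination with |q - p0| in (200, 400]
.sample_jump_target <- function(p0, W, H, lo = 200, hi = 400) {
  for (i in 1:1000) {
    m <- stats::runif(1, lo, hi)
    a <- stats::runif(1, 0, 2 * pi)
    q <- p0 + m * c(cos(a), sin(a))
    if (q[1] >= 0 && q[1] <= W && q[2] >= 0 && q[2] <= H && m > lo) return(q)
  }
  stop("field too small to place an in-bounds jump > ", lo, " px")
}

#' Simulate a spatial point pattern
#'
#' Validation inputs for the nearest-neighbor index: complete spatial
#' randomness (CSR, the null of the random-distribution normalization), a
#' Thomas cluster process (Poisson parents with Gaussian daughter scatter,
#' folded into the window), or a regular square lattice.
#'
#' @param kind `"CSR"`, `"Thomas_cluster"` or `"square_lattice"`.
#' @param n_points number of points (a perfect square for the lattice).
#' @param width,height window extent, px.
#' @param params list; for Thomas: `n_parents` (default `max(1, n_points %/% 20)`)
#'   and `sigma` (daughter scatter sd, default `min(width, height) / 50`).
#' @param seed integer seed.
#' @return matrix with columns `x`, `y` and exactly `n_points` rows.
#' @export
simulate_point_pattern <- function(kind = c("CSR", "Thomas_cluster", "square_lattice"),
                                   n_points, width = 1000, height = 1000,
                                   params = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (n_points < 1) stop("n_points must be >= 1")
  if (kind == "square_lattice") {
    m <- sqrt(n_points)
    if (m != floor(m)) stop("square_lattice requires n_points to be a perfect square")
    m <- as.integer(m)
    sx <- width / m; sy <- height / m
    gx <- sx / 2 + sx * (seq_len(m) - 1L)
    gy <- sy / 2 + sy * (seq_len(m) - 1L)
    pts <- as.matrix(expand.grid(x = gx, y = gy))
    return(pts)
  }
  withr::with_seed(seed, {
    if (kind == "CSR") {
      pts <- cbind(x = stats::runif(n_points, 0, width),
                   y = stats::runif(n_points, 0, height))
    } else {
      n_parents <- params$n_parents %||% max(1L, n_points %/% 20L)
      sigma <- params$sigma %||% (min(width, height) / 50)
      px <- stats::runif(n_parents, 0, width)
      py <- stats::runif(n_parents, 0, height)
      par <- sample.int(n_parents, n_points, replace = TRUE)
      pts <- cbind(x = .reflect(px[par] + stats::rnorm(n_points, 0, sigma), width),
                   y = .reflect(py[par] + stats::rnorm(n_points, 0, sigma), height))
    }
    pts
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a pair of condition networks with known rewiring ground truth
#'
#' Builds a random signed, directed interaction network A (relations sampled
#' from `relations`), then derives network B by deleting a fraction of A's
#' edges and adding the same number of fresh edges. Optionally plants extra
#' added edges incident to one node so that a known node carries the largest
#' rewiring score. The returned truth table holds, for every node, the exact
#' number of incident edge edits (each deleted or added edge counts once for
#' each endpoint it touches).
#'
#' @param n_nodes node count; nodes are named `N01`, `N02`, ...
#' @param rewired_fraction fraction of A's edges deleted (and replaced) in B.
#' @param seed integer seed.
#' @param n_edges edges in A (default `3 * n_nodes`).
#' @param relations relation labels to sample from.
#' @param planted_node node name to overload with extra additions, or `NULL`.
#' @param planted_edits number of extra added edges incident to `planted_node`.
#' @return list with `net_a`, `net_b` ([condition_network()]s) and `truth`
#'   (data.frame `node`, `edits`, covering every node of either network).
#' @export
simulate_condition_networks <- function(n_nodes, rewired_fraction, seed = 1L,
                                        n_edges = 3L * n_nodes,
                                        relations = c("phosphorylates", "dephosphorylates"),
                                        planted_node = NULL, planted_edits = 0L) {
  if (rewired_fraction < 0 || rewired_fraction > 1) {
    stop("rewired_fraction must be in [0, 1]")
  }
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  withr::with_seed(seed, {
    max_pairs <- n_nodes * (n_nodes - 1L)
    n_edges <- min(n_edges, max_pairs %/% 2L)
    pick_edges <- function(n, exclude_keys = character(0)) {
      out <- character(0)
      df <- NULL
      while (n > 0) {
        s <- sample(nodes, 2L * n, replace = TRUE)
        t <- sample(nodes, 2L * n, replace = TRUE)
        r <- sample(relations, 2L * n, replace = TRUE)
        cand <- data.frame(source = s, relation = r, target = t)
        cand <- cand[cand$source != cand$target, , drop = FALSE]
        key <- paste(cand$source, cand$relation, cand$target)
        keep <- !duplicated(key) & !(key %in% exclude_keys) & !(key %in% out)
        cand <- cand[keep, , drop = FALSE]
        take <- utils::head(cand, n)
        df <- rbind(df, take)
        out <- c(out, paste(take$source, take$relation, take$target))
        n <- n - nrow(take)
      }
      df
    }
    ea <- pick_edges(n_edges)
    key_a <- paste(ea$source, ea$relation, ea$target)
    n_del <- round(rewired_fraction * n_edges)
    del_idx <- if (n_del > 0) sample.int(n_edges, n_del) else integer(0)
    deleted <- ea[del_idx, , drop = FALSE]
    kept <- ea[setdiff(seq_len(n_edges), del_idx), , drop = FALSE]
    added <- if (n_del > 0) pick_edges(n_del, exclude_keys = key_a) else ea[0, ]
    if (!is.null(planted_node) && planted_edits > 0) {
      stopifnot(planted_node %in% nodes)
      extra <- NULL
      used <- c(key_a, paste(added$source, added$relation, added$target))
      others <- setdiff(nodes, planted_node)
      while (is.null(extra) || nrow(extra) < planted_edits) {
        o <- sample(others, 1L); r <- sample(relations, 1L)
        e <- data.frame(source = planted_node, relation = r, target = o)
        k <- paste(e$source, e$relation, e$target)
        if (!(k %in% used)) { extra <- rbind(extra, e); used <- c(used, k) }
      }
      added <- rbind(added, extra)
    }
    eb <- rbind(kept, added)
    edits <- rbind(deleted, added)
    cnt <- table(c(edits$source, edits$target))
    all_nodes <- sort(unique(c(ea$source, ea$target, eb$source, eb$target)))
    truth <- data.frame(node = all_nodes,
                        edits = as.integer(cnt[all_nodes]),
                        stringsAsFactors = FALSE)
    truth$edits[is.na(truth$edits)] <- 0L
    rownames(truth) <- NULL
    list(net_a = condition_network(ea, condition = "A"),
         net_b = condition_network(eb, condition = "B"),
         truth = truth)
  })
}

#' Simulate a knockdown-screen phenotype table
#'
#' Generates replicate phenotype scores laid out as knockdown x treatment x
#' metric x replicate, following `score = control_mean * (1 + effect) +
#' Gaussian noise`. A scrambled control knockdown (`siSCR`, zero effect) is
#' always included.
#'
#' @param n_knockdowns number of (non-control) knockdowns; named `siKD01`, ...
#' @param effect_matrix 3-d numeric array `[knockdown, treatment, metric]` of
#'   relative effects (0 = no change); dimensions may carry dimnames, else
#'   defaults are used. `NULL` means all zeros.
#' @param noise_sd sd of additive Gaussian noise, on the raw score scale.
#' @param n_replicates replicates per cell of the design (>= 2).
#' @param seed integer seed.
#' @param treatments treatment labels.
#' @param metrics metric labels.
#' @param control_means named raw-scale control means per metric.
#' @return data.frame with columns `knockdown`, `treatment`, `metric`,
#'   `replicate`, `value`.
#' @export
simulate_phenotype_table <- function(n_knockdowns, effect_matrix = NULL,
                                     noise_sd = 0, n_replicates = 3L, seed = 1L,
                                     treatments = c("EGF", "OSM", "IFNG"),
                                     metrics = c("cell_count_norm", "msd_slope",
                                                 "nn_index", "cosine_similarity"),
                                     control_means = c(cell_count_norm = 1.5,
                                                       msd_slope = 100,
                                                       nn_index = 1.2,
                                                       cosine_similarity = 0.3)) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (n_knockdowns < 1) stop("n_knockdowns must be >= 1")
  kds <- sprintf("siKD%02d", seq_len(n_knockdowns))
  if (is.null(effect_matrix)) {
    effect_matrix <- array(0, dim = c(n_knockdowns, length(treatments), length(metrics)))
  }
  stopifnot(length(dim(effect_matrix)) == 3L,
            dim(effect_matrix)[1] == n_knockdowns,
            dim(effect_matrix)[2] == length(treatments),
            dim(effect_matrix)[3] == length(metrics))
  if (!is.null(dimnames(effect_matrix)[[1]])) kds <- dimnames(effect_matrix)[[1]]
  cm <- control_means[metrics]
  if (any(is.na(cm))) stop("control_means must name every metric")
  grid <- expand.grid(knockdown = c("siSCR", kds), treatment = treatments,
                      metric = metrics, replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  eff <- numeric(nrow(grid))
  is_kd <- grid$knockdown != "siSCR"
  ki <- match(grid$knockdown[is_kd], kds)
  ti <- match(grid$treatment[is_kd], treatments)
  mi <- match(grid$metric[is_kd], metrics)
  eff[is_kd] <- effect_matrix[cbind(ki, ti, mi)]
  base <- cm[grid$metric] * (1 + eff)
  withr::with_seed(seed, {
    grid$value <- as.numeric(base + stats::rnorm(nrow(grid), 0, noise_sd))
  })
  grid
}

#' Write a YAML sidecar recording simulation parameters
#'
#' Every simulator output can be accompanied by a `key: value` sidecar file
#' capturing the full parameter set and seed, for reproducibility.
#'
#' @param config a `sim_config` (or any named list of scalars).
#' @param path output path (conventionally `<data file>.yaml`).
#' @return `path`, invisibly.
#' @export
write_sim_sidecar <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
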