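#' Quantification parameters for the phenotype metrics
#'
#' Fixed constants of the live-cell quantification: tracks with any
#' consecutive-frame jump above `jump_threshold` px are treated as tracking
#' errors and excluded from displacement-based metrics; the MSD slope is fit
#' over lags from `msd_min_lag` to `msd_max_lag` minutes; collectivity uses
#' the `n_neighbors_cosine` nearest cells; clustering uses the distance to
#' the `nn_order`-th nearest cell, normalized by the expected nearest-
#' neighbor distance under complete spatial randomness.
#'
#' @param jump_threshold px per frame interval (default 200).
#' @param msd_min_lag,msd_max_lag lag window in minutes (defaults 30 and 360).
#' @param n_neighbors_cosine neighbors per focal cell for the cosine metric.
#' @param nn_order neighbor rank for the observed distance (default 2, the
#'   second-nearest cell).
#' @param nn_expectation_order `"first"` normalizes by the CSR expectation of
#'   the FIRST nearest neighbor regardless of `nn_order` (the conventional
#'   reporting); `"matched"` normalizes by the CSR expectation of the same
#'   rank `nn_order`, which makes the index converge to 1 under CSR.
#' @param frame_interval minutes between frames (default 30).
#' @return object of class `metric_params`.
#' @export
metric_params <- function(jump_threshold = 200,
                          msd_min_lag = 30, msd_max_lag = 360,
                          n_neighbors_cosine = 10L,
                          nn_order = 2L,
                          nn_expectation_order = c("first", "matched"),
                          frame_interval = 30) {
  nn_expectation_order <- match.arg(nn_expectation_order)
  if (jump_threshold <= 0) stop("jump_threshold must be > 0")
  if (msd_min_lag > msd_max_lag) stop("msd_min_lag must be <= msd_max_lag")
  if (n_neighbors_cosine < 1) stop("n_neighbors_cosine must be >= 1")
  if (nn_order < 1) stop("nn_order must be >= 1")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  structure(list(jump_threshold = jump_threshold,
                 msd_min_lag = msd_min_lag, msd_max_lag = msd_max_lag,
                 n_neighbors_cosine = as.integer(n_neighbors_cosine),
                 nn_order = as.integer(nn_order),
                 nn_expectation_order = nn_expectation_order,
                 frame_interval = frame_interval),
            class = "metric_params")
}

#' Exclude tracks with tracking-error jumps
#'
#' A track is excluded entirely when ANY consecutive-frame displacement
#' strictly exceeds `params$jump_threshold` px (default 200 px per 30-min
#' interval): such jumps indicate a tracking error, not cell motion. Only
#' consecutive-frame pairs are screened; displacements spanning a gap are
#' not steps and are ignored here (and by the displacement-based metrics).
#'
#' @param trackset a [track_set()].
#' @param params a [metric_params()].
#' @return list with `trackset` (filtered copy) and `excluded` (character
#'   vector of excluded track ids).
#' @export
qc_filter_tracks <- function(trackset, params = metric_params()) {
  stopifnot(inherits(trackset, "track_set"))
  tr <- trackset$tracks  # already sorted by (track_id, frame)
  same <- tr$track_id[-1L] == tr$track_id[-nrow(tr)]
  consec <- same & (tr$frame[-1L] - tr$frame[-nrow(tr)] == 1L)
  step <- sqrt((tr$x[-1L] - tr$x[-nrow(tr)])^2 + (tr$y[-1L] - tr$y[-nrow(tr)])^2)
  bad_pair <- consec & step > params$jump_threshold
  excluded <- unique(tr$track_id[-1L][bad_pair])
  out <- trackset
  out$tracks <- tr[!(tr$track_id %in% excluded), , drop = FALSE]
  rownames(out$tracks) <- NULL
  list(trackset = out, excluded = excluded)
}

#' Per-frame cell count normalized to the T0 count
#'
#' Counts tracked cells per frame and divides by the count at frame 0, so
#' the series starts at 1 and its final value estimates net proliferation.
#'
#' @param trackset a [track_set()].
#' @return data.frame with columns `frame`, `n_cells`, `count_norm`.
#' @export
normalized_cell_count <- function(trackset) {
  stopifnot(inherits(trackset, "track_set"))
  tab <- table(trackset$tracks$frame)
  frames <- as.integer(names(tab))
  if (!0L %in% frames || tab[["0"]] < 1L) {
    stop("frame 0 is empty: cannot normalize to the T0 count")
  }
  data.frame(frame = frames, n_cells = as.integer(tab),
             count_norm = as.integer(tab) / tab[["0"]])
}

#' Expected k-th nearest-neighbor distance under CSR
#'
#' For a homogeneous Poisson process of intensity `rho` in the plane,
#' `E[r_k] = Gamma(k + 1/2) / (Gamma(k) * sqrt(rho * pi))`; for `k = 1` this
#' is the Clark-Evans expectation `1 / (2 * sqrt(rho))`.
#'
#' @param k neighbor rank (>= 1).
#' @param rho intensity, points per squared pixel.
#' @return expected distance in px.
#' @export
expected_nn_distance <- function(k, rho) {
  stopifnot(k >= 1, rho > 0)
  gamma(k + 0.5) / (gamma(k) * sqrt(rho * pi))
}

# distance from each point to its k-th nearest other point
.kth_nn_dist <- function(pts, k) {
  n <- nrow(pts)
  if (n < k + 1L) stop("need at least k + 1 points")
  D <- as.matrix(stats::dist(pts))
  # (k+1)-th smallest per row, counting the zero self-distance
  apply(D, 1L, function(r) sort.int(r, partial = k + 1L)[k + 1L])
}

#' Nearest-neighbor clustering index at one frame
#'
#' Mean observed distance from each cell to its `nn_order`-th nearest
#' neighbor, divided by the expected mean distance under a uniform-random
#' (Poisson/CSR) model at the same cell density. Values below 1 indicate
#' clustering. With `nn_expectation_order = "first"` the denominator is the
#' CSR expectation for the first nearest neighbor (so a CSR pattern scores
#' `E[r_k]/E[r_1]`, e.g. 1.5 for `nn_order = 2`); with `"matched"` the
#' denominator matches `nn_order` and CSR scores 1.
#'
#' @param positions two-column matrix (x, y) of cell centroids at one frame.
#' @param area field area in squared px.
#' @param params a [metric_params()].
#' @return the dimensionless index, or `NA` (with a warning) when fewer than
#'   `nn_order + 1` cells are present.
#' @export
nn_distance_index <- function(positions, area, params = metric_params()) {
  positions <- as.matrix(positions)
  k <- params$nn_order
  if (nrow(positions) < k + 1L) {
    warning(sprintf("need >= %d cells for nn_order %d; index undefined", k + 1L, k))
    return(NA_real_)
  }
  obs <- mean(.kth_nn_dist(positions, k))
  rho <- nrow(positions) / area
  k_exp <- if (params$nn_expectation_order == "matched") k else 1L
  obs / expected_nn_distance(k_exp, rho)
}

#' MSD slope (motility)
#'
#' Computes the mean squared displacement over lags from `msd_min_lag` to
#' `msd_max_lag` minutes in `frame_interval` steps, pooling time-averaged
#' (overlapping) displacements over all tracks, then fits ordinary least
#' squares of MSD against lag (with intercept, absorbing localization
#' noise) and returns the slope. For 2D Brownian motion the slope is `4D`.
#' Only displacement spans made of consecutive observed frames contribute;
#' spans crossing a gap are discarded rather than interpolated. Apply
#' [qc_filter_tracks()] first.
#'
#' @param trackset a [track_set()] (QC-filtered).
#' @param params a [metric_params()].
#' @return list with `slope` (px^2/min), `intercept`, and `msd` (data.frame
#'   `lag` minutes, `msd` px^2, `n_pairs`).
#' @export
msd_slope <- function(trackset, params = metric_params()) {
  stopifnot(inherits(trackset, "track_set"))
  dt <- trackset$frame_interval
  lags <- seq(from = max(1L, ceiling(params$msd_min_lag / dt)),
              to = floor(params$msd_max_lag / dt))
  if (length(lags) == 0L) stop("no usable lags in the configured window")
  tr <- trackset$tracks
  ssq <- numeric(length(lags)); cnt <- numeric(length(lags))
  for (trk in split(tr[, c("frame", "x", "y")], tr$track_id)) {
    o <- order(trk$frame)
    fr <- trk$frame[o]; xx <- trk$x[o]; yy <- trk$y[o]
    # maximal runs of consecutive frames
    run <- cumsum(c(1L, diff(fr) != 1L))
    for (r in split(seq_along(fr), run)) {
      m <- length(r)
      if (m < 2L) next
      for (li in seq_along(lags)) {
        L <- lags[li]
        if (m <= L) next
        i <- seq_len(m - L)
        d2 <- (xx[r[i + L]] - xx[r[i]])^2 + (yy[r[i + L]] - yy[r[i]])^2
        ssq[li] <- ssq[li] + sum(d2)
        cnt[li] <- cnt[li] + length(d2)
      }
    }
  }
  ok <- cnt > 0
  if (!any(ok)) stop("no usable lag pairs: tracks too short or all gapped")
  msd <- data.frame(lag = lags[ok] * dt, msd = ssq[ok] / cnt[ok],
                    n_pairs = cnt[ok])
  if (nrow(msd) == 1L) {
    # a single lag cannot anchor an intercept; slope through the origin
    slope <- msd$msd / msd$lag
    intercept <- 0
  } else {
    fit <- stats::lm.fit(cbind(1, msd$lag), msd$msd)
    intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  }
  list(slope = unname(slope), intercept = unname(intercept), msd = msd)
}

#' Velocity cosine-similarity collectivity
#'
#' For every consecutive frame pair and every focal cell with a nonzero
#' displacement, finds the `n_neighbors_cosine` nearest cells at the starting
#' frame (among cells that also have a nonzero displacement over the pair;
#' fewer when fewer are available, never padded) and computes the cosine
#' similarity between the focal and each neighbor displacement. Returns the
#' grand mean over all (focal, neighbor, frame) triples: near 0 for
#' independent motion, near 1 for coordinated collective drift. Apply
#' [qc_filter_tracks()] first.
#'
#' @param trackset a [track_set()] (QC-filtered).
#' @param params a [metric_params()].
#' @return list with `mean_cosine`, `n_triples`, and `zero_excluded` (count
#'   of zero-length displacement vectors excluded). `mean_cosine` is `NA`
#'   with a warning when no valid triple exists.
#' @export
collectivity_cosine <- function(trackset, params = metric_params()) {
  stopifnot(inherits(trackset, "track_set"))
  tr <- trackset$tracks
  k <- params$n_neighbors_cosine
  frames <- sort(unique(tr$frame))
  total <- 0; n_tri <- 0L; zero_excluded <- 0L
  by_frame <- split(tr[, c("track_id", "x", "y")], tr$frame)
  for (fi in seq_len(length(frames) - 1L)) {
    f0 <- as.character(frames[fi]); f1 <- as.character(frames[fi] + 1L)
    a <- by_frame[[f0]]; b <- by_frame[[f1]]
    if (is.null(a) || is.null(b)) next
    common <- intersect(a$track_id, b$track_id)
    if (length(common) < 2L) next
    ia <- match(common, a$track_id); ib <- match(common, b$track_id)
    vx <- b$x[ib] - a$x[ia]; vy <- b$y[ib] - a$y[ia]
    nrm <- sqrt(vx^2 + vy^2)
    nz <- nrm > 0
    zero_excluded <- zero_excluded + sum(!nz)
    if (sum(nz) < 2L) next
    px <- a$x[ia][nz]; py <- a$y[ia][nz]
    ux <- vx[nz] / nrm[nz]; uy <- vy[nz] / nrm[nz]
    n <- length(ux)
    U <- cbind(ux, uy)
    cosmat <- U %*% t(U)
    D <- as.matrix(stats::dist(cbind(px, py)))
    kk <- min(k, n - 1L)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(kk + 1L)]
      total <- total + sum(cosmat[i, nb])
      n_tri <- n_tri + kk
    }
  }
  if (n_tri == 0L) {
    warning("no valid displacement pairs: cosine collectivity undefined")
    return(list(mean_cosine = NA_real_, n_triples = 0L,
                zero_excluded = zero_excluded))
  }
  list(mean_cosine = total / n_tri, n_triples = n_tri,
       zero_excluded = zero_excluded)
}

#' Compute the four phenotype metrics for a collection of track sets
#'
#' One row per field: normalized cell count at the final frame, MSD slope
#' and cosine collectivity on jump-filtered tracks, and the nearest-neighbor
#' index both time-averaged over frames and at the final frame (position-
#' based metrics use all tracks; the jump filter applies only to the
#' displacement-based metrics). Per-metric failures propagate as `NA`
#' without aborting the table.
#'
#' @param tracksets list of [track_set()] objects.
#' @param params a [metric_params()].
#' @return data.frame with one row per track set: identifiers, the four
#'   metrics (`cell_count_norm`, `msd_slope`, `nn_index`, `nn_index_final`,
#'   `cosine_similarity`), and usage counts (`n_cells_t0`, `n_tracks_used`,
#'   `n_tracks_excluded`).
#' @export
compute_phenotype_table <- function(tracksets, params = metric_params()) {
  cols <- c("field_id", "condition", "knockdown", "replicate",
            "cell_count_norm", "msd_slope", "nn_index", "nn_index_final",
            "cosine_similarity", "n_cells_t0", "n_tracks_used",
            "n_tracks_excluded")
  if (length(tracksets) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  rows <- lapply(tracksets, function(ts) {
    stopifnot(inherits(ts, "track_set"))
    area <- ts$field_width * ts$field_height
    counts <- tryCatch(normalized_cell_count(ts), error = function(e) NULL)
    ccn <- if (is.null(counts)) NA_real_ else counts$count_norm[nrow(counts)]
    n0 <- if (is.null(counts)) NA_integer_ else counts$n_cells[counts$frame == 0L]

    qc <- qc_filter_tracks(ts, params)
    slope <- tryCatch(msd_slope(qc$trackset, params)$slope,
                      error = function(e) NA_real_)
    cosr <- tryCatch(suppressWarnings(collectivity_cosine(qc$trackset, params)),
                     error = function(e) list(mean_cosine = NA_real_))

    by_frame <- split(ts$tracks[, c("x", "y")], ts$tracks$frame)
    nn_series <- suppressWarnings(vapply(by_frame, function(p) {
      nn_distance_index(as.matrix(p), area, params)
    }, numeric(1)))
    nn_avg <- if (all(is.na(nn_series))) NA_real_ else mean(nn_series, na.rm = TRUE)
    nn_final <- nn_series[length(nn_series)]

    data.frame(field_id = ts$field_id, condition = ts$condition,
               knockdown = ts$knockdown, replicate = ts$replicate,
               cell_count_norm = ccn, msd_slope = slope,
               nn_index = nn_avg, nn_index_final = unname(nn_final),
               cosine_similarity = cosr$mean_cosine,
               n_cells_t0 = n0, n_tracks_used = n_tracks(qc$trackset),
               n_tracks_excluded = length(qc$excluded),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a phenotype table with an embedded parameters header
#'
#' Delimited text, one row per field x condition x replicate, preceded by
#' '#'-prefixed lines recording every [metric_params()] field.
#'
#' @param phenotypes data.frame from [compute_phenotype_table()].
#' @param path output path.
#' @param params the [metric_params()] used to compute the table.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path, params = metric_params()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(params),
                     vapply(params, as.character, character(1))), con)
  utils::write.csv(phenotypes, con, row.names = FALSE)
  invisible(path)
}
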