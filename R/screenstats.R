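#' Screen design: control labels and significance level
#'
#' @param control_condition treatment serving as control in ligand
#'   comparisons (default `"EGF"`).
#' @param control_knockdown control knockdown for screen comparisons
#'   (default the scrambled siRNA, `"siSCR"`).
#' @param alpha significance level (default 0.05).
#' @return object of class `screen_design`.
#' @export
screen_design <- function(control_condition = "EGF",
                          control_knockdown = "siSCR", alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(control_condition = control_condition,
                 control_knockdown = control_knockdown, alpha = alpha),
            class = "screen_design")
}

#' Normalize phenotype scores to the control knockdown
#'
#' Divides each score by the mean control-knockdown score within its
#' treatment x metric stratum, so control rows normalize to mean 1 and
#' every other score reads as a fold change relative to the scrambled
#' control under the same ligand.
#'
#' @param phenotypes long data.frame with columns `knockdown`, `treatment`,
#'   `metric`, `value` (extra columns are preserved).
#' @param design a [screen_design()].
#' @return the input with an added `norm_value` column.
#' @export
normalize_to_control <- function(phenotypes, design = screen_design()) {
  req <- c("knockdown", "treatment", "metric", "value")
  stopifnot(all(req %in% names(phenotypes)))
  key <- paste(phenotypes$treatment, phenotypes$metric, sep = "\r")
  ctrl <- phenotypes$knockdown == design$control_knockdown
  have_ctrl <- unique(key[ctrl])
  missing_strata <- setdiff(unique(key), have_ctrl)
  if (length(missing_strata) > 0L) {
    stop("no control rows ('", design$control_knockdown, "') for stratum: ",
         paste(gsub("\r", " x ", missing_strata), collapse = "; "))
  }
  ctrl_mean <- tapply(phenotypes$value[ctrl], key[ctrl], mean)
  phenotypes$norm_value <- phenotypes$value / as.numeric(ctrl_mean[key])
  phenotypes
}

#' Dunnett many-to-one comparisons against a control
#'
#' Compares every group mean with the control mean under the family-wise
#' adjustment of Dunnett's procedure (multivariate-t critical values via a
#' single-step \pkg{multcomp} contrast on a one-way fit), two-sided.
#' Both the adjusted and the model-based unadjusted p-values are returned;
#' the adjustment can only increase p, so `p_adjusted >= p_unadjusted`.
#'
#' @param values numeric vector of scores.
#' @param group factor/character of the same length; must include the control.
#' @param control control group label (e.g. `"EGF"`).
#' @param metric optional metric label carried into the result.
#' @return data.frame with one row per non-control group: `group`, `control`,
#'   `metric`, `estimate` (group minus control), `p_unadjusted`,
#'   `p_adjusted`, `method`, `adjusted`.
#' @export
dunnett_vs_control <- function(values, group, control, metric = NA_character_) {
  stopifnot(length(values) == length(group))
  group <- as.character(group)
  if (!control %in% group) stop("control group '", control, "' absent from data")
  tab <- table(group)
  if (any(tab < 2L)) {
    stop("every group needs >= 2 replicates for a variance estimate; ",
         "offending group(s): ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  if (length(tab) < 2L) stop("need at least one non-control group")
  g <- stats::relevel(factor(group), ref = control)
  fit <- stats::aov(values ~ g, data = data.frame(values = values, g = g))
  glht_fit <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  adj <- summary(glht_fit, test = multcomp::adjusted("single-step"))
  una <- summary(glht_fit, test = multcomp::univariate())
  res <- data.frame(
    group = sub(" - .*$", "", names(adj$test$coefficients)),
    control = control, metric = metric,
    estimate = as.numeric(adj$test$coefficients),
    p_unadjusted = as.numeric(una$test$pvalues),
    p_adjusted = pmax(as.numeric(adj$test$pvalues),
                      as.numeric(una$test$pvalues)),
    method = "Dunnett", adjusted = TRUE, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Pairwise Student's t-tests of each knockdown against the control
#'
#' Two-sided two-sample t-test (equal-variance by default, Welch behind the
#' `var_equal` flag) of every knockdown against the control knockdown within
#' each treatment x metric stratum. P-values are intentionally unadjusted
#' and flagged as such.
#'
#' @param phenotypes long data.frame with `knockdown`, `treatment`, `metric`
#'   and a score column.
#' @param design a [screen_design()].
#' @param value column holding the score (default `"norm_value"`, falling
#'   back to `"value"`).
#' @param var_equal pooled-variance Student t when `TRUE` (default), Welch
#'   when `FALSE`.
#' @return data.frame: `treatment`, `metric`, `knockdown`, `control`,
#'   `estimate` (knockdown mean minus control mean), `t`, `df`, `p_value`,
#'   `method`, `adjusted` (always `FALSE`).
#' @export
ttest_vs_control <- function(phenotypes, design = screen_design(),
                             value = NULL, var_equal = TRUE) {
  if (is.null(value)) {
    value <- if ("norm_value" %in% names(phenotypes)) "norm_value" else "value"
  }
  stopifnot(all(c("knockdown", "treatment", "metric", value) %in% names(phenotypes)))
  ctrl_kd <- design$control_knockdown
  out <- list()
  for (tt in unique(phenotypes$treatment)) {
    for (mm in unique(phenotypes$metric)) {
      sub <- phenotypes[phenotypes$treatment == tt & phenotypes$metric == mm, ]
      ctrl_vals <- sub[[value]][sub$knockdown == ctrl_kd]
      if (length(ctrl_vals) < 2L) {
        stop("control knockdown '", ctrl_kd, "' has < 2 replicates in stratum ",
             tt, " x ", mm)
      }
      for (kd in setdiff(unique(sub$knockdown), ctrl_kd)) {
        v <- sub[[value]][sub$knockdown == kd]
        if (length(v) < 2L) stop("knockdown '", kd, "' has < 2 replicates")
        pooled_sd <- sqrt(((length(v) - 1) * stats::var(v) +
                           (length(ctrl_vals) - 1) * stats::var(ctrl_vals)) /
                          (length(v) + length(ctrl_vals) - 2))
        if (var_equal && pooled_sd == 0 && mean(v) != mean(ctrl_vals)) {
          warning("zero pooled variance with unequal means for '", kd,
                  "' in ", tt, " x ", mm, "; p reported as 0")
          tst <- list(statistic = c(t = sign(mean(v) - mean(ctrl_vals)) * Inf),
                      parameter = c(df = length(v) + length(ctrl_vals) - 2),
                      p.value = 0)
        } else if (pooled_sd == 0 && mean(v) == mean(ctrl_vals)) {
          tst <- list(statistic = c(t = 0),
                      parameter = c(df = length(v) + length(ctrl_vals) - 2),
                      p.value = 1)
        } else {
          tst <- stats::t.test(v, ctrl_vals, var.equal = var_equal)
        }
        out[[length(out) + 1L]] <- data.frame(
          treatment = tt, metric = mm, knockdown = kd, control = ctrl_kd,
          estimate = mean(v) - mean(ctrl_vals),
          t = unname(tst$statistic), df = unname(tst$parameter),
          p_value = tst$p.value,
          method = if (var_equal) "Student t" else "Welch t",
          adjusted = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-knockdown phenotypic effect sizes
#'
#' Aggregates a normalized phenotype table into one effect magnitude per
#' knockdown x treatment: the deviation of the replicate-mean normalized
#' metric vector from 1, collapsed over metrics by the Euclidean norm
#' (default) or by the maximum absolute deviation.
#'
#' @param phenotypes normalized table (see [normalize_to_control()]) with
#'   `knockdown`, `treatment`, `metric`, `norm_value`.
#' @param method `"l2"` (Euclidean norm over metrics) or `"maxabs"`.
#' @return data.frame `knockdown`, `treatment`, `effect`.
#' @export
knockdown_effect_sizes <- function(phenotypes, method = c("l2", "maxabs")) {
  method <- match.arg(method)
  stopifnot(all(c("knockdown", "treatment", "metric", "norm_value") %in%
                names(phenotypes)))
  agg <- stats::aggregate(norm_value ~ knockdown + treatment + metric,
                          data = phenotypes, FUN = mean)
  dev <- abs(agg$norm_value - 1)
  eff <- stats::aggregate(
    dev, by = list(knockdown = agg$knockdown, treatment = agg$treatment),
    FUN = if (method == "l2") function(d) sqrt(sum(d^2)) else max)
  names(eff)[3] <- "effect"
  eff
}

#' Exact binomial test for OSM-vs-IFNG effect enrichment
#'
#' For each knockdown, forms the ratio of its phenotypic effect magnitude
#' under OSM to that under IFNG; a ratio above 1 counts as a success. Tests
#' whether successes exceed the 50% expected when neither ligand dominates,
#' with a one-sided exact binomial test (`p0 = 0.5`).
#'
#' @param effect_osm named numeric vector of effect magnitudes under OSM.
#' @param effect_ifng named numeric vector under IFNG (matched by name when
#'   names are present, by position otherwise).
#' @param p0 null success probability (default 0.5).
#' @return list: `ratios` (named), `n_success`, `n`, `p_value` (one-sided,
#'   greater), `dropped` (knockdowns with zero IFNG effect, excluded with a
#'   warning).
#' @export
osm_effect_enrichment <- function(effect_osm, effect_ifng, p0 = 0.5) {
  if (!is.null(names(effect_osm)) && !is.null(names(effect_ifng))) {
    common <- intersect(names(effect_osm), names(effect_ifng))
    effect_osm <- effect_osm[common]; effect_ifng <- effect_ifng[common]
  }
  stopifnot(length(effect_osm) == length(effect_ifng), length(effect_osm) >= 1L)
  zero <- abs(effect_ifng) == 0
  dropped <- if (!is.null(names(effect_ifng))) names(effect_ifng)[zero] else which(zero)
  if (any(zero)) {
    warning(length(dropped), " knockdown(s) with zero IFNG effect dropped: ",
            "ratio undefined")
  }
  ratios <- abs(effect_osm[!zero]) / abs(effect_ifng[!zero])
  n <- length(ratios)
  if (n == 0L) stop("no knockdown with a defined OSM/IFNG effect ratio")
  k <- sum(ratios > 1)
  bt <- stats::binom.test(k, n, p = p0, alternative = "greater")
  list(ratios = ratios, n_success = k, n = n, p_value = bt$p.value,
       dropped = dropped)
}

#' Principal component analysis of phenotype scores
#'
#' PCA on centered, unit-scaled phenotype metrics. Rows are knockdown x
#' treatment replicate means by default (replicate-level rows behind
#' `by_replicate`); missing entries are imputed by the column mean with a
#' log entry. Each loading vector is oriented so its largest-magnitude entry
#' is positive, removing run-to-run sign ambiguity. Per-treatment mean
#' scores per component summarize which ligand condition dominates an axis.
#'
#' @param phenotypes normalized long table with `knockdown`, `treatment`,
#'   `metric`, `norm_value` (and `replicate` when `by_replicate = TRUE`).
#' @param by_replicate keep replicate-level rows instead of means.
#' @return object of class `phenotype_pca`: list with `loadings` (metric x
#'   PC), `scores` (row x PC, with `knockdown`/`treatment` columns),
#'   `treatment_weights` (treatment x PC mean scores),
#'   `variance_explained`, `n_imputed`.
#' @export
phenotype_pca <- function(phenotypes, by_replicate = FALSE) {
  stopifnot(all(c("knockdown", "treatment", "metric", "norm_value") %in%
                names(phenotypes)))
  if (by_replicate) {
    stopifnot("replicate" %in% names(phenotypes))
    fm <- norm_value ~ knockdown + treatment + replicate + metric
  } else {
    fm <- norm_value ~ knockdown + treatment + metric
  }
  agg <- stats::aggregate(fm, data = phenotypes, FUN = mean, na.action = stats::na.pass)
  wide <- stats::reshape(agg, direction = "wide", timevar = "metric",
                         idvar = setdiff(names(agg), c("metric", "norm_value")))
  metric_cols <- grep("^norm_value\\.", names(wide))
  mat <- as.matrix(wide[, metric_cols, drop = FALSE])
  colnames(mat) <- sub("^norm_value\\.", "", names(wide)[metric_cols])
  if (nrow(mat) < 2L) stop("need at least 2 rows for PCA")
  n_imputed <- sum(is.na(mat))
  if (n_imputed > 0L) {
    for (j in seq_len(ncol(mat))) {
      mis <- is.na(mat[, j])
      mat[mis, j] <- mean(mat[, j], na.rm = TRUE)
    }
  }
  keep <- apply(mat, 2L, stats::sd) > 0
  if (!all(keep)) {
    warning("constant metric column(s) dropped from PCA: ",
            paste(colnames(mat)[!keep], collapse = ", "))
    mat <- mat[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- data.frame(wide[, setdiff(seq_along(wide), metric_cols), drop = FALSE],
                       pc$x, check.names = FALSE)
  tw <- do.call(rbind, lapply(split(as.data.frame(pc$x), scores$treatment), colMeans))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, scores = scores,
                 treatment_weights = tw,
                 variance_explained = ve, n_imputed = n_imputed),
            class = "phenotype_pca")
}

#' @export
print.phenotype_pca <- function(x, ...) {
  cat("<phenotype_pca>\n variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "), "\n")
  cat(" loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}
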