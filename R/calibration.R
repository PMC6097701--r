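#' Normalize steady-state cargo levels to a reference motif
#'
#' Reporter-cargo steady-state measurements (e.g. ng cargo per mg total
#' protein) are comparable only within an experiment, so each experiment
#' group is divided by the mean level of its reference tripeptide (the
#' wild-type motif "IPV" by default). Reference rows normalize to 1 by
#' construction.
#'
#' @param data data.frame with columns `experiment`, `tripeptide`, `value`
#'   (positive raw levels).
#' @param reference reference tripeptide present in every experiment group.
#' @return The input with an added `normalized` column.
#' @examples
#' d <- data.frame(experiment = 1, tripeptide = c("IPV", "EET"),
#'                 value = c(10, 80))
#' normalizeToReference(d)$normalized
#' @export
normalizeToReference <- function(data, reference = "IPV") {
  need <- c("experiment", "tripeptide", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns experiment, tripeptide, value")
  if (any(is.na(data$value)) || any(data$value <= 0))
    stop("values must be positive")
  data$tripeptide <- toupper(data$tripeptide)
  refmean <- tapply(data$value[data$tripeptide == reference],
                    data$experiment[data$tripeptide == reference], mean)
  groups <- unique(as.character(data$experiment))
  missing_ref <- setdiff(groups, names(refmean))
  if (length(missing_ref))
    stop("experiment group(s) without reference '", reference, "': ",
         paste(missing_ref, collapse = ", "))
  data$normalized <- as.numeric(data$value /
                                  refmean[as.character(data$experiment)])
  data
}

#' Aggregate normalized levels across replicates
#'
#' Per-tripeptide mean of replicate normalized values with standard error
#' of the mean (SEM; NA for single replicates).
#'
#' @param data output of [normalizeToReference()].
#' @return data.frame with columns `tripeptide`, `mean_level`, `sem`, `n`.
#' @export
aggregateSteadyState <- function(data) {
  if (!all(c("tripeptide", "normalized") %in% names(data)))
    stop("data must have columns tripeptide and normalized (run normalizeToReference first)")
  sp <- split(data$normalized, data$tripeptide)
  out <- data.frame(
    tripeptide = names(sp),
    mean_level = vapply(sp, mean, numeric(1L)),
    sem = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1L)),
    n = lengths(sp),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

## Weighted pool-adjacent-violators for a non-DECREASING fit of y on the
## (already sorted) x order. Ties in x must be pre-pooled by the caller.
.pavNonDecreasing <- function(y, w) {
  n <- length(y)
  ghat <- y; wt <- w
  ## block representation: level[i], weight[i], size[i]
  lvl <- numeric(n); bw <- numeric(n); sz <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    lvl[k] <- y[i]; bw[k] <- w[i]; sz[k] <- 1L
    while (k > 1L && lvl[k - 1L] > lvl[k]) {
      lvl[k - 1L] <- (bw[k - 1L] * lvl[k - 1L] + bw[k] * lvl[k]) /
        (bw[k - 1L] + bw[k])
      bw[k - 1L] <- bw[k - 1L] + bw[k]
      sz[k - 1L] <- sz[k - 1L] + sz[k]
      k <- k - 1L
    }
  }
  rep(lvl[seq_len(k)], times = sz[seq_len(k)])
}

#' CalibrationFit: monotone mapping from motif score to steady-state level
#'
#' Result of [fitMonotone()]: a least-squares monotone non-increasing step
#' function relating the additive motif score to the mean normalized
#' steady-state level (higher score, i.e. stronger predicted receptor
#' affinity, maps to a lower level), together with Spearman rank
#' correlation and per-tripeptide residuals.
#'
#' @slot table DataFrame with per-tripeptide `tripeptide`, `score`,
#'   `mean_level`, `n`, `fitted`, `residual`.
#' @slot rho Spearman correlation between score and mean level.
#' @slot stepfun list with sorted unique `score` and fitted `level` used by
#'   [predictCalibration()].
#' @export
setClass("CalibrationFit",
  representation(table = "DataFrame", rho = "numeric", stepfun = "list"))

setMethod("show", "CalibrationFit", function(object) {
  cat("CalibrationFit:", nrow(object@table), "tripeptides,",
      length(object@stepfun$score), "distinct scores\n")
  cat("  Spearman rho(score, level):", format(object@rho, digits = 3), "\n")
  cat("  residual SD:", format(stats::sd(object@table$residual), digits = 3), "\n")
  invisible(object)
})

#' Fit a monotone calibration of steady-state level on motif score
#'
#' Isotonic (pool-adjacent-violators) least-squares regression of mean
#' normalized level on additive motif score, constrained non-increasing:
#' stronger motifs deplete the ER pool faster and sit at lower steady
#' state. Replicates are first aggregated per tripeptide
#' ([aggregateSteadyState()]); tripeptides with tied scores are pooled into
#' a weighted observation (weights = number of tripeptides x replicates).
#'
#' @param data a normalized steady-state table (output of
#'   [normalizeToReference()], or an already aggregated frame with columns
#'   `tripeptide`, `mean_level`).
#' @param table a [PositionWeightTable-class] used to score the tripeptides.
#' @return A [CalibrationFit-class].
#' @examples
#' d <- genSteadyStateTable(c("IPV", "APV", "ITV", "EET"), seed = 1)
#' fitMonotone(normalizeToReference(d))
#' @export
fitMonotone <- function(data, table = defaultWeightTable()) {
  agg <- if (all(c("tripeptide", "mean_level") %in% names(data)) &&
             !"normalized" %in% names(data)) {
    data
  } else {
    aggregateSteadyState(data)
  }
  if (!"n" %in% names(agg)) agg$n <- 1L
  agg$score <- unname(scoreTripeptide(agg$tripeptide, table))
  if (length(unique(agg$score)) < 3L)
    stop("degenerate fit: need at least 3 distinct scores")
  ## pool score ties, weight by replicate counts
  o <- order(agg$score)
  agg <- agg[o, , drop = FALSE]
  us <- sort(unique(agg$score))
  ybar <- vapply(us, function(s) {
    sel <- agg$score == s
    stats::weighted.mean(agg$mean_level[sel], agg$n[sel])
  }, numeric(1L))
  wsum <- vapply(us, function(s) sum(agg$n[agg$score == s]), numeric(1L))
  ## non-increasing in score == non-decreasing in -score order;
  ## fit on reversed score order
  fit_rev <- .pavNonDecreasing(rev(ybar), rev(wsum))
  fitted_us <- rev(fit_rev)
  fitted <- fitted_us[match(agg$score, us)]
  rho <- stats::cor(agg$score, agg$mean_level, method = "spearman")
  tab <- DataFrame(tripeptide = agg$tripeptide, score = agg$score,
                   mean_level = agg$mean_level, n = agg$n,
                   fitted = fitted, residual = agg$mean_level - fitted)
  new("CalibrationFit", table = tab, rho = rho,
      stepfun = list(score = us, level = fitted_us))
}

#' Predict steady-state level from motif score
#'
#' Evaluates the fitted monotone step function at new scores. Values
#' between fitted knots take the level of the nearest knot at or below the
#' query (scores beyond the fitted range are clamped to the end levels).
#'
#' @param fit a [CalibrationFit-class].
#' @param scores numeric scores (or a character vector of tripeptides,
#'   which are scored with the default table).
#' @return Numeric predicted normalized levels.
#' @export
predictCalibration <- function(fit, scores) {
  stopifnot(is(fit, "CalibrationFit"))
  if (is.character(scores)) scores <- unname(scoreTripeptide(scores))
  idx <- findInterval(scores, fit@stepfun$score)
  idx[idx < 1L] <- 1L
  fit@stepfun$level[idx]
}

#' Rank-concordance diagnostics for a calibration fit
#'
#' Per-tripeptide residuals with outliers flagged; systematic outliers are
#' candidates for per-tripeptide exception rules (tripeptides whose
#' measured level departs from the additive model, e.g. a consensus motif
#' sitting well above its predicted level).
#'
#' @param fit a [CalibrationFit-class].
#' @param flagThreshold absolute standardized-residual cutoff for flagging
#'   (default 3; residuals are scaled by their median absolute deviation,
#'   with no flags when residual spread is numerically zero).
#' @return data.frame with `tripeptide`, `score`, `mean_level`, `fitted`,
#'   `residual`, `standardized`, `flagged`.
#' @export
concordanceReport <- function(fit, flagThreshold = 3) {
  stopifnot(is(fit, "CalibrationFit"), flagThreshold > 0)
  tab <- as.data.frame(fit@table)
  scale <- stats::mad(tab$residual, center = 0)
  if (!is.finite(scale) || scale < 1e-12) scale <- stats::sd(tab$residual)
  if (!is.finite(scale) || scale < 1e-12) {
    tab$standardized <- 0
    tab$flagged <- FALSE
    return(tab)
  }
  tab$standardized <- tab$residual / scale
  tab$flagged <- abs(tab$standardized) > flagThreshold
  tab
}
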