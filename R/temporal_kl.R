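# Seasonal curve analysis: monthly series of per-sample CUP statistics,
# loess smoothing with leave-one-out span selection, normalisation to
# probability curves, Kullback-Leibler divergence between annual courses,
# and delta-threshold peak detection on linearly detrended series.

#' Monthly mean series of a per-sample statistic
#'
#' Pools the replicate sites of each management system and averages the
#' chosen per-sample statistic per month, for one matrix and distance
#' class. The result is the raw material for loess smoothing and system
#' comparison.
#'
#' @param table A [residue_table()].
#' @param matrix `"soil"` or `"vegetation"`.
#' @param distance_class One of [cup_distance_classes()].
#' @param statistic Column of [summarize_samples()] to average, default
#'   the number of detected CUPs.
#' @return Tibble with columns `system`, `month_index`, `value`, ordered by
#'   month within system.
#' @export
monthly_series <- function(table, matrix, distance_class = "in_field",
                           statistic = "n_cups_detected") {
  s <- summarize_samples(table)
  if (!statistic %in% names(s)) {
    stop("unknown statistic: ", statistic, call. = FALSE)
  }
  s <- s[s$matrix == matrix & s$distance_class == distance_class, ]
  if (nrow(s) == 0) stop("no samples for requested subset", call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(s, .data$system, .data$month_index),
    value = mean(.data[[statistic]]), .groups = "drop")
  dplyr::arrange(out, .data$system, .data$month_index)
}

check_series <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("month_index", "value") %in% names(series)))
  if (any(!is.finite(series$value))) stop("series values must be finite",
                                          call. = FALSE)
  series[order(series$month_index), ]
}

loess_window <- function(span, n) floor(span * n)

#' Loess smooth of a monthly series
#'
#' Locally weighted polynomial regression (tricube weights, default local
#' quadratic, no robustness iterations) evaluated on the series' own month
#' grid. Fitting uses exact local regression (`surface = "direct"`), which
#' also permits the extrapolation needed by leave-one-out validation at the
#' grid ends.
#'
#' @param series Data frame with `month_index` and `value` (>= 4 points).
#' @param span Fraction of points in the local window, in `(0, 1]`; the
#'   window must contain at least `degree + 1` points.
#' @param degree Local polynomial degree, 1 or 2 (default 2).
#' @return A list of class `smoothed_series`: `grid`, `fitted`, `span`,
#'   `degree`, `cv_score` (`NA` unless set by [select_span_cv()]).
#' @export
fit_loess <- function(series, span = 0.75, degree = 2) {
  series <- check_series(series)
  n <- nrow(series)
  if (n < 4) stop("need at least 4 points for a loess smooth", call. = FALSE)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  if (loess_window(span, n) < degree + 1) {
    stop(sprintf("span %.2f gives a window of %d points; need >= %d",
                 span, loess_window(span, n), degree + 1), call. = FALSE)
  }
  fit <- stats::loess(value ~ month_index, data = series, span = span,
                      degree = degree, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  structure(list(grid = series$month_index,
                 fitted = as.numeric(stats::fitted(fit)),
                 span = span, degree = degree, cv_score = NA_real_),
            class = "smoothed_series")
}

loo_cv_score <- function(series, span, degree) {
  n <- nrow(series)
  err <- vapply(seq_len(n), function(i) {
    train <- series[-i, ]
    fit <- try(suppressWarnings(
      stats::loess(value ~ month_index, data = train, span = span,
                   degree = degree, family = "gaussian",
                   control = stats::loess.control(surface = "direct"))),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(NA_real_)
    pred <- try(suppressWarnings(
      stats::predict(fit, newdata = series[i, , drop = FALSE])),
      silent = TRUE)
    if (inherits(pred, "try-error") || !is.finite(pred)) return(NA_real_)
    (pred - series$value[i])^2
  }, numeric(1))
  if (anyNA(err)) NA_real_ else mean(err)
}

#' Select a loess span by leave-one-out cross-validation
#'
#' Scores every candidate span by the mean squared leave-one-out prediction
#' error and returns the minimiser; ties (within a relative tolerance of
#' 1e-9) are broken towards the largest, smoothest span. Candidates whose
#' window is infeasible on the reduced series are dropped.
#'
#' @inheritParams fit_loess
#' @param candidate_spans Numeric vector of at least two candidates.
#' @return The selected span, with the per-candidate scores attached as
#'   attribute `"cv"`.
#' @export
select_span_cv <- function(series, candidate_spans = seq(0.3, 1, by = 0.1),
                           degree = 2) {
  series <- check_series(series)
  if (length(candidate_spans) < 2) {
    stop("need at least two candidate spans", call. = FALSE)
  }
  n <- nrow(series)
  scores <- vapply(candidate_spans, function(sp) {
    if (sp <= 0 || sp > 1 || loess_window(sp, n - 1) < degree + 1) {
      return(NA_real_)
    }
    loo_cv_score(series, sp, degree)
  }, numeric(1))
  if (all(is.na(scores))) stop("no feasible candidate span", call. = FALSE)
  best <- min(scores, na.rm = TRUE)
  tol <- best * 1e-9 + 1e-12
  chosen <- max(candidate_spans[!is.na(scores) & scores <= best + tol])
  attr(chosen, "cv") <- tibble::tibble(span = candidate_spans,
                                       cv_score = scores)
  chosen
}

#' Remove the linear annual trend from a monthly series
#'
#' Returns the residuals of an ordinary least squares regression of the
#' value on the month index, isolating shorter-term fluctuations for peak
#' detection. Residuals sum to zero up to rounding.
#'
#' @param series Data frame with `month_index` and `value` (>= 3 points,
#'   at least two distinct months).
#' @return The series with `value` replaced by the OLS residuals.
#' @export
detrend_linear <- function(series) {
  series <- check_series(series)
  if (nrow(series) < 3) stop("need at least 3 points to detrend",
                             call. = FALSE)
  if (length(unique(series$month_index)) < 2) {
    stop("degenerate month grid", call. = FALSE)
  }
  series$value <- as.numeric(residuals(lm(value ~ month_index,
                                          data = series)))
  series
}

#' Delta-threshold peak detection
#'
#' Single forward pass tracking running maximum and minimum candidates: an
#' extremum is emitted once the series has moved more than `delta` away
#' from the current candidate, after which the search direction flips, so
#' emitted kinds alternate. The pass starts searching for a maximum, so the
#' first emission's kind is set by the first crossing: a drop of more than
#' `delta` below the running maximum emits that maximum. A trailing
#' candidate that is never confirmed by a crossing is not emitted.
#'
#' @param values Numeric sequence (typically detrended monthly means).
#' @param delta Positive threshold in the units of `values`; default 0.3.
#' @param positions Positions reported for the peaks; defaults to 0-based
#'   indices matching the month grid.
#' @return Tibble with columns `position`, `value`, `kind`
#'   (`"maximum"`/`"minimum"`), with `delta` attached as an attribute.
#' @export
detect_peaks <- function(values, delta = 0.3,
                         positions = seq_along(values) - 1L) {
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  stopifnot(length(positions) == length(values))
  pos <- numeric(0); val <- numeric(0); kind <- character(0)
  mx <- -Inf; mn <- Inf; mxpos <- NA; mnpos <- NA
  look_max <- TRUE
  for (i in seq_along(values)) {
    v <- values[i]
    if (v > mx) { mx <- v; mxpos <- positions[i] }
    if (v < mn) { mn <- v; mnpos <- positions[i] }
    if (look_max) {
      if (v < mx - delta) {
        pos <- c(pos, mxpos); val <- c(val, mx); kind <- c(kind, "maximum")
        mn <- v; mnpos <- positions[i]
        look_max <- FALSE
      }
    } else {
      if (v > mn + delta) {
        pos <- c(pos, mnpos); val <- c(val, mn); kind <- c(kind, "minimum")
        mx <- v; mxpos <- positions[i]
        look_max <- TRUE
      }
    }
  }
  out <- tibble::tibble(position = pos, value = val, kind = kind)
  attr(out, "delta") <- delta
  out
}

#' Normalise a smoothed curve to a probability distribution
#'
#' Values are floored at `epsilon` (clipping any negative loess
#' excursions), then divided by their sum, yielding a strictly positive
#' distribution over the month grid suitable for Kullback-Leibler
#' divergence.
#'
#' @param curve A `smoothed_series` from [fit_loess()] or a numeric vector.
#' @param epsilon Positive floor, default `1e-6`.
#' @return Numeric probability vector summing to 1.
#' @export
to_probability <- function(curve, epsilon = 1e-6) {
  x <- if (inherits(curve, "smoothed_series")) curve$fitted else as.numeric(curve)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (all(x <= 0)) stop("all values are <= 0; cannot normalise", call. = FALSE)
  p <- pmax(x, epsilon)
  p / sum(p)
}

#' Kullback-Leibler divergence between two annual curves
#'
#' `KL(P || Q) = sum_i P_i * log2(P_i / Q_i)`, in bits. Asymmetric,
#' non-negative, and zero iff `P == Q`.
#'
#' @param p,q Probability vectors on the same grid (see
#'   [to_probability()]).
#' @return Divergence in bits.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) stop("P and Q are on different grids",
                                   call. = FALSE)
  for (v in list(p, q)) {
    if (any(v <= 0) || abs(sum(v) - 1) > 1e-6) {
      stop("inputs must be strictly positive and sum to 1", call. = FALSE)
    }
  }
  sum(p * log2(p / q))
}

#' Pairwise KL divergence of smoothed annual courses across systems
#'
#' Builds the monthly series of each management system for one matrix and
#' distance class, loess-smooths each (with a shared fixed span or
#' per-system leave-one-out selection), normalises to probability curves
#' and returns the full asymmetric matrix of pairwise divergences.
#'
#' @inheritParams monthly_series
#' @param span Fixed span, or `NULL` to select per system via
#'   [select_span_cv()].
#' @param candidate_spans Candidates used when `span` is `NULL`.
#' @param epsilon Floor passed to [to_probability()].
#' @param degree Loess degree.
#' @return Square numeric matrix `K` with `K[i, j] = KL(P_i || P_j)` in
#'   bits; dimnames are the systems.
#' @export
compare_systems <- function(table, matrix, distance_class = "in_field",
                            statistic = "n_cups_detected", span = NULL,
                            candidate_spans = seq(0.3, 1, by = 0.1),
                            epsilon = 1e-6, degree = 2) {
  ms <- monthly_series(table, matrix, distance_class, statistic)
  systems <- sort(unique(ms$system))
  if (length(systems) < 2) stop("need at least two systems to compare",
                                call. = FALSE)
  curves <- lapply(systems, function(s) {
    series <- ms[ms$system == s, c("month_index", "value")]
    sp <- span %||% as.numeric(select_span_cv(series, candidate_spans,
                                              degree))
    to_probability(fit_loess(series, span = sp, degree = degree), epsilon)
  })
  names(curves) <- systems
  k <- matrix(0, length(systems), length(systems),
              dimnames = list(systems, systems))
  for (i in systems) for (j in systems) {
    k[i, j] <- kl_divergence(curves[[i]], curves[[j]])
  }
  k
}
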