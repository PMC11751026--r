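# Exponential distance decay of residues from the field into the adjacent
# meadow: y = a * exp(b * x) + c, with the background term c fixed from the
# data (never estimated) and (a, b) fitted by damped least squares
# (Levenberg-Marquardt, minpack.lm::nlsLM). a is a vertical scaling factor
# (the excess at the field margin over the background), b the decay rate in
# 1/m (more negative = faster decay), c the background level the curve
# relaxes to at distance.

#' Map distance classes to metres from the field margin
#'
#' In-field samples (taken 20 m inside the cultivated area) are treated as
#' representative of the field margin and mapped to 0 m; off-field samples
#' sit at 1, 5 and 20 m into the adjacent meadow.
#'
#' @param distance_class Character vector of distance classes.
#' @return Named numeric vector of distances in metres.
#' @export
map_distance <- function(distance_class) {
  lut <- c(in_field = 0, m1 = 1, m5 = 5, m20 = 20)
  bad <- !distance_class %in% names(lut)
  if (any(bad)) {
    stop("unknown distance class: ",
         paste(unique(distance_class[bad]), collapse = ", "), call. = FALSE)
  }
  lut[distance_class]
}

#' Per-sample observations along the distance transect
#'
#' @param table A [residue_table()].
#' @param matrix `"soil"` or `"vegetation"`.
#' @param system Optional management system to subset to.
#' @param statistic Per-sample response: `"n_cups_detected"` (the CUP
#'   count, as in the headline analysis) or `"total_concentration"`.
#' @return Tibble with columns `site_id`, `system`, `month_index`, `x`
#'   (metres) and `y`.
#' @export
distance_observations <- function(table, matrix, system = NULL,
                                  statistic = "n_cups_detected") {
  s <- summarize_samples(table)
  s <- s[s$matrix == matrix, ]
  if (!is.null(system)) s <- s[s$system %in% system, ]
  if (nrow(s) == 0) stop("no samples for requested subset", call. = FALSE)
  if (!statistic %in% names(s)) stop("unknown statistic: ", statistic,
                                     call. = FALSE)
  tibble::tibble(site_id = s$site_id, system = s$system,
                 month_index = s$month_index,
                 x = unname(map_distance(s$distance_class)),
                 y = s[[statistic]])
}

#' Fit the exponential distance-decay model
#'
#' Fits `y = a * exp(b * x) + c` with `c` fixed, never estimated. By
#' default `c` is the mean response of the farthest sampled distance -- the
#' background level the decaying curve relaxes to; `c_background` may also
#' be a number (a known background) or `"in_field"` (mean at x = 0).
#' `(a, b)` minimise the residual sum of squares by Levenberg-Marquardt
#' damped least squares. `b` is unconstrained but the fit is flagged when
#' `b > 0` or `a <= 0`.
#'
#' @param obs Data frame with columns `x` (metres; in-field mapped to 0)
#'   and `y`. Requires at least one observation at x = 0 and two further
#'   distinct distances.
#' @param c_background `"far"` (default), `"in_field"`, or a number.
#' @param include_infield Include the x = 0 observations in the residual
#'   sum (default `TRUE`) or use them only to anchor `c` conventions.
#' @param start_b Initial decay rate, default -0.1.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A list of class `exp_fit`: `a`, `b`, `c`, `rss`, `converged`,
#'   `n_obs`, `flags` (character vector of warnings such as
#'   `"a_nonpositive"`, `"b_positive"`).
#' @export
fit_exponential <- function(obs, c_background = "far",
                            include_infield = TRUE, start_b = -0.1,
                            max_iter = 200) {
  stopifnot(is.data.frame(obs), all(c("x", "y") %in% names(obs)))
  obs <- obs[is.finite(obs$x) & is.finite(obs$y), c("x", "y")]
  if (!any(obs$x == 0)) stop("need at least one observation at x = 0",
                             call. = FALSE)
  if (length(setdiff(unique(obs$x), 0)) < 2) {
    stop("need at least two distinct distances besides 0", call. = FALSE)
  }
  if (length(unique(obs$y)) == 1) {
    stop("degenerate data: all responses equal (amplitude unidentifiable)",
         call. = FALSE)
  }
  c0 <- if (is.numeric(c_background)) {
    c_background
  } else if (identical(c_background, "far")) {
    mean(obs$y[obs$x == max(obs$x)])
  } else if (identical(c_background, "in_field")) {
    mean(obs$y[obs$x == 0])
  } else {
    stop("c_background must be 'far', 'in_field' or a number", call. = FALSE)
  }
  fitdat <- if (include_infield) obs else obs[obs$x > 0, ]
  a0 <- max(mean(obs$y[obs$x == 0]) - c0, 1e-3)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    y ~ a * exp(b * x) + c0, data = fitdat,
    start = list(a = a0, b = start_b),
    control = minpack.lm::nls.lm.control(maxiter = max_iter,
                                         ftol = 1e-10))),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(a = NA_real_, b = NA_real_, c = c0, rss = NA_real_,
                          converged = FALSE, n_obs = nrow(fitdat),
                          flags = "fit_failed"),
                     class = "exp_fit"))
  }
  cf <- stats::coef(fit)
  flags <- character(0)
  if (cf[["a"]] <= 0) flags <- c(flags, "a_nonpositive")
  if (cf[["b"]] > 0) flags <- c(flags, "b_positive")
  structure(list(a = unname(cf[["a"]]), b = unname(cf[["b"]]), c = c0,
                 rss = sum(stats::resid(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 n_obs = nrow(fitdat), flags = flags),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit> y = %.4g * exp(%.4g * x) + %.4g | rss %.4g | n %d | %s%s\n",
    x$a, x$b, x$c, x$rss, x$n_obs,
    if (isTRUE(x$converged)) "converged" else "NOT converged",
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
    else ""))
  invisible(x)
}

#' Predict from an exponential distance-decay fit
#'
#' @param object An `exp_fit`.
#' @param x Distances in metres.
#' @param ... Unused.
#' @return Expected response `a * exp(b * x) + c`.
#' @export
predict.exp_fit <- function(object, x, ...) {
  if (!isTRUE(object$converged)) stop("cannot predict from a non-converged fit",
                                      call. = FALSE)
  object$a * exp(object$b * x) + object$c
}

#' Distance-decay fits per management system
#'
#' Convenience wrapper fitting [fit_exponential()] separately for each
#' management system of one matrix, pooling all months (the transect
#' analysis of the annual data set).
#'
#' @inheritParams distance_observations
#' @inheritParams fit_exponential
#' @return Tibble with one row per system: `system`, `a`, `b`, `c`, `rss`,
#'   `converged`, `n_obs`, `flags`.
#' @export
fit_distance_decay <- function(table, matrix,
                               statistic = "n_cups_detected",
                               c_background = "far",
                               include_infield = TRUE) {
  systems <- sort(unique(table$records$system))
  rows <- lapply(systems, function(s) {
    obs <- distance_observations(table, matrix, system = s,
                                 statistic = statistic)
    f <- fit_exponential(obs, c_background = c_background,
                         include_infield = include_infield)
    tibble::tibble(system = s, matrix = matrix, statistic = statistic,
                   a = f$a, b = f$b, c = f$c, rss = f$rss,
                   converged = f$converged, n_obs = f$n_obs,
                   flags = paste(f$flags, collapse = ";"))
  })
  dplyr::bind_rows(rows)
}
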