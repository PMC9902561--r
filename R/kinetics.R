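#' Build the empirical survival (decay) curve of a dissociation dataset
#'
#' The fraction of tethers remaining, evaluated at every saved-frame time
#' from time zero to the end of the experiment. Censored beads count as
#' remaining throughout, so the curve's final value is at least the
#' censored fraction.
#'
#' @param dataset A `dissociation_dataset` (columns time_s and censored).
#' @param frame_interval Grid spacing in seconds (defaults to the spacing
#'   implied by the event times, or 1 s).
#' @param t_end Experiment end in seconds; defaults to the dataset's
#'   `duration` attribute, else the largest recorded time. Points after the
#'   last event are retained so the baseline offset stays identifiable.
#' @return An object of class `survival_curve`: list(times,
#'   fraction_remaining, n_total, n_censored, frame_interval).
#' @examples
#' d <- data.frame(time_s = 1:4, censored = 0L)
#' build_survival_curve(d, frame_interval = 1, t_end = 4)$fraction_remaining
#' @export
build_survival_curve <- function(dataset, frame_interval = NULL,
                                 t_end = NULL) {
  if (!is.data.frame(dataset) || nrow(dataset) == 0)
    stop("`dataset` must contain at least one tether", call. = FALSE)
  stopifnot(all(c("time_s", "censored") %in% names(dataset)))
  if (is.null(t_end)) {
    t_end <- attr(dataset, "duration")
    if (is.null(t_end)) t_end <- max(dataset$time_s)
  }
  if (is.null(frame_interval)) {
    fi <- attr(dataset, "frame_interval")
    frame_interval <- if (!is.null(fi)) fi else 1
  }
  times <- seq(0, t_end, by = frame_interval)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  ev <- dataset$time_s[dataset$censored == 0]
  n <- nrow(dataset)
  remaining <- n - vapply(times, function(t) sum(ev <= t), numeric(1))
  structure(
    list(times = times, fraction_remaining = remaining / n,
         n_total = n, n_censored = sum(dataset$censored == 1),
         frame_interval = frame_interval),
    class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Survival curve: n = %d tethers (%d censored), %d points, t = 0..%g s\n",
              x$n_total, x$n_censored, length(x$times),
              x$times[length(x$times)]))
  invisible(x)
}

#' Fit the single-exponential decay model to a survival curve
#'
#' Bounded nonlinear least squares of y(t) = y0 + A * exp(-k * t) against
#' the empirical fraction of tethers remaining, with y0 in [0, 1] (the
#' baseline offset absorbing stuck beads), A in (0, 1.5] and k > 0.
#' Initialisation: y0 from the curve's final value, A = 1 - y0, and k from
#' the area under the baseline-corrected curve (the mean lifetime); up to
#' `restarts` perturbed restarts are attempted on failure.
#'
#' @param curve A `survival_curve` with at least 5 points and one event.
#' @param restarts Maximum number of perturbed restarts (default 5).
#' @return An object of class `exponential_fit`: list(k, A, y0, r_squared,
#'   n, converged, message).
#' @export
fit_single_exponential <- function(curve, restarts = 5L) {
  stopifnot(inherits(curve, "survival_curve"))
  if (length(curve$times) < 5)
    stop("curve must have at least 5 points", call. = FALSE)
  if (curve$n_censored >= curve$n_total)
    stop("curve must contain at least one dissociation event", call. = FALSE)
  t <- curve$times; y <- curve$fraction_remaining
  y0_0 <- min(max(y[length(y)], 0), 1)
  A_0 <- min(max(1 - y0_0, 1e-3), 1.5)
  # mean lifetime ~ integral of (y - y0)/A over the observed window
  area <- sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  tau <- max((area - y0_0 * max(t)) / A_0, max(t) / 50, .Machine$double.eps)
  k_0 <- 1 / tau
  start <- c(k = k_0, A = A_0, y0 = y0_0)
  lower <- c(k = 1e-12, A = 1e-9, y0 = 0)
  upper <- c(k = Inf, A = 1.5, y0 = 1)
  residual_fn <- function(p) p[["y0"]] + p[["A"]] * exp(-p[["k"]] * t) - y
  fit <- NULL
  msg <- NULL
  for (att in 0:restarts) {
    st <- start
    if (att > 0) {  # deterministic perturbation ladder, no RNG involvement
      fac <- c(0.3, 3, 0.1, 10, 1)[min(att, 5)]
      st["k"] <- start["k"] * fac
    }
    st <- pmin(pmax(st, lower + 1e-12), c(k = 1e6, A = 1.5, y0 = 1))
    out <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = residual_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) { msg <<- conditionMessage(e); NULL })
    if (!is.null(out) && out$info %in% 1:4) { fit <- out; break }
    if (!is.null(out)) msg <- out$message
  }
  if (is.null(fit))
    return(structure(list(k = NA_real_, A = NA_real_, y0 = NA_real_,
                          r_squared = NA_real_, n = curve$n_total,
                          converged = FALSE, message = msg),
                     class = "exponential_fit"))
  p <- fit$par
  yhat <- p[["y0"]] + p[["A"]] * exp(-p[["k"]] * t)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(k = p[["k"]], A = p[["A"]], y0 = p[["y0"]],
                 r_squared = r2, n = curve$n_total, converged = TRUE,
                 message = NULL),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Single-exponential fit: NOT converged (", x$message, ")\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Single-exponential fit y = y0 + A exp(-k t): k = %.4g /s, A = %.3f, y0 = %.3f, R^2 = %.4f (n = %d)\n",
    x$k, x$A, x$y0, x$r_squared, x$n))
  invisible(x)
}

#' Histogram of dissociation times with span-scaled bin width
#'
#' Bin width is the event-time span divided by `target_bins`, rounded to a
#' whole number of saved-frame intervals (never below one frame), so data
#' sets whose time spans differ by an order of magnitude still get about
#' the same number of bins. Display / QC only; fitting always uses the
#' survival curve.
#'
#' @param dataset A `dissociation_dataset` with at least one event.
#' @param target_bins Approximate number of bins (default 20).
#' @param frame_interval Saved-frame interval in seconds (default from the
#'   dataset attribute, else 1).
#' @return A list with `breaks`, `counts`, `bin_width`.
#' @export
histogram_dissociation <- function(dataset, target_bins = 20,
                                   frame_interval = NULL) {
  ev <- dataset$time_s[dataset$censored == 0]
  if (length(ev) == 0)
    stop("dataset has no dissociation events", call. = FALSE)
  if (is.null(frame_interval)) {
    fi <- attr(dataset, "frame_interval")
    frame_interval <- if (!is.null(fi)) fi else 1
  }
  span <- max(ev)
  width <- max(1, round(span / target_bins / frame_interval)) *
    frame_interval
  breaks <- seq(0, ceiling(span / width) * width, by = width)
  counts <- graphics::hist(ev, breaks = breaks, plot = FALSE)$counts
  list(breaks = breaks, counts = counts, bin_width = width)
}

#' Aggregate replicate off-rates into a single estimate
#'
#' The off-rate of a condition is the unweighted mean of the individual
#' replicate fits, reported with the sample standard deviation across
#' replicates. Fewer than three replicates triggers a warning (conditions
#' are normally run at least in triplicate); a single replicate yields
#' sd = 0 with a low-replicate flag.
#'
#' @param fits List of `exponential_fit` objects (one per replicate).
#' @param construct,force Labels carried into the estimate.
#' @return An object of class `off_rate_estimate`: list(k_mean, k_sd,
#'   n_replicates, n_tethers_total, construct, force, low_replicates).
#' @export
aggregate_replicates <- function(fits, construct = NA_character_,
                                 force = NA_real_) {
  stopifnot(is.list(fits), length(fits) >= 1)
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0)
    stop("no converged replicate fits to aggregate", call. = FALSE)
  if (length(conv) < 3)
    warning("fewer than 3 converged replicates (", length(conv), ")",
            call. = FALSE)
  ks <- vapply(conv, function(f) f$k, numeric(1))
  structure(
    list(k_mean = mean(ks),
         k_sd = if (length(ks) > 1) stats::sd(ks) else 0,
         n_replicates = length(ks),
         n_tethers_total = sum(vapply(conv, function(f) f$n, numeric(1))),
         construct = construct, force = force,
         low_replicates = length(ks) < 3),
    class = "off_rate_estimate")
}

#' @export
print.off_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "Off-rate %s at %g pN: k = %.4g +/- %.2g /s (%d replicates, n = %d tethers)\n",
    x$construct, x$force, x$k_mean, x$k_sd, x$n_replicates,
    x$n_tethers_total))
  invisible(x)
}

#' Closed-form MLE of an exponential rate under right censoring
#'
#' k-hat = d / (sum of event times + n_censored * t_end), the maximum
#' likelihood estimator when all censoring happens at the experiment end.
#' Used as an independent cross-check of the survival-curve fit.
#'
#' @param dataset A `dissociation_dataset`.
#' @param t_end Censoring time (defaults to the dataset's duration).
#' @return The rate estimate in s^-1.
#' @export
censored_mle_rate <- function(dataset, t_end = NULL) {
  if (is.null(t_end)) {
    t_end <- attr(dataset, "duration")
    if (is.null(t_end)) t_end <- max(dataset$time_s)
  }
  ev <- dataset$time_s[dataset$censored == 0]
  n_c <- sum(dataset$censored == 1)
  if (length(ev) == 0) stop("no events", call. = FALSE)
  length(ev) / (sum(ev) + n_c * t_end)
}
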