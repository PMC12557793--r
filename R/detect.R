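#' Centred moving average with truncated edges
#'
#' Window mean aligned 1:1 with the input: sample `i` is averaged with the
#' `(window-1)/2` samples on each side, truncating the window where it runs
#' off either end of the series. A symmetric window avoids phase lag in the
#' deviation test used by [stability_filter()].
#'
#' @param x Numeric vector of weights.
#' @param window Odd window length, `1 <= window <= length(x)`.
#' @return Numeric vector the same length as `x`.
#' @export
#' @examples
#' moving_average(c(100, 100, 100, 200, 100, 100, 100), 5)
moving_average <- function(x, window = 5L) {
  n <- length(x)
  if (n == 0L) stop("empty trace")
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L, window <= n)
  if (window == 1L) return(as.numeric(x))
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Stability filter
#'
#' Removes raw samples that deviate from the centred moving average by more
#' than the stability tolerance (strictly more; a deviation of exactly the
#' tolerance is retained). Surviving samples form the stable-weight series
#' that serial-loss detection operates on; removed samples are dropped, not
#' interpolated.
#'
#' @param trace Data.frame with `timestamp` and `weight_g` columns.
#' @param config A [detector_config()].
#' @return The subset of `trace` that passed, with the aligned moving
#'   average of retained rows in attribute `moving_average`.
#' @export
stability_filter <- function(trace, config = detector_config()) {
  stopifnot(is.data.frame(trace), nrow(trace) > 0L)
  ma <- moving_average(trace$weight_g, min(config$ma_window,
                                           make_odd(nrow(trace))))
  keep <- abs(trace$weight_g - ma) <= config$stability_tolerance_g
  if (!any(keep))
    stop("stability filter removed every sample; trace segment unusable")
  out <- trace[keep, , drop = FALSE]
  attr(out, "moving_average") <- ma[keep]
  attr(out, "sampling_interval_s") <- attr(trace, "sampling_interval_s")
  out
}

make_odd <- function(n) if (n %% 2L == 0L) n - 1L else n

#' Flag transient fluctuations
#'
#' A transient fluctuation is an excursion away from the current stable
#' weight that returns to exactly that weight within the transient window
#' (e.g. a nose bump on the scale). Flagged spans are excluded before serial
#' losses are computed, so a brief dip can never masquerade as a small
#' drinking event. A departure that never returns (a real drink step, or a
#' sustained refill) updates the running stable weight instead.
#'
#' @param trace Data.frame with `timestamp` and `weight_g`.
#' @param config A [detector_config()].
#' @return Data.frame of flagged spans (`start_idx`, `end_idx`,
#'   `start_time`, `end_time`, `baseline_g`), with the per-sample logical
#'   flag vector in attribute `flags`.
#' @export
classify_transients <- function(trace, config = detector_config()) {
  w <- trace$weight_g
  tt <- trace$timestamp
  n <- length(w)
  flag <- logical(n)
  if (n >= 2L) {
    chg <- which(diff(w) != 0) + 1L   # candidate departure points
    stable <- w[1L]
    ci <- 1L
    while (ci <= length(chg)) {
      i <- chg[ci]
      if (w[i] == stable) { ci <- ci + 1L; next }
      j <- i + 1L
      ret <- 0L
      while (j <= n && tt[j] - tt[i] <= config$transient_window_s) {
        if (w[j] == stable) { ret <- j; break }
        j <- j + 1L
      }
      if (ret) {
        flag[i:(ret - 1L)] <- TRUE
        while (ci <= length(chg) && chg[ci] < ret) ci <- ci + 1L
      } else {
        stable <- w[i]
        ci <- ci + 1L
      }
    }
  }
  idx <- which(flag)
  if (length(idx)) {
    grp <- cumsum(c(1L, diff(idx) > 1L))
    spans <- data.frame(
      start_idx = tapply(idx, grp, min),
      end_idx = tapply(idx, grp, max))
    spans$start_time <- tt[spans$start_idx]
    spans$end_time <- tt[spans$end_idx]
    spans$baseline_g <- w[spans$start_idx - 1L]
    rownames(spans) <- NULL
  } else {
    spans <- data.frame(start_idx = integer(0), end_idx = integer(0),
                        start_time = numeric(0), end_time = numeric(0),
                        baseline_g = numeric(0))
  }
  attr(spans, "flags") <- flag
  spans
}

#' Segment a stable trace at refills
#'
#' A gain of at least `refill_threshold_g` between successive stable samples
#' is treated as an owner refill. Consumption is computed within the
#' resulting segments only, so a refill never counts as (negative)
#' consumption and never bridges losses across it.
#'
#' @param stable Stable-weight data.frame from [stability_filter()].
#' @param config A [detector_config()].
#' @return `stable` with an integer `segment` column added.
#' @export
handle_refills <- function(stable, config = detector_config()) {
  d <- diff(stable$weight_g)
  seg <- cumsum(c(1L, as.integer(d >= config$refill_threshold_g)))
  out <- stable
  out$segment <- seg
  attr(out, "sampling_interval_s") <- attr(stable, "sampling_interval_s")
  out
}

#' Detect consumption events on a stable-weight series
#'
#' Serial losses between successive stable samples are computed within each
#' refill segment. A loss strictly greater than `min_loss_g` seeds an
#' event; contiguous loss steps separated by at most `merge_gap_samples`
#' stable samples are merged into one event whose mass is the sum of the
#' losses in the merged span (so sub-threshold edge losses adjoining a
#' qualifying step are included, and the event mass equals the drop in
#' stable weight across the span). Weight gains never contribute.
#'
#' @param stable Stable-weight data.frame, optionally with a `segment`
#'   column from [handle_refills()].
#' @param config A [detector_config()].
#' @return Data.frame of events: `bowl_id`, `start_time`, `end_time`,
#'   `mass_g`, `n_steps`.
#' @export
detect_consumption <- function(stable, config = detector_config()) {
  if (is.null(stable$segment)) stable$segment <- 1L
  out <- lapply(split(seq_len(nrow(stable)), stable$segment), function(idx) {
    if (length(idx) < 2L) return(NULL)
    w <- stable$weight_g[idx]
    tt <- stable$timestamp[idx]
    loss <- -diff(w)                 # step i: between samples i and i+1
    is_loss <- loss > 0
    seeds <- loss > config$min_loss_g
    if (!any(seeds)) return(NULL)
    li <- which(is_loss)
    grp <- cumsum(c(1L, diff(li) > config$merge_gap_samples + 1L))
    res <- lapply(split(li, grp), function(steps) {
      if (!any(seeds[steps])) return(NULL)
      data.frame(start_time = tt[min(steps)],
                 end_time = tt[max(steps) + 1L],
                 mass_g = sum(loss[steps]),
                 n_steps = length(steps))
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  bowl <- if (!is.null(stable$scale_id) && nrow(stable)) stable$scale_id[1] else NA_character_
  if (is.null(out))
    return(data.frame(bowl_id = character(0), start_time = numeric(0),
                      end_time = numeric(0), mass_g = numeric(0),
                      n_steps = integer(0)))
  out <- out[order(out$start_time), , drop = FALSE]
  rownames(out) <- NULL
  cbind(bowl_id = rep(bowl, nrow(out)), out)
}

#' Detect consumption events on a raw trace
#'
#' End-to-end detector: flags transient fluctuations on the raw trace,
#' applies the moving-average stability filter, drops flagged samples,
#' segments at refills, and extracts serial-loss consumption events.
#'
#' @param trace Raw trace data.frame (`timestamp`, `weight_g`, `scale_id`).
#' @param config A [detector_config()].
#' @return Data.frame of consumption events as in [detect_consumption()],
#'   with the number of transient spans excluded in attribute
#'   `n_transients`.
#' @export
#' @examples
#' tr <- data.frame(timestamp = seq(0, 95, by = 5),
#'                  weight_g = c(rep(1000, 10), rep(990, 10)),
#'                  scale_id = "b1")
#' detect_events(tr)  # one 10 g event
detect_events <- function(trace, config = detector_config()) {
  stopifnot(is.data.frame(trace), nrow(trace) > 0L,
            !is.unsorted(trace$timestamp, strictly = TRUE))
  spans <- classify_transients(trace, config)
  flags <- attr(spans, "flags")
  ma <- moving_average(trace$weight_g, min(config$ma_window,
                                           make_odd(nrow(trace))))
  keep <- abs(trace$weight_g - ma) <= config$stability_tolerance_g & !flags
  if (!any(keep))
    stop("no stable samples left after filtering; trace unusable")
  stable <- trace[keep, , drop = FALSE]
  stable <- handle_refills(stable, config)
  ev <- detect_consumption(stable, config)
  attr(ev, "n_transients") <- nrow(spans)
  ev
}

#' Fit a scale calibration line
#'
#' Ordinary least-squares line mapping raw scale readings to grams, fitted
#' from paired readings of known reference masses (e.g. adding and removing
#' a precision 2,000 g calibration weight). The fit is accepted when the
#' largest absolute residual over all reference points is at most 1 g.
#'
#' @param raw Numeric raw scale readings.
#' @param reference_g Known reference masses (g); at least 2 distinct
#'   values.
#' @param max_residual_accept_g Acceptance bound on the worst residual (g).
#' @return Object of class `calibration_fit`: `slope` (g per raw unit),
#'   `intercept` (g), `max_residual_g`, `accepted`.
#' @export
#' @examples
#' calibrate_scale(c(10, 4010), c(0, 2000))  # slope 0.5, intercept -5
calibrate_scale <- function(raw, reference_g, max_residual_accept_g = 1) {
  stopifnot(length(raw) == length(reference_g))
  if (length(unique(reference_g)) < 2L)
    stop("calibration needs at least 2 distinct reference masses")
  fit <- lm(reference_g ~ raw)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 max_residual_g = max(abs(resid(fit))),
                 accepted = max(abs(resid(fit))) <= max_residual_accept_g),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Scale calibration: grams = %.6g * raw %+.6g (max residual %.3g g, %s)\n",
              x$slope, x$intercept, x$max_residual_g,
              if (x$accepted) "accepted" else "REJECTED"))
  invisible(x)
}

#' Apply a calibration fit to raw readings
#'
#' @param fit A `calibration_fit`.
#' @param raw Numeric raw readings.
#' @return Calibrated weights in grams.
#' @export
apply_calibration <- function(fit, raw) {
  stopifnot(inherits(fit, "calibration_fit"))
  fit$intercept + fit$slope * raw
}
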