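# Constructed-trace builders used across detector tests.

# Trace from a vector of weights at a fixed sampling interval.
make_trace <- function(weights, interval = 5, scale_id = "b1") {
  tr <- data.frame(timestamp = (seq_along(weights) - 1) * interval,
                   weight_g = as.numeric(weights), scale_id = scale_id,
                   stringsAsFactors = FALSE)
  attr(tr, "sampling_interval_s") <- interval
  tr
}

# Stepwise stable trace: rep each level n_per times.
make_step_trace <- function(levels, n_per = 10, interval = 5) {
  make_trace(rep(levels, each = n_per), interval = interval)
}

# Brute-force serial-loss oracle on an already-stable weight series:
# total mass = sum of all per-step losses that belong to a span containing
# at least one step > min_loss (independent re-derivation used to check
# detect_consumption).
oracle_total_loss <- function(w, min_loss = 2, merge_gap = 2) {
  loss <- -diff(w)
  li <- which(loss > 0)
  if (!length(li)) return(0)
  grp <- cumsum(c(1, diff(li) > merge_gap + 1))
  tot <- 0
  for (g in unique(grp)) {
    steps <- li[grp == g]
    if (any(loss[steps] > min_loss)) tot <- tot + sum(loss[steps])
  }
  tot
}

quiet_fit <- function(expr) suppressWarnings(suppressMessages(expr))
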