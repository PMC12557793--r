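#' Time-of-day bin of a timestamp
#'
#' Half-open six-hour clock bins: morning \[06,12), afternoon \[12,18),
#' evening \[18,24), night \[00,06). Every timestamp maps to exactly one
#' bin.
#'
#' @param timestamp Epoch seconds (numeric vector).
#' @param midnight_offset_s Offset (s) added before taking the local clock
#'   time, for traces whose epoch zero is not local midnight.
#' @return Character vector of bin labels.
#' @export
#' @examples
#' bin_time_of_day(18.5 * 3600)  # "evening"
bin_time_of_day <- function(timestamp, midnight_offset_s = 0) {
  h <- ((timestamp + midnight_offset_s) %% 86400) / 3600
  ifelse(h < 6, "night",
         ifelse(h < 12, "morning",
                ifelse(h < 18, "afternoon", "evening")))
}

#' Daily per-bowl consumption summaries
#'
#' Aggregates detected (or ground-truth) events into the analysis variable
#' of the study: daily water consumption per bowl, normalised by body mass
#' (1 g of water is taken as 1 mL, so grams / kg = mL/kg), with totals per
#' time-of-day bin. Days on which a bowl recorded no events are kept as
#' explicit zero rows, since zero-consumption bowl-days are observations,
#' not missing data.
#'
#' @param events Event data.frame with `dog_id`, `bowl_id`, `start_time`,
#'   `mass_g` (e.g. from [detect_events()], with `dog_id` joined on).
#' @param dogs Dog metadata data.frame (needs `dog_id`, `body_mass_kg`).
#' @param bowls Bowl map data.frame (`dog_id`, `bowl_id`, `sleeve`).
#' @param n_days Number of study days.
#' @param study_start Epoch second of local midnight starting day 1.
#' @param midnight_offset_s Clock offset passed to [bin_time_of_day()].
#' @return Data.frame of class `daily_summary`: one row per dog, day and
#'   bowl with `ml_per_kg`, `n_events`, bin totals `morning`, `afternoon`,
#'   `evening`, `night`, and `first_event` (earliest event start that day,
#'   `NA` if none).
#' @export
daily_consumption <- function(events, dogs, bowls, n_days,
                              study_start = 0, midnight_offset_s = 0) {
  stopifnot(all(c("dog_id", "body_mass_kg") %in% names(dogs)),
            all(c("dog_id", "bowl_id", "sleeve") %in% names(bowls)),
            n_days >= 1)
  grid <- merge(bowls, expand.grid(day = seq_len(n_days),
                                   bowl_id = bowls$bowl_id,
                                   KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE),
                by = "bowl_id")
  grid <- merge(grid, dogs[, c("dog_id", "body_mass_kg")], by = "dog_id")
  bins <- c("morning", "afternoon", "evening", "night")
  for (b in bins) grid[[b]] <- 0
  grid$ml_per_kg <- 0
  grid$n_events <- 0L
  grid$first_event <- NA_real_

  if (nrow(events)) {
    day <- floor((events$start_time - study_start + midnight_offset_s) / 86400) + 1L
    if (any(day < 1L | day > n_days))
      stop("event outside the study window (day ", paste(unique(day[day < 1 | day > n_days]), collapse = ","), ")")
    bin <- bin_time_of_day(events$start_time, midnight_offset_s)
    key_g <- paste(grid$bowl_id, grid$day)
    key_e <- paste(events$bowl_id, day)
    i <- match(key_e, key_g)
    if (anyNA(i)) stop("event on unknown bowl: ",
                       paste(unique(events$bowl_id[is.na(i)]), collapse = ", "))
    for (k in seq_len(nrow(events))) {
      g <- i[k]
      mlkg <- events$mass_g[k] / grid$body_mass_kg[g]
      grid$ml_per_kg[g] <- grid$ml_per_kg[g] + mlkg
      grid[[bin[k]]][g] <- grid[[bin[k]]][g] + mlkg
      grid$n_events[g] <- grid$n_events[g] + 1L
      grid$first_event[g] <- min(grid$first_event[g], events$start_time[k], na.rm = TRUE)
    }
  }
  out <- grid[order(grid$dog_id, grid$day, grid$bowl_id),
              c("dog_id", "day", "bowl_id", "sleeve", "ml_per_kg", "n_events",
                bins, "first_event")]
  rownames(out) <- NULL
  class(out) <- c("daily_summary", "data.frame")
  out
}

#' Per-event consumption statistics
#'
#' Events per day and mean quantity per event for one dog (or one
#' dog-bowl). Zero-event periods contribute to the events/day denominator;
#' quantity per event is undefined (reported `NA`) when there are no
#' events.
#'
#' @param events Event data.frame with `mass_g` for a single dog/bowl.
#' @param dog One-row dog profile (for `body_mass_kg`).
#' @param n_days Days observed (>= 1).
#' @return List with `events_per_day` and `ml_per_kg_per_event`.
#' @export
per_event_stats <- function(events, dog, n_days) {
  stopifnot(n_days >= 1, nrow(dog) == 1L)
  n <- nrow(events)
  list(events_per_day = n / n_days,
       ml_per_kg_per_event = if (n == 0L) NA_real_ else
         sum(events$mass_g) / dog$body_mass_kg / n)
}

#' Assign a dog's preferred scent from four-bowl summaries
#'
#' The preferred scent is the sleeve with the largest total mL/kg over the
#' screening days. Exact ties are broken deterministically in favour of the
#' sleeve with the earliest first drink. If nothing was drunk at all, no
#' preference is assigned.
#'
#' @param summaries [daily_consumption()] rows for a single dog.
#' @return List of class `preference_assignment`: `dog_id`,
#'   `preferred_scent` (`NA` if no consumption), `per_scent_totals`,
#'   `no_preference` flag.
#' @export
assign_preference <- function(summaries) {
  stopifnot(length(unique(summaries$dog_id)) == 1L)
  totals <- tapply(summaries$ml_per_kg, summaries$sleeve, sum)
  firsts <- tapply(summaries$first_event, summaries$sleeve,
                   function(x) if (all(is.na(x))) Inf else min(x, na.rm = TRUE))
  if (all(totals == 0))
    return(structure(list(dog_id = summaries$dog_id[1],
                          preferred_scent = NA_character_,
                          per_scent_totals = totals, no_preference = TRUE),
                     class = "preference_assignment"))
  best <- names(totals)[totals == max(totals)]
  if (length(best) > 1L) best <- best[which.min(firsts[best])]
  structure(list(dog_id = summaries$dog_id[1], preferred_scent = best,
                 per_scent_totals = totals, no_preference = FALSE),
            class = "preference_assignment")
}

#' @export
print.preference_assignment <- function(x, ...) {
  cat(sprintf("%s prefers %s (totals: %s)\n", x$dog_id,
              if (x$no_preference) "nothing (no consumption)" else x$preferred_scent,
              paste(sprintf("%s=%.2f", names(x$per_scent_totals),
                            x$per_scent_totals), collapse = ", ")))
  invisible(x)
}

#' Stratified random sample of dogs by preferred scent
#'
#' Samples a fixed number of dogs uniformly without replacement within each
#' preference stratum, reproducibly under a seed (e.g. five
#' chicken-preferring and five beef-preferring dogs for the follow-up
#' experiment).
#'
#' @param assignments Data.frame with `dog_id` and `preferred_scent` (or a
#'   list of `preference_assignment` objects).
#' @param per_stratum_n Dogs to draw from each stratum.
#' @param strata Stratum labels to sample from.
#' @param seed Integer seed.
#' @return Character vector of selected `dog_id`s.
#' @export
stratified_sample <- function(assignments, per_stratum_n,
                              strata = c("chicken", "beef"), seed = 1L) {
  if (!is.data.frame(assignments))
    assignments <- do.call(rbind, lapply(assignments, function(a)
      data.frame(dog_id = a$dog_id, preferred_scent = a$preferred_scent,
                 stringsAsFactors = FALSE)))
  set.seed(as.integer(seed))
  out <- lapply(strata, function(s) {
    ids <- assignments$dog_id[assignments$preferred_scent %in% s]
    if (length(ids) < per_stratum_n)
      stop(sprintf("stratum '%s' has %d dogs; %d requested", s,
                   length(ids), per_stratum_n))
    if (length(ids) == per_stratum_n) ids else sample(ids, per_stratum_n)
  })
  unlist(out)
}
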