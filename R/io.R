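#' Read and write trace, event and metadata CSV files
#'
#' Plain-CSV interchange formats. A trace file has columns
#' `timestamp,weight_g,scale_id`; timestamps are integer epoch seconds by
#' default or ISO-8601 UTC with `dialect = "iso"`. Event files carry
#' `dog_id,bowl_id,start_time,end_time,mass_g`; truth files add `kind`
#' (`drink`/`refill`/`nudge`); dog metadata files carry
#' `dog_id,body_mass_kg,diet,activity,age_years,preferred_scent`.
#'
#' @param trace,events,dogs Data.frames to write.
#' @param path File path.
#' @param dialect Timestamp dialect for traces: `"epoch"` or `"iso"`.
#' @return Readers return a data.frame (traces with attribute
#'   `sampling_interval_s` inferred from the first two rows); writers
#'   return the path invisibly.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
write_trace_csv <- function(trace, path, dialect = c("epoch", "iso")) {
  dialect <- match.arg(dialect)
  out <- trace
  if (dialect == "iso")
    out$timestamp <- format(as.POSIXct(trace$timestamp, origin = "1970-01-01",
                                       tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_trace_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "weight_g", "scale_id") %in% names(x)))
  if (is.character(x$timestamp))
    x$timestamp <- as.numeric(as.POSIXct(x$timestamp, tz = "UTC",
                                         format = "%Y-%m-%dT%H:%M:%SZ"))
  if (nrow(x) >= 2L)
    attr(x, "sampling_interval_s") <- x$timestamp[2] - x$timestamp[1]
  x
}

#' @rdname trace_io
#' @export
write_events_csv <- function(events, path) {
  write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_events_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname trace_io
#' @export
write_dogs_csv <- function(dogs, path) {
  cols <- c("dog_id", "body_mass_kg", "diet", "activity", "age_years",
            "preferred_scent")
  write.csv(dogs[, intersect(cols, names(dogs)), drop = FALSE], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trace_io
#' @export
read_dogs_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cohort to a directory of CSV files
#'
#' Writes `dogs.csv`, `bowls.csv`, `truth.csv`, `nuisance.csv` and one
#' trace CSV per bowl under `traces/`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param dialect Timestamp dialect for trace files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = "epoch") {
  stopifnot(inherits(cohort, "hydro_cohort"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  write_dogs_csv(cohort$dogs, file.path(dir, "dogs.csv"))
  write.csv(cohort$bowls, file.path(dir, "bowls.csv"), row.names = FALSE,
            quote = FALSE)
  truth <- cohort$truth
  truth$kind <- "drink"
  write_events_csv(truth, file.path(dir, "truth.csv"))
  write.csv(cohort$nuisance, file.path(dir, "nuisance.csv"),
            row.names = FALSE, quote = FALSE)
  for (id in names(cohort$traces))
    write_trace_csv(cohort$traces[[id]],
                    file.path(dir, "traces", paste0(id, ".csv")),
                    dialect = dialect)
  invisible(dir)
}
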