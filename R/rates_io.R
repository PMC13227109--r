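# Rate-set configuration files: JSON mapping each rate label to
# {value, units}, with the mechanism variant recorded alongside.
# A packaged default file carries the measured constants with their
# provenance notes.

#' Read a rate-constant set from a JSON configuration file
#'
#' @param path JSON file with fields `mechanism_variant` and `rates`
#'   (label -> list(value, units)); see the packaged example at
#'   `system.file("extdata", "crosslinked_rates.json",
#'   package = "polbkin")`.
#' @return A `rate_set`.
#' @export
read_rates <- function(path) {
  cfg <- jsonlite::read_json(path)
  if (is.null(cfg$mechanism_variant) || is.null(cfg$rates)) {
    stop("rate config must contain mechanism_variant and rates")
  }
  values <- vapply(cfg$rates, function(x) as.numeric(x$value), numeric(1))
  rates <- rate_set(cfg$mechanism_variant, values)
  # cross-check declared units against the variant's bimolecular steps
  units <- vapply(cfg$rates, function(x)
    if (is.null(x$units)) NA_character_ else x$units, character(1))
  bimol <- names(values) %in% rates$bimolecular
  bad <- !is.na(units) &
    ((bimol & units != "uM^-1 s^-1") | (!bimol & units != "s^-1"))
  if (any(bad)) {
    stop("unexpected units for rate label(s): ",
         paste(names(values)[bad], collapse = ", "))
  }
  rates
}

#' Write a rate-constant set to a JSON configuration file
#'
#' @param rates A `rate_set`.
#' @param path Output path.
#' @param notes Optional named character vector of per-label comments.
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path, notes = NULL) {
  stopifnot(inherits(rates, "rate_set"))
  entries <- lapply(names(rates$values), function(label) {
    e <- list(value = unname(rates$values[label]),
              units = if (label %in% rates$bimolecular) "uM^-1 s^-1" else
                "s^-1")
    if (!is.null(notes) && label %in% names(notes)) {
      e$note <- unname(notes[label])
    }
    e
  })
  names(entries) <- names(rates$values)
  jsonlite::write_json(
    list(mechanism_variant = rates$variant, rates = entries),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a full-species trajectory to CSV
#'
#' Columns: `time_s`, then one column per species (nM).
#'
#' @param trajectory A `polbkin_trajectory` from [integrate_scheme()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
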