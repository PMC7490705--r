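# CSV readers and writers for all table schemas. All files are UTF-8 CSVs
# with headers and ISO-8601 dates. Readers validate schemas and report
# offending rows by line number (header = line 1, first data row = line 2).

read_csv_checked <- function(path, required, col_types = NULL) {
  if (!file.exists(path)) {
    stop("File not found: ", path, call. = FALSE)
  }
  x <- readr::read_csv(path,
    col_types = col_types, show_col_types = FALSE, progress = FALSE
  )
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(
      basename(path), ": missing column(s) ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  x
}

fail_rows <- function(path, bad, what) {
  if (length(bad) > 0) {
    stop(
      basename(path), ": ", what, " at line(s) ",
      paste(head(bad + 1L, 5), collapse = ", "),
      if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "",
      call. = FALSE
    )
  }
}

check_date_column <- function(x, path, col) {
  if (!inherits(x[[col]], "Date")) {
    parsed <- as.Date(as.character(x[[col]]), format = "%Y-%m-%d")
    fail_rows(path, which(is.na(parsed) & !is.na(x[[col]])), paste("unparseable", col))
    x[[col]] <- parsed
  }
  fail_rows(path, which(is.na(x[[col]])), paste("missing", col))
  x
}

#' Read an arrival schedule
#'
#' Expects columns `date` (ISO-8601) and `containers` (nonnegative
#' integers); dates must be unique.
#'
#' @param path Path to `arrivals.csv`.
#' @return A tibble `(date, containers)`.
#' @export
read_arrivals <- function(path) {
  x <- read_csv_checked(path, c("date", "containers"))
  x <- check_date_column(x, path, "date")
  fail_rows(path, which(is.na(x$containers) | x$containers < 0 |
    x$containers != floor(x$containers)), "invalid container count")
  fail_rows(path, which(duplicated(x$date)), "duplicated arrival date")
  tibble::as_tibble(x[c("date", "containers")])
}

#' Read per-container sample records
#'
#' Expects columns `date`, `container_id`, `taxon`, `seed_count`; seed
#' counts must be nonnegative integers (explicit zeros are meaningful --
#' they enter the seeds-per-container denominator).
#'
#' @param path Path to `samples.csv`.
#' @return A tibble `(date, container_id, taxon, seed_count)`.
#' @export
read_samples <- function(path) {
  x <- read_csv_checked(path, c("date", "container_id", "taxon", "seed_count"),
    col_types = readr::cols(
      container_id = readr::col_character(),
      taxon = readr::col_character()
    )
  )
  x <- check_date_column(x, path, "date")
  fail_rows(path, which(is.na(x$seed_count) | x$seed_count < 0 |
    x$seed_count != floor(x$seed_count)), "invalid seed_count")
  tibble::as_tibble(x[c("date", "container_id", "taxon", "seed_count")])
}

#' Read germination-trial records
#'
#' Dish-level or pooled tallies with columns `taxon`, `seeds_plated`,
#' `germinated`, `survived_transplant` (a `dish_id` column is kept when
#' present). Enforces `survived <= germinated <= plated` per row.
#'
#' @param path Path to `trials.csv`.
#' @return A tibble of tallies.
#' @export
read_trials <- function(path) {
  x <- read_csv_checked(
    path, c("taxon", "seeds_plated", "germinated", "survived_transplant"),
    col_types = readr::cols(taxon = readr::col_character())
  )
  for (col in c("seeds_plated", "germinated", "survived_transplant")) {
    fail_rows(path, which(is.na(x[[col]]) | x[[col]] < 0 |
      x[[col]] != floor(x[[col]])), paste("invalid", col))
  }
  fail_rows(path, which(x$germinated > x$seeds_plated |
    x$survived_transplant > x$germinated), "inconsistent tally")
  keep <- intersect(
    c("taxon", "dish_id", "seeds_plated", "germinated", "survived_transplant"),
    names(x)
  )
  tibble::as_tibble(x[keep])
}

#' Read a taxon life-history table
#'
#' Expects `taxon`, `germination_pct`, `survival_pct` (integer percents) and
#' `fecundity`; percentages are converted to proportions.
#'
#' @param path Path to `life_history.csv`.
#' @return A tibble `(taxon, germination, survival, fecundity)`.
#' @export
read_life_history <- function(path) {
  x <- read_csv_checked(path,
    c("taxon", "germination_pct", "survival_pct", "fecundity"),
    col_types = readr::cols(taxon = readr::col_character())
  )
  for (col in c("germination_pct", "survival_pct")) {
    fail_rows(path, which(is.na(x[[col]]) | x[[col]] < 0 | x[[col]] > 100),
      paste("invalid", col)
    )
  }
  fail_rows(path, which(is.na(x$fecundity) | x$fecundity < 1), "invalid fecundity")
  tibble::tibble(
    taxon = x$taxon,
    germination = x$germination_pct / 100,
    survival = x$survival_pct / 100,
    fecundity = x$fecundity
  )
}

#' Write the standard CSV outputs of a synthetic season
#'
#' Writes `arrivals.csv`, `samples.csv`, `trials.csv` (if provided) and
#' `truth.csv` into `dir`.
#'
#' @param season A `seedflux_season` from [generate_season()].
#' @param dir Output directory (created if needed).
#' @param trials Optional dish-level trial table to write alongside.
#' @return Invisibly, the paths written.
#' @export
write_season_csvs <- function(season, dir, trials = NULL) {
  stopifnot(inherits(season, "seedflux_season"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    arrivals = file.path(dir, "arrivals.csv"),
    samples = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(season$arrivals, paths["arrivals"])
  readr::write_csv(season$samples, paths["samples"])
  readr::write_csv(season$truth, paths["truth"])
  if (!is.null(trials)) {
    paths <- c(paths, trials = file.path(dir, "trials.csv"))
    readr::write_csv(trials, paths["trials"])
  }
  invisible(paths)
}
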