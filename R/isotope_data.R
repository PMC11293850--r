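#' @title Stable-isotope survey tables
#' @description
#' A survey dataset holds one row per analysed individual: an opaque sample
#' id, the area (gulf) code, the area's protection status (`"fra"` for a
#' fishery-restricted area, `"trawled"` otherwise), the ecological role
#' (`"consumer"`, `"baseline_benthic"` or `"baseline_pelagic"`), a taxon
#' code, carbon and nitrogen isotope ratios in per-mil delta notation
#' (vs PeeDee Belemnite and Atmospheric Air), and an optional total length
#' in cm.  Pelagic baselines are stored but excluded from trophic-position
#' fitting by default; they exist so the baseline screening step can assess
#' them.
#' @name isotope-data
NULL

ISOTOPE_COLUMNS <- c("sample_id", "area", "protection", "role", "taxon",
                     "d13C", "d15N", "total_length_cm")
ROLES <- c("consumer", "baseline_benthic", "baseline_pelagic")
PROTECTIONS <- c("fra", "trawled")

#' Construct a survey dataset from a samples table
#'
#' @param samples data.frame with columns
#'   `sample_id, area, protection, role, taxon, d13C, d15N, total_length_cm`
#'   (`total_length_cm` may be missing or NA).
#' @return a `survey_dataset`: the samples data.frame plus an `areas`
#'   attribute mapping area codes to protection labels.
#' @export
survey_dataset <- function(samples) {
  if (is.null(samples$total_length_cm)) samples$total_length_cm <- NA_real_
  missing_cols <- setdiff(ISOTOPE_COLUMNS, names(samples))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  samples <- samples[, ISOTOPE_COLUMNS]
  for (col in c("sample_id", "area", "protection", "role", "taxon"))
    samples[[col]] <- as.character(samples[[col]])
  for (col in c("d13C", "d15N", "total_length_cm"))
    samples[[col]] <- as.numeric(samples[[col]])
  if (nrow(samples)) {
    bad_role <- !samples$role %in% ROLES
    if (any(bad_role))
      stop("unknown role in row(s) ", paste(which(bad_role), collapse = ", "))
    bad_prot <- !samples$protection %in% PROTECTIONS
    if (any(bad_prot))
      stop("unknown protection in row(s) ", paste(which(bad_prot), collapse = ", "))
    bad_delta <- !is.finite(samples$d13C) | !is.finite(samples$d15N)
    if (any(bad_delta))
      stop("non-finite delta value in row(s) ",
           paste(which(bad_delta), collapse = ", "))
    # protection must be constant within an area
    tab <- unique(samples[, c("area", "protection")])
    dup <- tab$area[duplicated(tab$area)]
    if (length(dup))
      stop("conflicting protection labels for area(s): ",
           paste(unique(dup), collapse = ", "))
    areas <- stats::setNames(tab$protection, tab$area)
  } else {
    areas <- stats::setNames(character(0), character(0))
  }
  structure(samples, areas = areas, class = c("survey_dataset", "data.frame"))
}

#' @export
print.survey_dataset <- function(x, ...) {
  a <- attr(x, "areas")
  cat(sprintf("Isotope survey: %d samples, %d area(s) [%s]\n", nrow(x),
              length(a), paste0(names(a), ":", a, collapse = " ")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Read an isotope survey table from CSV
#'
#' Comma-separated, UTF-8, decimal point, header required; columns
#' `sample_id,area,protection,role,taxon,d13C,d15N,total_length_cm`
#' (the last may be empty).  Row order is preserved.  Unparseable or
#' non-finite delta values and missing required columns are errors.
#'
#' @param path file path.
#' @return a [survey_dataset()].
#' @seealso [write_isotope_table()]
#' @export
read_isotope_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(setdiff(ISOTOPE_COLUMNS, "total_length_cm"), names(raw))
  if (length(missing_cols))
    stop("format error in ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(raw$total_length_cm)) raw$total_length_cm <- NA
  for (col in c("d13C", "d15N", "total_length_cm")) {
    v <- trimws(raw[[col]])
    num <- suppressWarnings(as.numeric(v))
    bad <- is.na(num) & !(v == "" | toupper(v) == "NA")
    if (any(bad))
      stop("record error in ", path, ": unparseable ", col, " in row(s) ",
           paste(which(bad), collapse = ", "))
    raw[[col]] <- num
  }
  survey_dataset(raw)
}

#' Write an isotope survey table to CSV
#'
#' Inverse of [read_isotope_table()]; a write/read round trip reproduces
#' every field exactly (deltas are written with full precision).
#'
#' @param ds a [survey_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(ds, path) {
  df <- as.data.frame(ds)
  for (col in c("d13C", "d15N", "total_length_cm"))
    df[[col]] <- vapply(df[[col]], function(x)
      if (is.na(x)) "" else format(x, digits = 17), "")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a survey dataset against the sampling-design invariants
#'
#' Errors are violations that preclude trophic-position fitting: any
#' (consumer taxon, area) group with fewer than 3 individuals, and any area
#' without a benthic baseline taxon having at least 3 individuals.
#' Warnings flag suspect records: consumer groups whose mean carbon
#' signature sits more than 5 per-mil from every baseline in their area.
#'
#' @param ds a [survey_dataset()].
#' @return a `validation_report` list with `errors` and `warnings`
#'   character vectors; the dataset is accepted for fitting iff `errors`
#'   is empty (see [is_valid()]).
#' @export
validate_dataset <- function(ds) {
  errors <- character(0)
  warnings <- character(0)
  areas <- attr(ds, "areas")
  if (!length(areas))
    errors <- c(errors, "dataset has no areas (no baselines, no consumers)")
  for (area in names(areas)) {
    sub <- ds[ds$area == area, , drop = FALSE]
    cons <- sub[sub$role == "consumer", , drop = FALSE]
    if (nrow(cons)) {
      n_by_taxon <- table(cons$taxon)
      small <- names(n_by_taxon)[n_by_taxon < 3]
      for (tx in small)
        errors <- c(errors, sprintf(
          "consumer group (%s, %s) has %d sample(s), need >= 3",
          tx, area, n_by_taxon[[tx]]))
    }
    benth <- sub[sub$role == "baseline_benthic", , drop = FALSE]
    ok_taxa <- if (nrow(benth)) sum(table(benth$taxon) >= 3) else 0L
    if (ok_taxa == 0)
      errors <- c(errors, sprintf(
        "area %s has no benthic baseline taxon with >= 3 samples", area))
    # suspect-record screen: consumers far (in d13C) from every baseline
    base <- sub[sub$role != "consumer", , drop = FALSE]
    if (nrow(base) && nrow(cons)) {
      base_means <- tapply(base$d13C, base$taxon, mean)
      for (tx in unique(cons$taxon)) {
        mc <- mean(cons$d13C[cons$taxon == tx])
        if (all(abs(mc - base_means) > 5))
          warnings <- c(warnings, sprintf(
            "consumer %s in %s is > 5 permil (d13C) from every baseline",
            tx, area))
      }
    }
  }
  structure(list(errors = errors, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (!length(x$errors)) cat("dataset accepted for fitting (no errors)\n")
  else cat("errors:\n", paste0("  - ", x$errors, "\n"), sep = "")
  if (length(x$warnings))
    cat("warnings:\n", paste0("  - ", x$warnings, "\n"), sep = "")
  invisible(x)
}

#' @rdname validate_dataset
#' @export
is_valid <- function(ds) length(validate_dataset(ds)$errors) == 0

#' Split an area's samples into consumer groups and baseline pools
#'
#' The benthic pool merges all `baseline_benthic` taxa of the area into one
#' sample set (the model treats the local benthic community, not a single
#' species, as its baseline); the pelagic pool likewise.  Area matching is
#' strict: no cross-area baselines.
#'
#' @param ds a [survey_dataset()].
#' @param area area code present in the dataset.
#' @return list with `consumers` (named list of per-taxon data.frames),
#'   `benthic` and `pelagic` (data.frames, possibly empty).
#' @export
split_consumers_baselines <- function(ds, area) {
  areas <- attr(ds, "areas")
  if (!area %in% names(areas))
    stop("unknown area code: ", area)
  sub <- as.data.frame(ds[ds$area == area, , drop = FALSE])
  cons <- sub[sub$role == "consumer", , drop = FALSE]
  consumers <- split(cons, cons$taxon)
  list(consumers = consumers,
       benthic = sub[sub$role == "baseline_benthic", , drop = FALSE],
       pelagic = sub[sub$role == "baseline_pelagic", , drop = FALSE])
}
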