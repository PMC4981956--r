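#' @keywords internal
"_PACKAGE"

## controlled vocabularies
.status_levels  <- c("extinct", "extant")
.region_levels  <- c("precaudal", "caudal")
.element_levels <- c("ENB", "EPB", "MT", "POT")
.side_levels    <- c("epaxial", "hypaxial")

.specimen_cols <- c("taxon_id", "status", "clade",
                    "L_axis1", "L_axis2", "head_length", "L_head_in_vertebrae",
                    "N_PCV", "N_CV", "AR_head", "AR_PCV", "AR_CV")
## these may be absent (empty cell -> NA); 0 is a legal value and never
## stands in for "missing"
.specimen_optional <- c("clade", "head_length", "L_head_in_vertebrae",
                        "AR_head", "AR_PCV", "AR_CV")

.vertebra_cols <- c("taxon_id", "index", "region",
                    "centrum_length", "centrum_height")

.tendon_cols <- c("taxon_id", "element", "side", "k_min", "k_max",
                  "tl_start", "tl_end", "element_length")

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

.as_num <- function(df, cols, what) {
  for (col in cols) {
    raw <- df[[col]]
    if (is.numeric(raw)) next
    raw <- trimws(as.character(raw))
    raw[raw == ""] <- NA
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s' at row(s) %s",
                   what, col, paste(bad, collapse = ", ")), call. = FALSE)
    df[[col]] <- num
  }
  df
}

#' Validate a table of specimen records
#'
#' Checks the invariants every measured individual must satisfy: positive
#' primary and secondary body axes with \code{L_axis1 >= L_axis2} (the
#' secondary axis is maximum body depth, or width in extant fishes), at
#' least one vertebra, and strictly positive aspect ratios wherever they are
#' recorded.
#'
#' @param specimens data frame with one row per measured individual.
#' @return the validated data frame, invisibly classed
#'   \code{"specimen_table"}.
#' @export
validate_specimens <- function(specimens) {
  .check_columns(specimens, .specimen_cols, "specimen table")
  specimens <- .as_num(specimens, setdiff(.specimen_cols,
                                          c("taxon_id", "status", "clade")),
                       "specimen table")
  bad_status <- setdiff(unique(specimens$status), .status_levels)
  if (length(bad_status))
    stop("specimen table: unknown status value(s): ",
         paste(bad_status, collapse = ", "), call. = FALSE)

  .fail <- function(cond, msg) {
    hit <- which(!is.na(cond) & cond)
    if (length(hit))
      stop(sprintf("specimen table: %s for taxon %s", msg,
                   paste(specimens$taxon_id[hit], collapse = ", ")),
           call. = FALSE)
  }
  .fail(specimens$L_axis1 <= 0, "L_axis1 must be > 0")
  .fail(specimens$L_axis2 <= 0, "L_axis2 must be > 0")
  .fail(specimens$L_axis1 < specimens$L_axis2, "L_axis1 < L_axis2")
  .fail(specimens$N_PCV + specimens$N_CV < 1, "N_PCV + N_CV < 1")
  for (ar in c("AR_head", "AR_PCV", "AR_CV"))
    .fail(specimens[[ar]] <= 0, paste(ar, "must be > 0 when present"))
  .fail(!is.na(specimens$L_head_in_vertebrae) &
          specimens$L_head_in_vertebrae < 0,
        "L_head_in_vertebrae must be >= 0")
  class(specimens) <- unique(c("specimen_table", class(specimens)))
  invisible(specimens)
}

#' Read a specimen measurement table
#'
#' Reads a CSV of per-individual measurements (comma-separated, UTF-8, "."
#' decimal separator, header row mandatory) and validates it.  Empty cells
#' in optional columns become \code{NA} ("absent"); a measurement of 0 is a
#' legal value and is never used to encode absence.  Fossil names are stored
#' without any dagger; extinct status is carried by the \code{status}
#' column.
#'
#' @param path path to the CSV file.
#' @return a \code{specimen_table} data frame, rows in file order.
#' @seealso [write_specimen_table()], [compute_vsi()]
#' @export
read_specimen_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  .check_columns(df, .specimen_cols, basename(path))
  df$clade[df$clade == ""] <- NA
  out <- validate_specimens(df)
  class(out) <- unique(c("specimen_table", "data.frame"))
  out
}

#' Write a specimen table
#'
#' Linear measurements (mm) are written with 3 decimals so a
#' write-then-read round trip preserves them to the declared precision.
#'
#' @param specimens a \code{specimen_table}.
#' @param path output CSV path.
#' @export
write_specimen_table <- function(specimens, path) {
  out <- as.data.frame(specimens)[, .specimen_cols]
  for (col in c("L_axis1", "L_axis2", "head_length"))
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         sprintf("%.3f", out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read per-vertebra centrum measurements
#'
#' One row per vertebral centrum: taxon, 1-based ordinal along the column,
#' region (precaudal or caudal), centrum length and height in mm.
#'
#' @param path path to the CSV file.
#' @return a \code{vertebra_table} data frame.
#' @export
read_vertebra_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_vertebrae(df)
}

#' Validate per-vertebra measurements
#'
#' @param vertebrae data frame of centrum measurements.
#' @return the validated table, invisibly classed \code{"vertebra_table"}.
#' @export
validate_vertebrae <- function(vertebrae) {
  .check_columns(vertebrae, .vertebra_cols, "vertebra table")
  vertebrae <- .as_num(vertebrae,
                       c("index", "centrum_length", "centrum_height"),
                       "vertebra table")
  bad_region <- setdiff(unique(vertebrae$region), .region_levels)
  if (length(bad_region))
    stop("vertebra table: unknown region value(s): ",
         paste(bad_region, collapse = ", "), call. = FALSE)
  if (any(vertebrae$centrum_length <= 0, na.rm = TRUE) ||
      any(vertebrae$centrum_height <= 0, na.rm = TRUE))
    stop("vertebra table: centrum length and height must be > 0",
         call. = FALSE)
  dup <- vapply(split(vertebrae$index, vertebrae$taxon_id),
                anyDuplicated, 0L)
  if (any(dup > 0))
    stop("vertebra table: duplicated vertebra index for taxon ",
         paste(names(dup)[dup > 0], collapse = ", "), call. = FALSE)
  class(vertebrae) <- unique(c("vertebra_table", class(vertebrae)))
  invisible(vertebrae)
}

#' Read a table of ossified-tendon observations
#'
#' Each row records one ossified myoseptal element of a fossil: the element
#' type (ENB epineural bone, EPB epipleural bone, MT myorhabdoid tendon,
#' POT posterior oblique tendon), the body side (epaxial/hypaxial), the
#' traversal count beyond the attachment vertebra N in "N + k" notation as
#' a \code{[k_min, k_max]} range (fractional counts such as 2.5 allowed),
#' and the element's extent along the body in percent of total length.
#'
#' @param path path to the CSV file.
#' @return a \code{tendon_table} data frame.
#' @export
read_tendon_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tendons(df)
}

#' Validate tendon observations
#'
#' @param tendons data frame of tendon observations.
#' @return the validated table, invisibly classed \code{"tendon_table"}.
#' @export
validate_tendons <- function(tendons) {
  .check_columns(tendons, setdiff(.tendon_cols, "element_length"),
                 "tendon table")
  if (!"element_length" %in% names(tendons))
    tendons$element_length <- NA_real_
  tendons <- .as_num(tendons, c("k_min", "k_max", "tl_start", "tl_end",
                                "element_length"), "tendon table")
  bad_el <- setdiff(unique(tendons$element), .element_levels)
  if (length(bad_el))
    stop("tendon table: unknown element type(s): ",
         paste(bad_el, collapse = ", "), call. = FALSE)
  bad_side <- setdiff(unique(tendons$side), .side_levels)
  if (length(bad_side))
    stop("tendon table: unknown side value(s): ",
         paste(bad_side, collapse = ", "), call. = FALSE)
  with(tendons, {
    if (any(!is.finite(k_min)) || any(!is.finite(k_max)))
      stop("tendon table: k values must be finite", call. = FALSE)
    if (any(k_min < 0) || any(k_max < k_min))
      stop("tendon table: need 0 <= k_min <= k_max", call. = FALSE)
    if (any(tl_start < 0 | tl_end > 100 | tl_start > tl_end, na.rm = TRUE))
      stop("tendon table: need 0 <= tl_start <= tl_end <= 100",
           call. = FALSE)
  })
  class(tendons) <- unique(c("tendon_table", class(tendons)))
  invisible(tendons)
}
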