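#' Spontaneous-report sets
#'
#' A `report_set` is a tibble with one row per spontaneous report: an opaque
#' `report_id`, one character column per demographic attribute of the schema,
#' list-columns `drugs` and `symptoms` holding the report's drug and symptom
#' (MedDRA preferred term) groups as character sets, and an optional
#' `event_date` (`Date`, `NA` when unknown). All downstream counting is at
#' report level: a report contributes at most once to any count, however many
#' drug or symptom rows it spans in the de-normalized source table.
#'
#' @param df A data frame in de-normalized long form: one row per
#'   report x drug x symptom combination, with a report-id column, one column
#'   per demographic attribute, a `Drug` column and a `PT` column.
#' @param schema Character vector of demographic attribute names. Defaults to
#'   the five used throughout: Year, Age, Gender, Weight, Country.
#' @param id_col Name of the report-id column (default `"Demo_key"`).
#' @param date_col Optional name of an event-date column; parsed with
#'   [as.Date()] when present.
#'
#' @details Rows sharing a report id are grouped into one report whose drug
#'   and symptom groups are the distinct values over those rows; the grouping
#'   tolerates both the full m x k row cross-product and partial row sets.
#'   Rows of one report that disagree on a demographic value are an error.
#'   Empty or `NA` demographic values are replaced by [missing_token()].
#'
#' @return A `report_set` tibble.
#' @examples
#' df <- data.frame(Demo_key = 1, Year = "y1", Age = "a1", Gender = "g1",
#'                  Weight = "w1", Country = "c1", Drug = "d1", PT = "s1")
#' as_report_set(df)
#' @export
as_report_set <- function(df, schema = default_schema(), id_col = "Demo_key",
                          date_col = NULL) {
  df <- as_tibble(df)
  required <- c(id_col, schema, "Drug", "PT")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "adrmine_schema_error")
  }
  if (nrow(df) == 0) {
    return(new_report_set(empty_report_tbl(schema), schema))
  }
  df[[id_col]] <- as.character(df[[id_col]])
  for (at in schema) {
    v <- as.character(df[[at]])
    v[is.na(v) | v == ""] <- MISSING_TOKEN
    df[[at]] <- v
  }
  # demographic consistency within a report id
  demo <- dplyr::distinct(df, dplyr::across(dplyr::all_of(c(id_col, schema))))
  dup <- demo[[id_col]][duplicated(demo[[id_col]])]
  if (length(dup) > 0) {
    abort(paste0("conflicting demographic values within report id(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "adrmine_integrity_error")
  }
  ids <- unique(df[[id_col]])
  drugs <- lapply(split(as.character(df$Drug), df[[id_col]]),
                  function(x) sort(unique(x)))
  syms <- lapply(split(as.character(df$PT), df[[id_col]]),
                 function(x) sort(unique(x)))
  out <- demo[match(ids, demo[[id_col]]), ]
  names(out)[names(out) == id_col] <- "report_id"
  out$drugs <- unname(drugs[ids])
  out$symptoms <- unname(syms[ids])
  if (!is.null(date_col) && date_col %in% names(df)) {
    d <- df[[date_col]][match(ids, df[[id_col]])]
    out$event_date <- as.Date(as.character(d))
  } else {
    out$event_date <- as.Date(rep(NA_character_, length(ids)))
  }
  new_report_set(out, schema)
}

new_report_set <- function(tbl, schema) {
  tbl <- as_tibble(tbl)
  structure(tbl, schema = schema,
            class = c("report_set", class(tbl)))
}

empty_report_tbl <- function(schema) {
  out <- tibble(report_id = character())
  for (at in schema) out[[at]] <- character()
  out$drugs <- list()
  out$symptoms <- list()
  out$event_date <- as.Date(character())
  out
}

#' @export
`[.report_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) out <- new_report_set(out, report_schema(x))
  out
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d report(s); schema: %s\n", nrow(x),
              paste(report_schema(x), collapse = ", ")))
  NextMethod()
}

#' Schema of a report set
#'
#' @param reports A `report_set`.
#' @return Character vector of demographic attribute names.
#' @export
report_schema <- function(reports) {
  attr(reports, "schema") %||% default_schema()
}

#' Read a de-normalized report table
#'
#' Reads the delimited dialect in which a report with m drugs and k symptoms
#' appears as up to m x k rows, and re-groups rows into report-level records
#' by distinct values (see [as_report_set()]).
#'
#' @param file Path to a comma- or tab-delimited text file with a header row.
#' @param delim Field delimiter; when `NULL` (default) it is sniffed from the
#'   header line (tab if present, else comma).
#' @inheritParams as_report_set
#' @return A `report_set` tibble.
#' @export
read_reports <- function(file, schema = default_schema(),
                         id_col = "Demo_key", date_col = NULL, delim = NULL) {
  if (is.null(delim)) {
    hdr <- readLines(file, n = 1L)
    delim <- if (length(hdr) > 0 && grepl("\t", hdr)) "\t" else ","
  }
  df <- readr::read_delim(file, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    return(new_report_set(empty_report_tbl(schema), schema))
  }
  as_report_set(df, schema = schema, id_col = id_col, date_col = date_col)
}

#' Write a report set in de-normalized form
#'
#' Expands each report to the full drug x symptom row cross-product, the
#' inverse of the grouping performed by [read_reports()].
#'
#' @param reports A `report_set`.
#' @param file Output path.
#' @param delim Field delimiter (default comma).
#' @param id_col Name used for the report-id column.
#' @return `file`, invisibly.
#' @export
write_reports <- function(reports, file, delim = ",", id_col = "Demo_key") {
  schema <- report_schema(reports)
  long <- denormalize_reports(reports, id_col = id_col)
  readr::write_delim(long, file, delim = delim)
  invisible(file)
}

#' Expand a report set to de-normalized rows
#'
#' @inheritParams write_reports
#' @return A tibble with one row per report x drug x symptom combination.
#' @export
denormalize_reports <- function(reports, id_col = "Demo_key") {
  schema <- report_schema(reports)
  nd <- lengths(reports$drugs)
  ns <- lengths(reports$symptoms)
  reps <- nd * ns
  idx <- rep(seq_len(nrow(reports)), reps)
  out <- tibble(!!id_col := reports$report_id[idx])
  for (at in schema) out[[at]] <- reports[[at]][idx]
  out$Drug <- unlist(purrr::map2(reports$drugs, ns, function(d, k) rep(d, each = k)),
                     use.names = FALSE) %||% character()
  out$PT <- unlist(purrr::map2(reports$symptoms, nd, function(s, m) rep(s, times = m)),
                   use.names = FALSE) %||% character()
  if (any(!is.na(reports$event_date))) {
    out$Event_Time <- as.character(reports$event_date[idx])
  }
  out
}

interval_labels <- function(edges) {
  f <- format(edges, trim = TRUE, scientific = FALSE)
  f <- sub("\\.0+$", "", f)
  k <- length(edges)
  c(paste0("~", f[1]),
    if (k > 1) paste0(f[-k], "~", f[-1]),
    paste0(f[k], "~"))
}

#' Bin continuous demographic attributes
#'
#' Replaces numeric values of continuous attributes (typically Age and
#' Weight) by half-open interval labels of the form `"lo~hi"`, with
#' open-ended boundary bins `"~e1"` and `"ek~"`. A value that already equals
#' one of the configured labels passes through unchanged, so binning is
#' idempotent.
#'
#' @param reports A `report_set`.
#' @param breaks Named list mapping attribute name to a strictly increasing
#'   numeric vector of interval edges `e1 < ... < ek`; the induced intervals
#'   are `(-Inf, e1)`, `[e1, e2)`, ..., `[ek, Inf)`.
#' @return A `report_set` with binned attribute values.
#' @examples
#' # age 17 with edges 1,4,7,14,20,60 falls in "14~20"
#' @export
bin_demographics <- function(reports, breaks) {
  schema <- report_schema(reports)
  for (at in names(breaks)) {
    if (!at %in% schema) {
      abort(paste0("unknown attribute in binning config: ", at),
            class = "adrmine_query_error")
    }
    edges <- as.numeric(breaks[[at]])
    if (any(diff(edges) <= 0)) {
      abort("binning edges must be strictly increasing",
            class = "adrmine_config_error")
    }
    labels <- interval_labels(edges)
    v <- reports[[at]]
    keep <- v %in% c(labels, MISSING_TOKEN)
    num <- suppressWarnings(as.numeric(v))
    bad <- !keep & is.na(num)
    if (any(bad)) {
      abort(paste0("cannot bin non-numeric value(s) for ", at, ": ",
                   paste(unique(v[bad]), collapse = ", ")),
            class = "adrmine_parse_error")
    }
    binned <- labels[findInterval(num, edges) + 1L]
    v[!keep] <- binned[!keep]
    reports[[at]] <- v
  }
  reports
}

#' Closed time interval
#'
#' @param start,end Dates (or strings coercible with [as.Date()]);
#'   `start <= end`, both inclusive.
#' @return A `time_interval` object.
#' @export
time_interval <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start > end) {
    abort("time_interval requires start <= end", class = "adrmine_config_error")
  }
  structure(list(start = start, end = end), class = "time_interval")
}

#' Filter reports by time and demographic constraints
#'
#' Keeps reports whose event date lies in *any* of the supplied intervals
#' (union semantics, so discontinuous report histories are expressible) and
#' which satisfy *all* demographic equality constraints. An empty interval
#' list applies no time filter; reports without an event date are dropped by
#' a time filter.
#'
#' @param reports A `report_set`.
#' @param intervals A [time_interval()], or list of them, or `NULL`.
#' @param constraints Named list/vector of demographic constraints,
#'   `attribute = value` (a vector of values means membership).
#' @return The filtered `report_set`.
#' @export
filter_reports <- function(reports, intervals = NULL, constraints = list()) {
  schema <- report_schema(reports)
  keep <- rep(TRUE, nrow(reports))
  if (!is.null(intervals)) {
    if (inherits(intervals, "time_interval")) intervals <- list(intervals)
    if (length(intervals) > 0) {
      in_any <- rep(FALSE, nrow(reports))
      for (iv in intervals) {
        stopifnot(inherits(iv, "time_interval"))
        in_any <- in_any | (!is.na(reports$event_date) &
                              reports$event_date >= iv$start &
                              reports$event_date <= iv$end)
      }
      keep <- keep & in_any
    }
  }
  if (length(constraints) > 0) {
    bad <- setdiff(names(constraints), schema)
    if (length(bad) > 0) {
      abort(paste0("unknown attribute(s) in constraint: ",
                   paste(bad, collapse = ", ")),
            class = "adrmine_query_error")
    }
    for (at in names(constraints)) {
      keep <- keep & reports[[at]] %in% constraints[[at]]
    }
  }
  out <- reports[keep, , drop = FALSE]
  new_report_set(out, schema)
}
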