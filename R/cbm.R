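#' Query specification for the signal miners
#'
#' Bundles everything a mining run needs: the mode, the demographic
#' attributes to stratify on, optional fixed drug/symptom, the measure and
#' its thresholds, the minimum case count, and optional top-k truncation.
#'
#' @param mode `"single-drug"` (cube-based miner) or `"drug-interaction"`
#'   (associative-classification miner).
#' @param attributes Demographic attributes the rule antecedents must
#'   instantiate (possibly empty).
#' @param measure Ranking measure: `"PRR"`, `"ROR"`, `"IC"`, `"MHRA"` or
#'   `"LEVERAGE"`.
#' @param min_count Minimum case count `a` for a rule (default 3).
#' @param top_k Optional cap on the number of returned signals.
#' @param thresholds Named list overriding measure cutoffs (see
#'   [evaluate_criterion()]).
#' @param fixed_drug,fixed_symptom Optional drug / symptom the rules must
#'   involve.
#' @param time_intervals List of [time_interval()] restricting the reports
#'   (union over intervals); empty list = no time filter.
#' @param zero_policy,ci_scale Passed to the measures; see [measures].
#' @param min_drugs Minimum number of drugs in a rule's exposure set;
#'   defaults to 2 in drug-interaction mode, 1 otherwise.
#' @param include_missing Should the reserved missing-value token be allowed
#'   as an antecedent value? Default `FALSE`.
#' @return A `query_spec` object.
#' @export
query_spec <- function(mode = c("single-drug", "drug-interaction"),
                       attributes = character(), measure = "PRR",
                       min_count = 3, top_k = NULL, thresholds = list(),
                       fixed_drug = NULL, fixed_symptom = NULL,
                       time_intervals = list(),
                       zero_policy = "background", ci_scale = "natural",
                       min_drugs = NULL, include_missing = FALSE) {
  mode <- match.arg(mode)
  measure <- toupper(measure)
  if (!measure %in% MEASURE_NAMES) {
    abort(paste0("unknown measure: ", measure), class = "adrmine_query_error")
  }
  if (min_count < 1) abort("min_count must be >= 1", class = "adrmine_query_error")
  if (!is.null(top_k) && top_k < 1) {
    abort("top_k must be >= 1", class = "adrmine_query_error")
  }
  if (inherits(time_intervals, "time_interval")) {
    time_intervals <- list(time_intervals)
  }
  structure(list(mode = mode, attributes = attributes, measure = measure,
                 min_count = as.integer(min_count), top_k = top_k,
                 thresholds = thresholds, fixed_drug = fixed_drug,
                 fixed_symptom = fixed_symptom,
                 time_intervals = time_intervals,
                 zero_policy = zero_policy, ci_scale = ci_scale,
                 min_drugs = min_drugs %||%
                   if (mode == "drug-interaction") 2L else 1L,
                 include_missing = include_missing),
            class = "query_spec")
}

#' @export
print.query_spec <- function(x, ...) {
  cat(sprintf("<query_spec> mode=%s attrs={%s} measure=%s min_count=%d%s\n",
              x$mode, paste(x$attributes, collapse = ","), x$measure,
              x$min_count,
              if (!is.null(x$top_k)) paste0(" top_k=", x$top_k) else ""))
  invisible(x)
}

check_query_attrs <- function(query, schema) {
  bad <- setdiff(query$attributes, schema)
  if (length(bad) > 0) {
    abort(paste0("unknown attribute(s) in query: ", paste(bad, collapse = ", ")),
          class = "adrmine_query_error")
  }
}

#' Generate candidate rules from a count cube
#'
#' Enumerates the cube cells in which every selected attribute takes a
#' concrete value (attributes not selected are marginalized with `"*"`),
#' drug and symptom are concrete (restricted to a fixed drug/symptom when the
#' query names one), and the case count `a` reaches `min_count`. By default
#' cells whose antecedent value is the reserved missing-value token are not
#' candidates.
#'
#' @param cube An [build_cube()] result whose demographic dimensions are the
#'   query's attributes.
#' @param query A [query_spec()].
#' @return A tibble with one row per candidate: one column per selected
#'   attribute, `drug`, `symptom`, `a`.
#' @export
generate_candidates <- function(cube, query) {
  stopifnot(inherits(cube, "adr_cube"), inherits(query, "query_spec"))
  attrs <- query$attributes
  if (!all(attrs %in% cube$demo_dims)) {
    abort("cube is missing query attributes", class = "adrmine_query_error")
  }
  cells <- dplyr::count(cube$long,
                        dplyr::across(dplyr::all_of(c(attrs, "Drug", "PT"))),
                        name = "a")
  if (!query$include_missing && length(attrs) > 0) {
    for (at in attrs) cells <- cells[cells[[at]] != MISSING_TOKEN, ]
  }
  if (!is.null(query$fixed_drug)) cells <- cells[cells$Drug %in% query$fixed_drug, ]
  if (!is.null(query$fixed_symptom)) cells <- cells[cells$PT %in% query$fixed_symptom, ]
  cells <- cells[cells$a >= query$min_count, , drop = FALSE]
  out <- dplyr::rename(cells, drug = "Drug", symptom = "PT")
  dplyr::arrange(out, dplyr::across(dplyr::all_of(c(attrs, "drug", "symptom"))))
}

# Vectorized contingency cells for candidate rows via grouped counts on the
# cube's long pair table; equals a per-candidate direct partition.
candidate_contingency <- function(cube, cands, attrs) {
  long <- cube$long
  grp_d <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(attrs, "Drug")))),
    n_drug = dplyr::n_distinct(.data$report_id), .groups = "drop")
  grp_s <- dplyr::summarise(
    dplyr::group_by(long, dplyr::across(dplyr::all_of(c(attrs, "PT")))),
    n_sym = dplyr::n_distinct(.data$report_id), .groups = "drop")
  if (length(attrs) > 0) {
    grp_c <- dplyr::summarise(
      dplyr::group_by(long, dplyr::across(dplyr::all_of(attrs))),
      n_con = dplyr::n_distinct(.data$report_id), .groups = "drop")
  } else {
    grp_c <- tibble(n_con = cube$n_reports)
  }
  out <- cands
  out <- dplyr::left_join(out, dplyr::rename(grp_d, drug = "Drug"),
                          by = c(attrs, "drug"))
  out <- dplyr::left_join(out, dplyr::rename(grp_s, symptom = "PT"),
                          by = c(attrs, "symptom"))
  if (length(attrs) > 0) {
    out <- dplyr::left_join(out, grp_c, by = attrs)
  } else {
    out$n_con <- grp_c$n_con
  }
  out$b <- out$n_drug - out$a
  out$c <- out$n_sym - out$a
  out$d <- out$n_con - out$n_drug - out$n_sym + out$a
  out$n_drug <- out$n_sym <- out$n_con <- NULL
  out
}

rank_signals <- function(df, query, attrs) {
  if (nrow(df) == 0) {
    df$rank <- integer()
    return(df)
  }
  ante <- if (length(attrs) > 0) {
    do.call(paste, c(lapply(attrs, function(at) df[[at]]), sep = "|"))
  } else rep("", nrow(df))
  drug_key <- purrr::map_chr(df$drugs, paste, collapse = "|")
  n_items <- lengths(df$drugs) + length(attrs)
  ord <- order(-df$value, -n_items, -df$a, ante, drug_key, df$symptom)
  df <- df[ord, , drop = FALSE]
  if (!is.null(query$top_k)) df <- head(df, query$top_k)
  df$rank <- seq_len(nrow(df))
  df
}

finalize_signals <- function(df, query, attrs, n_reports) {
  cols <- c("rank", attrs, "drugs", "symptom", "a", "b", "c", "d",
            "measure", "value", "lower_bound", "is_signal")
  df <- df[, cols, drop = FALSE]
  structure(df, query = query, n_reports = n_reports,
            class = c("adr_signals", class(tibble())))
}

empty_signals <- function(query, attrs, n_reports) {
  df <- tibble(rank = integer())
  for (at in attrs) df[[at]] <- character()
  df$drugs <- list(); df$symptom <- character()
  df$a <- df$b <- df$c <- df$d <- integer()
  df$measure <- character(); df$value <- df$lower_bound <- numeric()
  df$is_signal <- logical()
  finalize_signals(df, query, attrs, n_reports)
}

#' Cube-based mining of single-drug signals (CBM-SS)
#'
#' Runs the four-phase cube-based miner: (1) cube extraction over the
#' selected attributes plus Drug and PT on the time-filtered reports, (2)
#' candidate rule generation from cells with `a >= min_count`, (3)
#' contingency and measure calculation per candidate, (4) ranking by measure
#' value (descending) of the rules passing the measure's signal criterion,
#' truncated to `top_k` when set. Ties are broken by larger `a`, then
#' lexicographic antecedent. Candidates on which the measure is degenerate
#' (e.g. under the strict zero-cell policy) are dropped with a message.
#'
#' @param reports A `report_set`.
#' @param query A [query_spec()] with `mode = "single-drug"`.
#' @return An `adr_signals` tibble: `rank`, one column per selected
#'   attribute, `drugs` (list-column; singletons here), `symptom`, the cells
#'   `a, b, c, d`, `measure`, `value`, `lower_bound`, `is_signal`.
#' @examples
#' # run_cbm_ss(reports, query_spec("single-drug", attributes = "Age"))
#' @export
run_cbm_ss <- function(reports, query) {
  stopifnot(inherits(query, "query_spec"))
  if (query$mode != "single-drug") {
    abort("run_cbm_ss requires a single-drug query", class = "adrmine_query_error")
  }
  schema <- report_schema(reports)
  check_query_attrs(query, schema)
  attrs <- query$attributes
  reports <- filter_reports(reports, query$time_intervals)
  if (nrow(reports) == 0) return(empty_signals(query, attrs, 0L))
  cube <- build_cube(reports, c(attrs, "Drug", "PT"))
  cands <- generate_candidates(cube, query)
  if (nrow(cands) == 0) return(empty_signals(query, attrs, nrow(reports)))
  df <- candidate_contingency(cube, cands, attrs)
  mv <- measure_vec(df$a, df$b, df$c, df$d, query$measure,
                    zero_policy = query$zero_policy,
                    ci_scale = query$ci_scale, thresholds = query$thresholds)
  df <- dplyr::bind_cols(df, mv)
  if (any(df$degenerate)) {
    message(sum(df$degenerate), " candidate(s) dropped: measure degenerate")
    df <- df[!df$degenerate, , drop = FALSE]
  }
  df <- df[df$is_signal, , drop = FALSE]
  df$drugs <- as.list(df$drug)
  df$measure <- query$measure
  df <- rank_signals(df, query, attrs)
  finalize_signals(df, query, attrs, nrow(reports))
}

#' @export
`[.adr_signals` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    out <- structure(out, query = attr(x, "query"),
                     n_reports = attr(x, "n_reports"),
                     class = class(x))
  }
  out
}

#' @export
print.adr_signals <- function(x, ...) {
  q <- attr(x, "query")
  cat(sprintf("<adr_signals> %d signal(s) (%s, %s mode, %d report(s))\n",
              nrow(x), q$measure, q$mode, attr(x, "n_reports")))
  NextMethod()
}

#' @export
glance.adr_signals <- function(x, ...) {
  q <- attr(x, "query")
  tibble(n_signals = nrow(x), mode = q$mode, measure = q$measure,
         min_count = q$min_count, n_reports = attr(x, "n_reports"),
         max_value = if (nrow(x) > 0) max(x$value) else NA_real_)
}

#' @export
tidy.adr_signals <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "query") <- NULL
  attr(out, "n_reports") <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out$drugs <- purrr::map_chr(out$drugs, paste, collapse = ";")
  out
}

#' Write a signal table as delimited text
#'
#' @param x An `adr_signals` tibble.
#' @param file Output path.
#' @param delim Delimiter (default tab).
#' @return `file`, invisibly.
#' @export
write_signals <- function(x, file, delim = "\t") {
  readr::write_delim(tidy(x), file, delim = delim)
  invisible(file)
}

#' Plot a ranked signal table
#'
#' Draws the ranked rules as a horizontal lollipop chart of the measure
#' value, signals filled, with the case count mapped to point size.
#'
#' @param object An `adr_signals` tibble.
#' @param top Show at most this many rules (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adr_signals <- function(object, top = 20, ...) {
  q <- attr(object, "query")
  df <- tidy(head(object, top))
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No signals", x = NULL, y = NULL))
  }
  attrs <- intersect(q$attributes, names(df))
  ante <- if (length(attrs) > 0) {
    paste0(do.call(paste, c(lapply(attrs, function(at) paste0(at, "=", df[[at]])),
                            sep = ", ")), ", ")
  } else ""
  df$rule <- paste0(ante, "{", df$drugs, "} → ", df$symptom)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   y = stats::reorder(.data$rule, .data$value))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = stats::reorder(
      .data$rule, .data$value)), linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$a, colour = .data$is_signal)) +
    ggplot2::labs(x = q$measure, y = NULL, size = "a", colour = "signal") +
    ggplot2::theme_minimal()
}

#' Heatmap of drug-by-symptom report counts in a cube
#'
#' @param object An `adr_cube`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adr_cube <- function(object, ...) {
  df <- dplyr::count(object$long, .data$Drug, .data$PT, name = "reports")
  ggplot2::ggplot(df, ggplot2::aes(.data$PT, .data$Drug, fill = .data$reports)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "symptom (PT)", y = "drug") +
    ggplot2::theme_minimal()
}
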