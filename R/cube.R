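#' Build a report-level count cube
#'
#' Materializes report-level occurrence counts over the chosen dimensions.
#' The last two dimensions are always `Drug` and `PT`; the others are
#' demographic attributes of the schema. A cell addressed entirely by
#' concrete values counts the distinct reports matching all of them; the
#' margin token `"*"` ("any") matches every value, and marginal cells are
#' evaluated lazily by [cube_count()], so a report with several drugs or
#' symptoms contributes exactly once to any marginal cell it matches.
#'
#' @param reports A `report_set`.
#' @param dims Character vector of dimensions, a subset of the schema plus
#'   `Drug` and `PT` (both required; they are moved to the end).
#' @return An `adr_cube` object.
#' @examples
#' # cube over (Age, Drug, PT); cell (a2, d1, s1) counts reports with
#' # Age = a2 that mention drug d1 and symptom s1
#' @export
build_cube <- function(reports, dims = c(report_schema(reports), "Drug", "PT")) {
  schema <- report_schema(reports)
  bad <- setdiff(dims, c(schema, "Drug", "PT"))
  if (length(bad) > 0) {
    abort(paste0("unknown dimension(s): ", paste(bad, collapse = ", ")),
          class = "adrmine_query_error")
  }
  if (!all(c("Drug", "PT") %in% dims)) {
    abort("cube dimensions must include Drug and PT",
          class = "adrmine_query_error")
  }
  demo_dims <- setdiff(dims, c("Drug", "PT"))
  dims <- c(demo_dims, "Drug", "PT")
  long <- pair_long(reports, demo_dims)
  cells <- dplyr::count(long, dplyr::across(dplyr::all_of(dims)), name = "count")
  structure(list(dims = dims, demo_dims = demo_dims, reports = reports,
                 long = long, cells = cells, n_reports = nrow(reports)),
            class = "adr_cube")
}

# long table of distinct (report_id, demo dims..., Drug, PT) rows
pair_long <- function(reports, demo_dims) {
  nd <- lengths(reports$drugs)
  ns <- lengths(reports$symptoms)
  idx <- rep(seq_len(nrow(reports)), nd * ns)
  out <- tibble(report_id = reports$report_id[idx])
  for (at in demo_dims) out[[at]] <- reports[[at]][idx]
  out$Drug <- unlist(purrr::map2(reports$drugs, ns, function(d, k) rep(d, each = k)),
                     use.names = FALSE) %||% character()
  out$PT <- unlist(purrr::map2(reports$symptoms, nd, function(s, m) rep(s, times = m)),
                   use.names = FALSE) %||% character()
  out
}

#' @export
print.adr_cube <- function(x, ...) {
  cat(sprintf("<adr_cube> dims (%s) over %d report(s); %d concrete cell(s)\n",
              paste(x$dims, collapse = ", "), x$n_reports, nrow(x$cells)))
  invisible(x)
}

#' Query a single cube cell
#'
#' Returns the report-level count of a coordinate tuple. Coordinates may use
#' the margin token `"*"` at any position (including `Drug`/`PT` for pure
#' counting); the count always equals a fresh scan of the source reports.
#'
#' @param cube An `adr_cube`.
#' @param coords Character vector of coordinates, one per cube dimension,
#'   either positional or named by dimension; `"*"` means "any".
#' @return Integer count of distinct matching reports.
#' @export
cube_count <- function(cube, coords) {
  coords <- unlist(coords)
  if (length(coords) != length(cube$dims)) {
    abort(sprintf("expected %d coordinate(s), got %d",
                  length(cube$dims), length(coords)),
          class = "adrmine_query_error")
  }
  if (!is.null(names(coords)) && all(nzchar(names(coords)))) {
    bad <- setdiff(names(coords), cube$dims)
    if (length(bad) > 0) {
      abort(paste0("unknown dimension(s): ", paste(bad, collapse = ", ")),
            class = "adrmine_query_error")
    }
    coords <- coords[cube$dims]
  } else {
    names(coords) <- cube$dims
  }
  keep <- rep(TRUE, nrow(cube$long))
  for (d in cube$dims) {
    if (coords[[d]] != ANY_TOKEN) keep <- keep & cube$long[[d]] == coords[[d]]
  }
  dplyr::n_distinct(cube$long$report_id[keep])
}

#' Concrete cube cells as a long table
#'
#' @param cube An `adr_cube`.
#' @param file Optional path; when given, the table is written there as
#'   tab-delimited text (columns: one per dimension, then `count`).
#' @return A tibble of concrete cells and counts (invisibly when writing).
#' @export
cube_table <- function(cube, file = NULL) {
  if (!is.null(file)) {
    readr::write_delim(cube$cells, file, delim = "\t")
    return(invisible(cube$cells))
  }
  cube$cells
}

#' 2x2 contingency table for a (constraint, exposure, symptom) triple
#'
#' Constructs the table underlying every disproportionality measure:
#' among reports satisfying the demographic constraint, `a` reports mention
#' the exposure drug(s) and the symptom, `b` the drug(s) without the symptom,
#' `c` the symptom without the drug(s), and `d` neither.
#'
#' @param a,b,c,d Non-negative integer report counts.
#' @param constraint Named character vector of demographic conditions.
#' @param drugs Character vector of exposure drugs.
#' @param symptom Symptom (PT) identifier.
#' @return A `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d, constraint = NULL, drugs = NULL,
                              symptom = NULL) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("contingency cells must be non-negative", class = "adrmine_error")
  }
  structure(list(a = a, b = b, c = c, d = d, constraint = constraint,
                 drugs = drugs, symptom = symptom),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  hdr <- character()
  if (length(x$constraint) > 0) {
    hdr <- paste(paste0(names(x$constraint), "=", x$constraint), collapse = ", ")
  }
  cat("<contingency_table>",
      if (nzchar(paste(hdr, collapse = ""))) paste0(" [", hdr, "]"), "\n", sep = "")
  if (!is.null(x$drugs)) {
    cat(sprintf("  exposure: {%s} -> %s\n", paste(x$drugs, collapse = ", "),
                x$symptom %||% "?"))
  }
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug(s)", "other drugs"),
                              c("symptom", "other symptoms")))
  print(m)
  invisible(x)
}

#' @export
tidy.contingency_table <- function(x, ...) {
  tibble(a = x$a, b = x$b, c = x$c, d = x$d,
         n = x$a + x$b + x$c + x$d,
         constraint = if (length(x$constraint) > 0) {
           paste(paste0(names(x$constraint), "=", x$constraint), collapse = ",")
         } else "",
         drugs = paste(x$drugs %||% character(), collapse = ";"),
         symptom = x$symptom %||% NA_character_)
}

# report-level predicate counting over a report_set
count_reports <- function(reports, constraint = NULL, drugs = NULL,
                          symptom = NULL) {
  keep <- rep(TRUE, nrow(reports))
  for (at in names(constraint)) keep <- keep & reports[[at]] == constraint[[at]]
  if (!is.null(drugs) && length(drugs) > 0) {
    keep <- keep & purrr::map_lgl(reports$drugs, function(x) all(drugs %in% x))
  }
  if (!is.null(symptom)) {
    keep <- keep & purrr::map_lgl(reports$symptoms, function(x) symptom %in% x)
  }
  sum(keep)
}

#' Contingency table from a report set
#'
#' Computes the 2x2 cells from positive-item counts only:
#' `a = count(constraint, drugs, symptom)`, `b = count(constraint, drugs) - a`,
#' `c = count(constraint, symptom) - a`, `d = count(constraint) - a - b - c`.
#' Multi-drug exposure means the report contains *all* drugs of the set.
#'
#' @param reports A `report_set`.
#' @param constraint Named character vector of demographic equalities (may be
#'   empty for an unconstrained table).
#' @param drugs Character vector of exposure drugs (non-empty).
#' @param symptom Symptom (PT) identifier.
#' @return A `contingency_table`.
#' @export
contingency <- function(reports, constraint = NULL, drugs, symptom) {
  schema <- report_schema(reports)
  bad <- setdiff(names(constraint), schema)
  if (length(bad) > 0) {
    abort(paste0("unknown attribute(s) in constraint: ",
                 paste(bad, collapse = ", ")),
          class = "adrmine_query_error")
  }
  a <- count_reports(reports, constraint, drugs, symptom)
  nd <- count_reports(reports, constraint, drugs, NULL)
  ns <- count_reports(reports, constraint, NULL, symptom)
  n <- count_reports(reports, constraint, NULL, NULL)
  contingency_table(a, nd - a, ns - a, n - nd - ns + a,
                    constraint = constraint, drugs = drugs, symptom = symptom)
}

#' Contingency table from a count cube
#'
#' For a single exposure drug the four cells are assembled from cube counts
#' (the drug/PT coordinates stay concrete; unconstrained dimensions are
#' marginalized with `"*"`). For a drug *set*, reports containing all drugs
#' of the set are counted by a report scan, since atomic cube cells cannot
#' express conjunctions of drugs.
#'
#' @param cube An `adr_cube`.
#' @param constraint Named character vector over the cube's demographic
#'   dimensions.
#' @param drugs Exposure drug(s).
#' @param symptom Symptom (PT) identifier.
#' @return A `contingency_table`.
#' @export
contingency_from_cube <- function(cube, constraint = NULL, drugs, symptom) {
  bad <- setdiff(names(constraint), cube$demo_dims)
  if (length(bad) > 0) {
    abort(paste0("constraint attribute(s) not cube dimensions: ",
                 paste(bad, collapse = ", ")),
          class = "adrmine_query_error")
  }
  if (length(drugs) == 0 || any(drugs == ANY_TOKEN) || symptom == ANY_TOKEN) {
    abort("Drug and PT must be concrete in contingency extraction",
          class = "adrmine_query_error")
  }
  base <- setNames(rep(ANY_TOKEN, length(cube$dims)), cube$dims)
  base[names(constraint)] <- unlist(constraint)
  if (length(drugs) == 1) {
    cd <- base; cd["Drug"] <- drugs
    cds <- cd; cds["PT"] <- symptom
    cs <- base; cs["PT"] <- symptom
    a <- cube_count(cube, cds)
    nd <- cube_count(cube, cd)
    ns <- cube_count(cube, cs)
    n <- cube_count(cube, base)
  } else {
    a <- count_reports(cube$reports, constraint, drugs, symptom)
    nd <- count_reports(cube$reports, constraint, drugs, NULL)
    ns <- count_reports(cube$reports, constraint, NULL, symptom)
    n <- count_reports(cube$reports, constraint, NULL, NULL)
  }
  contingency_table(a, nd - a, ns - a, n - nd - ns + a,
                    constraint = constraint, drugs = drugs, symptom = symptom)
}
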