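#' Configuration of the synthetic report generator
#'
#' Describes an AERS-like spontaneous-report population: categorical
#' demographic domains with sampling probabilities, background per-report
#' inclusion probabilities for every drug and symptom, and a list of
#' injected drug(-set)-to-symptom associations of known strength that the
#' miners should recover.
#'
#' @param n_reports Number of reports to generate.
#' @param demographics Named list; each element a named probability vector
#'   over the attribute's categories (normalized internally).
#' @param drug_probs Named numeric vector: per-report inclusion probability
#'   of each drug (independent Bernoulli draws). Unnamed vectors are named
#'   `d1, d2, ...`.
#' @param symptom_probs Named numeric vector of background per-report
#'   symptom probabilities; unnamed vectors are named `s1, s2, ...`.
#' @param associations List of injected associations, each a list with
#'   fields `drugs` (character set), `symptom`, `rho` (risk multiplier > 0)
#'   and optional `stratum` (named demographic values). A report containing
#'   all drugs of the set (and matching the stratum, when given) has the
#'   symptom's probability multiplied by `rho`, capped at 1.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_reports, demographics = default_demographics(),
                       drug_probs, symptom_probs, associations = list(),
                       seed = 1L) {
  if (is.null(names(drug_probs))) {
    names(drug_probs) <- paste0("d", seq_along(drug_probs))
  }
  if (is.null(names(symptom_probs))) {
    names(symptom_probs) <- paste0("s", seq_along(symptom_probs))
  }
  stopifnot(n_reports >= 0, all(drug_probs >= 0 & drug_probs <= 1),
            all(symptom_probs >= 0 & symptom_probs <= 1))
  if (length(intersect(names(drug_probs), names(symptom_probs))) > 0) {
    abort("drug and symptom vocabularies must be disjoint",
          class = "adrmine_config_error")
  }
  if (all(drug_probs == 0) || all(symptom_probs == 0)) {
    abort("infeasible config: all inclusion probabilities are zero",
          class = "adrmine_config_error")
  }
  for (as_ in associations) {
    stopifnot(!is.null(as_$drugs), !is.null(as_$symptom), as_$rho > 0)
    if (!all(as_$drugs %in% names(drug_probs)) ||
        !as_$symptom %in% names(symptom_probs)) {
      abort("association references unknown drug or symptom",
            class = "adrmine_config_error")
    }
  }
  structure(list(n_reports = as.integer(n_reports),
                 demographics = lapply(demographics, function(p) p / sum(p)),
                 drug_probs = drug_probs, symptom_probs = symptom_probs,
                 associations = associations, seed = as.integer(seed)),
            class = "sim_config")
}

default_demographics <- function() {
  list(Year = c(y1 = 0.4, y2 = 0.3, y3 = 0.3),
       Age = c(a1 = 0.2, a2 = 0.3, a3 = 0.3, a4 = 0.2),
       Gender = c(g1 = 0.5, g2 = 0.5),
       Weight = c(w1 = 0.3, w2 = 0.4, w3 = 0.3),
       Country = c(c1 = 0.5, c2 = 0.3, c3 = 0.2))
}

#' Read a generator configuration from JSON
#'
#' @param file Path to a JSON file with fields matching [sim_config()]
#'   (`associations` as an array of objects).
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  assoc <- cfg$associations
  if (is.data.frame(assoc)) {
    assoc <- lapply(seq_len(nrow(assoc)), function(i) {
      row <- as.list(assoc[i, ])
      row$drugs <- unlist(row$drugs)
      if (!is.null(row$stratum)) row$stratum <- unlist(row$stratum)
      row
    })
  }
  sim_config(n_reports = cfg$n_reports,
             demographics = lapply(cfg$demographics, unlist),
             drug_probs = unlist(cfg$drug_probs),
             symptom_probs = unlist(cfg$symptom_probs),
             associations = assoc %||% list(),
             seed = cfg$seed %||% 1L)
}

#' Generate a synthetic report set
#'
#' Samples `n_reports` reports: demographics independently per report from
#' the configured category probabilities; each drug by an independent
#' Bernoulli draw; each symptom with probability `p_s` multiplied by the
#' `rho` of every injected association whose drug set is contained in the
#' report's drugs (and whose stratum, if any, matches), capped at 1.
#' Empty drug or symptom groups are resampled so every report carries at
#' least one of each. Fully deterministic given the config's seed; the
#' global RNG state is left untouched.
#'
#' @param config A [sim_config()].
#' @return A `report_set`.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  schema <- names(config$demographics)
  n <- config$n_reports
  if (n == 0) return(new_report_set(empty_report_tbl(schema), schema))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  out <- tibble(report_id = as.character(seq_len(n)))
  for (at in schema) {
    p <- config$demographics[[at]]
    out[[at]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  dp <- config$drug_probs
  dmat <- matrix(stats::runif(n * length(dp)) < rep(dp, each = n), nrow = n,
                 dimnames = list(NULL, names(dp)))
  empty <- which(rowSums(dmat) == 0)
  if (length(empty) > 0) {
    forced <- sample(names(dp), length(empty), replace = TRUE,
                     prob = dp / sum(dp))
    dmat[cbind(empty, match(forced, colnames(dmat)))] <- TRUE
  }
  sp <- config$symptom_probs
  pm <- matrix(rep(sp, each = n), nrow = n, dimnames = list(NULL, names(sp)))
  for (as_ in config$associations) {
    hit <- rowSums(dmat[, as_$drugs, drop = FALSE]) == length(as_$drugs)
    if (!is.null(as_$stratum)) {
      for (at in names(as_$stratum)) {
        hit <- hit & out[[at]] == as_$stratum[[at]]
      }
    }
    pm[hit, as_$symptom] <- pmin(1, pm[hit, as_$symptom] * as_$rho)
  }
  smat <- matrix(stats::runif(length(pm)) < pm, nrow = n,
                 dimnames = dimnames(pm))
  # resample empty symptom groups under the same per-report probabilities
  for (iter in 1:1000) {
    empty <- which(rowSums(smat) == 0)
    if (length(empty) == 0) break
    if (all(rowSums(pm[empty, , drop = FALSE]) == 0)) {
      abort("infeasible config: reports with zero symptom probability",
            class = "adrmine_config_error")
    }
    sub <- pm[empty, , drop = FALSE]
    smat[empty, ] <- matrix(stats::runif(length(sub)) < sub, nrow = length(empty))
  }
  if (any(rowSums(smat) == 0)) {
    abort("failed to draw a non-empty symptom set; probabilities too small",
          class = "adrmine_config_error")
  }
  out$drugs <- logical_rows_to_sets(dmat)
  out$symptoms <- logical_rows_to_sets(smat)
  out$event_date <- as.Date(rep(NA_character_, n))
  new_report_set(out, schema)
}

logical_rows_to_sets <- function(mat) {
  idx <- which(mat, arr.ind = TRUE)
  nm <- colnames(mat)[idx[, "col"]]
  sets <- split(nm, factor(idx[, "row"], levels = seq_len(nrow(mat))))
  unname(lapply(sets, function(x) sort(unique(x))))
}
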