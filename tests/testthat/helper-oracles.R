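# Brute-force oracles, independent of the package's cube / tree code paths.
# They operate on a plain list-of-reports representation built directly from
# de-normalized rows with base R.

table5_df <- function() {
  read.csv(system.file("extdata", "table5.csv", package = "adrmine"),
           colClasses = "character")
}

table5_reports <- function() {
  read_reports(system.file("extdata", "table5.csv", package = "adrmine"))
}

# plain representation: list of list(demo = named chr, drugs, symptoms)
o_group <- function(df, schema = c("Year", "Age", "Gender", "Weight", "Country"),
                    id_col = "Demo_key") {
  ids <- unique(df[[id_col]])
  lapply(ids, function(i) {
    rows <- df[df[[id_col]] == i, , drop = FALSE]
    list(id = as.character(i),
         demo = vapply(schema, function(at) as.character(rows[[at]][1]), ""),
         drugs = sort(unique(as.character(rows$Drug))),
         symptoms = sort(unique(as.character(rows$PT))))
  })
}

o_reports <- function(rs) {
  # plain representation from a report_set (field extraction only)
  schema <- report_schema(rs)
  lapply(seq_len(nrow(rs)), function(i) {
    list(id = rs$report_id[i],
         demo = vapply(schema, function(at) rs[[at]][i], ""),
         drugs = rs$drugs[[i]], symptoms = rs$symptoms[[i]])
  })
}

o_match <- function(rep, constraint = NULL, drugs = NULL, symptom = NULL) {
  ok <- TRUE
  for (at in names(constraint)) ok <- ok && rep$demo[[at]] == constraint[[at]]
  if (!is.null(drugs)) ok <- ok && all(drugs %in% rep$drugs)
  if (!is.null(symptom)) ok <- ok && symptom %in% rep$symptoms
  ok
}

o_count <- function(reps, constraint = NULL, drugs = NULL, symptom = NULL) {
  sum(vapply(reps, o_match, TRUE, constraint, drugs, symptom))
}

# direct four-way partition of the constrained reports
o_contingency <- function(reps, constraint, drugs, symptom) {
  sub <- Filter(function(r) o_match(r, constraint), reps)
  exp_ <- vapply(sub, function(r) all(drugs %in% r$drugs), TRUE)
  sym_ <- vapply(sub, function(r) symptom %in% r$symptoms, TRUE)
  c(a = sum(exp_ & sym_), b = sum(exp_ & !sym_),
    c = sum(!exp_ & sym_), d = sum(!exp_ & !sym_))
}

# enumerate all (attribute-value combo, drug, symptom) candidates with
# a >= min_count; cells by direct partition
o_cbm_candidates <- function(reps, attributes, min_count,
                             include_missing = FALSE) {
  drugs <- sort(unique(unlist(lapply(reps, `[[`, "drugs"))))
  syms <- sort(unique(unlist(lapply(reps, `[[`, "symptoms"))))
  combos <- list(stats::setNames(character(0), character(0)))
  for (at in attributes) {
    vals <- sort(unique(vapply(reps, function(r) r$demo[[at]], "")))
    if (!include_missing) vals <- setdiff(vals, missing_token())
    combos <- unlist(lapply(combos, function(cm) {
      lapply(vals, function(v) c(cm, stats::setNames(v, at)))
    }), recursive = FALSE)
  }
  out <- list()
  for (cm in combos) for (d in drugs) for (s in syms) {
    cells <- o_contingency(reps, cm, d, s)
    if (cells[["a"]] >= min_count) {
      out[[length(out) + 1L]] <- list(constraint = cm, drug = d, symptom = s,
                                      cells = cells)
    }
  }
  out
}

o_cand_key <- function(x) {
  paste(paste(names(x$constraint), unlist(x$constraint), sep = "=",
              collapse = ","), x$drug, x$symptom, sep = " | ")
}

# exhaustive (itemset, label) support over transactions: enumerate every
# non-empty subset of each transaction's items
o_patterns <- function(items_list, labels_list, min_count) {
  env <- new.env(parent = emptyenv())
  for (i in seq_along(items_list)) {
    it <- items_list[[i]]
    if (length(it) == 0) next
    n <- length(it)
    for (mask in 1:(2^n - 1)) {
      sub <- sort(it[bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1)) > 0])
      for (s in labels_list[[i]]) {
        key <- paste(paste(sub, collapse = ","), s, sep = " :: ")
        env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
      }
    }
  }
  keys <- ls(env)
  counts <- vapply(keys, function(k) env[[k]], 0L)
  keep <- counts >= min_count
  sort(paste0(keys[keep], " = ", counts[keep]))
}

pattern_key <- function(items, symptom, count) {
  paste0(paste(sort(items), collapse = ","), " :: ", symptom, " = ", count)
}

# small random warehouses for property tests
random_reports <- function(seed, n = 60, n_drugs = 6, n_syms = 4,
                           p_drug = 0.3, p_sym = 0.35) {
  cfg <- sim_config(
    n_reports = n,
    demographics = list(Age = c(a1 = 0.4, a2 = 0.4, a3 = 0.2),
                        Gender = c(g1 = 0.5, g2 = 0.5)),
    drug_probs = stats::setNames(rep(p_drug, n_drugs), paste0("d", seq_len(n_drugs))),
    symptom_probs = stats::setNames(rep(p_sym, n_syms), paste0("s", seq_len(n_syms))),
    seed = seed)
  generate_reports(cfg)
}
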