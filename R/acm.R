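#' Itemized transactions for associative-classification mining
#'
#' The offline stage of the multidrug miner turns each report into a
#' transaction: its demographic attribute=value items and drug items, kept
#' only when frequent (report-level support `>= min_count`), ordered by
#' decreasing support, with the report's frequent symptoms as class labels.
#' Items are written `"Attr=value"` (e.g. `"Age=a2"`, `"Drug=d1"`).
#'
#' Equal-support items are ordered by schema attribute precedence (the
#' schema order, then Drug), then by value. Transactions left without any
#' frequent symptom label are eliminated. The result is query-independent
#' and cacheable; the online stage prunes it per query.
#'
#' @param reports A `report_set`.
#' @param min_count Report-level support threshold (default 3).
#' @param include_missing Keep items for the reserved missing-value token?
#'   Default `FALSE`.
#' @return An `adr_transactions` object: a tibble with columns `tid`,
#'   `items` (list of ordered item strings) and `labels` (list of symptom
#'   strings), carrying the `item_order` table as an attribute.
#' @export
build_transactions <- function(reports, min_count = 3, include_missing = FALSE) {
  schema <- report_schema(reports)
  n <- nrow(reports)
  # report-level supports
  demo_items <- list()
  for (at in schema) {
    tab <- table(reports[[at]])
    if (!include_missing) tab <- tab[names(tab) != MISSING_TOKEN]
    if (length(tab) > 0) {
      demo_items[[at]] <- tibble(attr = at, value = names(tab),
                                 support = as.integer(tab))
    }
  }
  drug_tab <- table(unlist(lapply(reports$drugs, unique), use.names = FALSE))
  sym_tab <- table(unlist(lapply(reports$symptoms, unique), use.names = FALSE))
  items <- dplyr::bind_rows(c(demo_items, list(
    tibble(attr = "Drug", value = names(drug_tab),
           support = as.integer(drug_tab)))))
  if (nrow(items) == 0) items <- tibble(attr = character(),
                                        value = character(),
                                        support = integer())
  items <- items[items$support >= min_count, , drop = FALSE]
  prec <- match(items$attr, c(schema, "Drug"))
  ord <- order(-items$support, prec, items$value)
  items <- items[ord, , drop = FALSE]
  items$item <- paste0(items$attr, "=", items$value)
  items$position <- seq_len(nrow(items))
  item_order <- items[, c("item", "attr", "value", "support", "position")]
  freq_syms <- names(sym_tab)[as.integer(sym_tab) >= min_count]

  pos <- setNames(item_order$position, item_order$item)
  tx_items <- vector("list", n)
  tx_labels <- vector("list", n)
  for (i in seq_len(n)) {
    it <- c(paste0(schema, "=", unlist(reports[i, schema])),
            paste0("Drug=", reports$drugs[[i]]))
    it <- it[it %in% item_order$item]
    tx_items[[i]] <- it[order(pos[it])]
    tx_labels[[i]] <- intersect(reports$symptoms[[i]], freq_syms)
  }
  keep <- lengths(tx_labels) > 0
  out <- tibble(tid = reports$report_id[keep],
                items = tx_items[keep], labels = tx_labels[keep])
  new_transactions(out, item_order, min_count, schema)
}

new_transactions <- function(tbl, item_order, min_count, schema) {
  structure(as_tibble(tbl), item_order = item_order,
            min_count = min_count, schema = schema,
            class = c("adr_transactions", class(tibble())))
}

#' Item frequency order of a transaction set
#'
#' @param ts An `adr_transactions` object.
#' @return Tibble with columns `item`, `attr`, `value`, `support`,
#'   `position` (ascending = more frequent first).
#' @export
item_order <- function(ts) attr(ts, "item_order")

#' @export
`[.adr_transactions` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    out <- new_transactions(out, attr(x, "item_order"),
                            attr(x, "min_count"), attr(x, "schema"))
  }
  out
}

#' @export
print.adr_transactions <- function(x, ...) {
  cat(sprintf("<adr_transactions> %d transaction(s), %d frequent item(s) (min_count=%d)\n",
              nrow(x), nrow(item_order(x)), attr(x, "min_count")))
  NextMethod()
}

#' Serialize / restore a reduced transaction set
#'
#' The offline stage's cache format: a tab-delimited file with columns
#' `tid`, `items` (comma-joined, in order) and `labels` (comma-joined),
#' preceded by the item-order table in a commented header.
#'
#' @param ts An `adr_transactions` object.
#' @param file Path.
#' @return `file` invisibly / the restored `adr_transactions`.
#' @export
write_transactions <- function(ts, file) {
  io <- item_order(ts)
  hdr <- c(sprintf("# min_count=%d", attr(ts, "min_count")),
           sprintf("# schema=%s", paste(attr(ts, "schema"), collapse = ",")),
           sprintf("# item\t%s\t%d", io$item, io$support))
  body <- c("tid\titems\tlabels",
            sprintf("%s\t%s\t%s", ts$tid,
                    purrr::map_chr(ts$items, paste, collapse = ","),
                    purrr::map_chr(ts$labels, paste, collapse = ",")))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' @rdname write_transactions
#' @export
read_transactions <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  min_count <- as.integer(sub("# min_count=", "", hdr[1], fixed = TRUE))
  schema <- strsplit(sub("# schema=", "", hdr[2], fixed = TRUE), ",")[[1]]
  io_lines <- hdr[startsWith(hdr, "# item\t")]
  parts <- strsplit(sub("^# item\t", "", io_lines), "\t")
  item <- purrr::map_chr(parts, 1)
  support <- as.integer(purrr::map_chr(parts, 2))
  av <- strsplit(item, "=", fixed = TRUE)
  io <- tibble(item = item, attr = purrr::map_chr(av, 1),
               value = purrr::map_chr(av, 2), support = support,
               position = seq_along(item))
  rows <- strsplit(body[-1], "\t")
  split_csv <- function(x) if (is.na(x) || x == "") character() else
    strsplit(x, ",", fixed = TRUE)[[1]]
  tbl <- tibble(tid = purrr::map_chr(rows, 1),
                items = lapply(purrr::map_chr(rows, function(r) if (length(r) >= 2) r[2] else ""), split_csv),
                labels = lapply(purrr::map_chr(rows, function(r) if (length(r) >= 3) r[3] else ""), split_csv))
  new_transactions(tbl, io, min_count, schema)
}

#' Prune transactions for a query (online stage)
#'
#' Removes demographic items whose attribute is not selected by the query;
#' drug items are always retained (restricted to the fixed drug when the
#' query names one), labels are restricted to the fixed symptom when given.
#' A transaction is eliminated when the query selects attributes but the
#' transaction retains no item of any selected attribute, or when it has no
#' label left. The input transaction set is never modified.
#'
#' @param ts An `adr_transactions` object.
#' @param query A [query_spec()].
#' @return A pruned `adr_transactions` object.
#' @export
prune_transactions <- function(ts, query) {
  io <- item_order(ts)
  attrs <- query$attributes
  keep_item <- io$attr == "Drug" | io$attr %in% attrs
  if (!is.null(query$fixed_drug)) {
    keep_item <- keep_item & (io$attr != "Drug" | io$value %in% query$fixed_drug)
  }
  allowed <- io$item[keep_item]
  items <- lapply(ts$items, function(x) x[x %in% allowed])
  labels <- ts$labels
  if (!is.null(query$fixed_symptom)) {
    labels <- lapply(labels, intersect, y = query$fixed_symptom)
  }
  keep <- lengths(labels) > 0
  if (length(attrs) > 0) {
    sel_items <- io$item[io$attr %in% attrs]
    keep <- keep & purrr::map_lgl(items, function(x) any(x %in% sel_items))
  }
  out <- tibble(tid = ts$tid[keep], items = items[keep], labels = labels[keep])
  new_transactions(out, io, attr(ts, "min_count"), attr(ts, "schema"))
}

#' Build a CR-tree from ordered transactions
#'
#' Inserts each transaction's frequency-ordered item list as a root path
#' with count accumulation; after the last item a symptom leaf per class
#' label accumulates one count. A header table threads each item's nodes in
#' insertion order. Transactions whose items violate the global frequency
#' order are an integrity error.
#'
#' @param ts An `adr_transactions` object.
#' @return A `cr_tree` object.
#' @export
build_cr_tree <- function(ts) {
  io <- item_order(ts)
  pos <- setNames(io$position, io$item)
  env <- new.env(parent = emptyenv())
  env$item <- NA_character_   # node 1 = root
  env$count <- 0L
  env$parent <- 0L
  env$children <- list(integer())      # named int vectors
  env$leaf <- list(numeric())          # named numeric: symptom -> count
  add_node <- function(parent, item) {
    id <- length(env$item) + 1L
    env$item[id] <- item
    env$count[id] <- 0L
    env$parent[id] <- parent
    env$children[[id]] <- integer()
    env$leaf[[id]] <- numeric()
    env$children[[parent]] <- c(env$children[[parent]], setNames(id, item))
    id
  }
  header <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ts))) {
    it <- ts$items[[i]]
    p <- pos[it]
    if (anyNA(p) || is.unsorted(p, strictly = TRUE)) {
      abort(paste0("transaction ", ts$tid[i],
                   " is not in global item order"),
            class = "adrmine_integrity_error")
    }
    node <- 1L
    for (x in it) {
      child <- env$children[[node]][x]
      if (is.na(child)) {
        child <- add_node(node, x)
        header[[x]] <- c(header[[x]], child)
      }
      env$count[child] <- env$count[child] + 1L
      node <- child
    }
    for (s in ts$labels[[i]]) {
      cur <- env$leaf[[node]][s]
      env$leaf[[node]][s] <- if (is.na(cur)) 1 else cur + 1
    }
  }
  structure(list(item = env$item, count = env$count, parent = env$parent,
                 children = env$children, leaf = env$leaf,
                 header = as.list(header), item_order = io,
                 n_transactions = nrow(ts)),
            class = "cr_tree")
}

#' @export
print.cr_tree <- function(x, ...) {
  cat(sprintf("<cr_tree> %d node(s) over %d transaction(s); %d item(s) in header\n",
              length(x$item) - 1L, x$n_transactions, length(x$header)))
  invisible(x)
}

# walk a node's item path back to the root (root excluded), most-frequent
# item first
node_path <- function(tree, id) {
  out <- character()
  while (id > 1L) {
    out <- c(tree$item[id], out)
    id <- tree$parent[id]
  }
  out
}

# weighted FP-growth over integer-coded transactions (ascending positions).
# Accumulates (itemset, count) pairs into `acc` (an environment with a list).
fp_grow <- function(trans, w, min_count, suffix, acc) {
  supp <- tapply(rep(w, lengths(trans)), unlist(trans), sum)
  freq <- as.integer(names(supp))[supp >= min_count]
  if (length(freq) == 0) return(invisible())
  supp <- supp[as.character(freq)]
  for (i in freq[order(supp, freq, decreasing = c(FALSE, TRUE), method = "radix")]) {
    pat <- c(i, suffix)
    acc$res[[length(acc$res) + 1L]] <- list(items = pat,
                                            count = as.integer(supp[[as.character(i)]]))
    hit <- purrr::map_lgl(trans, function(x) i %in% x)
    cond <- lapply(trans[hit], function(x) x[x < i])
    keep <- lengths(cond) > 0
    if (any(keep)) fp_grow(cond[keep], w[hit][keep], min_count, pat, acc)
  }
  invisible()
}

#' Mine frequent labeled patterns from a CR-tree
#'
#' Returns exactly the set of triples (itemset `I`, symptom `s`, count `n`)
#' with `I` a non-empty set of non-symptom items, `n` the number of
#' transactions containing all of `I` and labeled `s`, and `n >= min_count`.
#' Patterns are grown recursively from conditional pattern bases
#' (least-frequent suffix item first), the projections being recovered from
#' the tree's symptom leaves and prefix paths.
#'
#' @param tree A `cr_tree`.
#' @param min_count Minimum pattern count.
#' @return A tibble with columns `items` (list of item strings, in global
#'   frequency order), `symptom`, `count`.
#' @export
mine_patterns <- function(tree, min_count = 3) {
  io <- tree$item_order
  pos <- setNames(io$position, io$item)
  # recover weighted labeled prefix paths from the symptom leaves
  paths <- list(); weights <- numeric(); labels <- character()
  for (id in seq_along(tree$leaf)) {
    lv <- tree$leaf[[id]]
    if (length(lv) == 0) next
    p <- unname(pos[node_path(tree, id)])
    for (s in names(lv)) {
      paths[[length(paths) + 1L]] <- p
      weights[length(weights) + 1L] <- lv[[s]]
      labels[length(labels) + 1L] <- s
    }
  }
  out <- list()
  for (s in unique(labels)) {
    sel <- labels == s
    tr <- paths[sel]; w <- weights[sel]
    nonempty <- lengths(tr) > 0
    acc <- new.env(parent = emptyenv()); acc$res <- list()
    if (any(nonempty)) fp_grow(tr[nonempty], w[nonempty], min_count,
                               integer(), acc)
    if (length(acc$res) > 0) {
      out[[s]] <- tibble(
        items = lapply(acc$res, function(r) io$item[sort(r$items)]),
        symptom = s,
        count = purrr::map_int(acc$res, "count"))
    }
  }
  if (length(out) == 0) {
    return(tibble(items = list(), symptom = character(), count = integer()))
  }
  res <- dplyr::bind_rows(out)
  res[order(purrr::map_chr(res$items, paste, collapse = "|"), res$symptom), ]
}

#' Associative-classification mining of multidrug signals (ACM-MS)
#'
#' Chains the four phases of the multidrug miner: the offline data
#' transformation ([build_transactions()], reusable via `transactions`),
#' query pruning ([prune_transactions()]), CR-tree construction and
#' FP-growth pattern mining, then the signal phase: patterns must carry at
#' least one item of *each* selected attribute and at least `min_drugs` drug
#' items (default 2 in drug-interaction mode); each surviving pattern is
#' scored on a contingency table computed over the **full** report set
#' (constraint = the pattern's demographic items, exposure = its drug set),
#' filtered by the measure's signal criterion, and ranked by measure value
#' (descending), then antecedent size (descending).
#'
#' @param reports A `report_set` (the full warehouse; also used for the
#'   final contingency counts).
#' @param query A [query_spec()] (typically `mode = "drug-interaction"`).
#' @param transactions Optional cached result of [build_transactions()] for
#'   these reports.
#' @return An `adr_signals` tibble (see [run_cbm_ss()]); `drugs` holds the
#'   full exposure drug set.
#' @export
run_acm_ms <- function(reports, query, transactions = NULL) {
  stopifnot(inherits(query, "query_spec"))
  schema <- report_schema(reports)
  check_query_attrs(query, schema)
  attrs <- query$attributes
  reports <- filter_reports(reports, query$time_intervals)
  if (nrow(reports) == 0) return(empty_signals(query, attrs, 0L))
  ts <- transactions %||% build_transactions(reports, query$min_count)
  pruned <- prune_transactions(ts, query)
  if (nrow(pruned) == 0) return(empty_signals(query, attrs, nrow(reports)))
  tree <- build_cr_tree(pruned)
  pats <- mine_patterns(tree, query$min_count)
  if (nrow(pats) == 0) return(empty_signals(query, attrs, nrow(reports)))
  io <- item_order(ts)
  attr_of <- setNames(io$attr, io$item)
  val_of <- setNames(io$value, io$item)
  keep <- purrr::map_lgl(pats$items, function(it) {
    ats <- attr_of[it]
    all(attrs %in% ats) && sum(ats == "Drug") >= query$min_drugs
  })
  if (!is.null(query$fixed_symptom)) {
    keep <- keep & pats$symptom %in% query$fixed_symptom
  }
  if (!is.null(query$fixed_drug)) {
    keep <- keep & purrr::map_lgl(pats$items, function(it) {
      any(attr_of[it] == "Drug" & val_of[it] %in% query$fixed_drug)
    })
  }
  pats <- pats[keep, , drop = FALSE]
  if (nrow(pats) == 0) return(empty_signals(query, attrs, nrow(reports)))
  rows <- purrr::pmap(list(pats$items, pats$symptom), function(it, s) {
    ats <- attr_of[it]
    constraint <- setNames(val_of[it][ats != "Drug"], ats[ats != "Drug"])
    drugs <- unname(val_of[it][ats == "Drug"])
    ct <- contingency(reports, constraint, drugs, s)
    out <- tibble(a = ct$a, b = ct$b, c = ct$c, d = ct$d,
                  drugs = list(sort(drugs)), symptom = s)
    for (at in attrs) out[[at]] <- unname(constraint[at])
    out
  })
  df <- dplyr::bind_rows(rows)
  mv <- measure_vec(df$a, df$b, df$c, df$d, query$measure,
                    zero_policy = query$zero_policy,
                    ci_scale = query$ci_scale, thresholds = query$thresholds)
  df <- dplyr::bind_cols(df, mv)
  if (any(df$degenerate)) {
    message(sum(df$degenerate), " pattern(s) dropped: measure degenerate")
    df <- df[!df$degenerate, , drop = FALSE]
  }
  df <- df[df$is_signal & df$a >= query$min_count, , drop = FALSE]
  df$measure <- query$measure
  df <- rank_signals(df, query, attrs)
  finalize_signals(df, query, attrs, nrow(reports))
}
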