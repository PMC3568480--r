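items_str <- function(ts) purrr::map_chr(ts$items, paste, collapse = ",")

test_that("offline reduction reproduces the printed supports and order", {
  ts <- build_transactions(table5_reports(), 3)
  io <- item_order(ts)
  expect_equal(io$item,
               c("Age=a2", "Weight=w2", "Drug=d2", "Drug=d3",
                 "Year=y1", "Gender=g1", "Gender=g2", "Drug=d1"))
  expect_equal(io$support, c(4, 4, 4, 4, 3, 3, 3, 3))
  expect_equal(nrow(ts), 4)
  expect_equal(ts$tid, c("1", "3", "4", "5"))
  expect_equal(items_str(ts), c(
    "Age=a2,Weight=w2,Drug=d2,Drug=d3,Gender=g1,Drug=d1",
    "Age=a2,Weight=w2,Drug=d3,Gender=g2,Drug=d1",
    "Age=a2,Drug=d3,Year=y1,Gender=g1,Drug=d1",
    "Drug=d2,Year=y1,Gender=g2"))
  expect_true(all(purrr::map_chr(ts$labels, paste, collapse = ",") == "s1"))
})

test_that("min_count 1 keeps every report and item", {
  r <- table5_reports()
  ts <- build_transactions(r, 1)
  expect_equal(nrow(ts), 6)
  # each transaction carries all of its report's demographic + drug items
  n_items <- lengths(r$drugs) + length(report_schema(r))
  expect_equal(lengths(ts$items)[match(r$report_id, ts$tid)], n_items)
})

test_that("item supports equal a brute-force counter on random data", {
  for (seed in 61:63) {
    r <- random_reports(seed, n = 50)
    ts <- build_transactions(r, 3)
    io <- item_order(ts)
    reps <- o_reports(r)
    for (i in seq_len(nrow(io))) {
      expected <- if (io$attr[i] == "Drug") {
        o_count(reps, drugs = io$value[i])
      } else {
        o_count(reps, constraint = stats::setNames(list(io$value[i]), io$attr[i]))
      }
      expect_equal(io$support[i], expected, info = io$item[i])
    }
    expect_false(is.unsorted(-io$support))
  }
})

test_that("query pruning reproduces the printed pruned transactions", {
  ts <- build_transactions(table5_reports(), 3)
  q <- query_spec("drug-interaction", attributes = "Age")
  p <- prune_transactions(ts, q)
  expect_equal(p$tid, c("1", "3", "4"))      # tid 5 has no Age item
  expect_equal(items_str(p), c("Age=a2,Drug=d2,Drug=d3,Drug=d1",
                               "Age=a2,Drug=d3,Drug=d1",
                               "Age=a2,Drug=d3,Drug=d1"))
  # no selected attributes: nothing is "unrelated", drug items only
  p0 <- prune_transactions(ts, query_spec("drug-interaction"))
  expect_equal(nrow(p0), 4)
  expect_true(all(grepl("^Drug=", unlist(p0$items))))
  # pruning never mutates the cached offline transactions
  ts2 <- build_transactions(table5_reports(), 3)
  expect_equal(items_str(ts), items_str(ts2))
})

test_that("the CR-tree merges ordered prefixes with counts and leaves", {
  ts <- build_transactions(table5_reports(), 3)
  p <- prune_transactions(ts, query_spec("drug-interaction", attributes = "Age"))
  tree <- build_cr_tree(p)
  root_children <- tree$children[[1]]
  expect_equal(names(root_children), "Age=a2")
  a2 <- root_children[["Age=a2"]]
  expect_equal(tree$count[a2], 3)
  kids <- tree$children[[a2]]
  expect_setequal(names(kids), c("Drug=d2", "Drug=d3"))
  expect_equal(tree$count[kids[["Drug=d2"]]], 1)
  expect_equal(tree$count[kids[["Drug=d3"]]], 2)
  # the d3-branch path ends in a leaf counting 2 transactions labeled s1
  d3 <- kids[["Drug=d3"]]
  d1 <- tree$children[[d3]][["Drug=d1"]]
  expect_equal(tree$leaf[[d1]][["s1"]], 2)
  # conservation: root children counts sum to the transaction count
  expect_equal(sum(tree$count[tree$children[[1]]]), nrow(p))
  # single transaction -> a single chain of count-1 nodes
  t1 <- build_cr_tree(p[1, ])
  expect_true(all(t1$count[-1] == 1))
})

test_that("out-of-order transactions are an integrity error", {
  ts <- build_transactions(table5_reports(), 3)
  bad <- ts
  bad$items[[1]] <- rev(bad$items[[1]])
  expect_error(build_cr_tree(bad), class = "adrmine_integrity_error")
})

test_that("pattern growth reproduces the seven printed patterns", {
  ts <- build_transactions(table5_reports(), 3)
  p <- prune_transactions(ts, query_spec("drug-interaction", attributes = "Age"))
  pats <- mine_patterns(build_cr_tree(p), 3)
  expect_equal(nrow(pats), 7)
  expect_true(all(pats$count == 3))
  got <- purrr::pmap_chr(list(pats$items, pats$symptom, pats$count), pattern_key)
  expect_setequal(got, c(
    pattern_key("Drug=d1", "s1", 3),
    pattern_key(c("Drug=d1", "Drug=d3"), "s1", 3),
    pattern_key(c("Age=a2", "Drug=d1"), "s1", 3),
    pattern_key(c("Age=a2", "Drug=d1", "Drug=d3"), "s1", 3),
    pattern_key("Drug=d3", "s1", 3),
    pattern_key(c("Age=a2", "Drug=d3"), "s1", 3),
    pattern_key("Age=a2", "s1", 3)))
  expect_equal(nrow(mine_patterns(build_cr_tree(p), 4)), 0)
})

test_that("mining equals exhaustive subset enumeration on random data", {
  for (seed in 71:75) {
    r <- random_reports(seed, n = 60)
    ts <- build_transactions(r, 3)
    p <- prune_transactions(ts, query_spec("drug-interaction", attributes = "Age"))
    pats <- mine_patterns(build_cr_tree(p), 3)
    got <- sort(purrr::pmap_chr(list(pats$items, pats$symptom, pats$count),
                                function(i, s, n)
                                  paste0(paste(sort(i), collapse = ","),
                                         " :: ", s, " = ", n)))
    expect_equal(got, o_patterns(p$items, p$labels, 3), info = seed)
  }
})

test_that("pattern counts are anti-monotone and order-independent", {
  r <- random_reports(81, n = 80)
  ts <- build_transactions(r, 3)
  p <- prune_transactions(ts, query_spec("drug-interaction", attributes = "Age"))
  pats <- mine_patterns(build_cr_tree(p), 3)
  key <- purrr::map_chr(pats$items, paste, collapse = ",")
  for (i in seq_len(nrow(pats))) {
    for (j in seq_len(nrow(pats))) {
      if (i != j && pats$symptom[i] == pats$symptom[j] &&
          all(pats$items[[i]] %in% pats$items[[j]])) {
        expect_lte(pats$count[j], pats$count[i])
      }
    }
  }
  # reversed insertion order yields the same pattern set
  rev_p <- p[rev(seq_len(nrow(p))), ]
  pats2 <- mine_patterns(build_cr_tree(rev_p), 3)
  expect_equal(pats, pats2)
})

test_that("the worked example outputs exactly one multidrug signal", {
  r <- table5_reports()
  q <- query_spec("drug-interaction", attributes = "Age", measure = "PRR",
                  min_count = 3)
  sig <- run_acm_ms(r, q)
  expect_equal(nrow(sig), 1)
  expect_equal(sig$Age, "a2")
  expect_equal(sig$drugs[[1]], c("d1", "d3"))
  expect_equal(sig$symptom, "s1")
  expect_equal(c(sig$a, sig$b, sig$c, sig$d), c(3, 0, 0, 1))
  expect_equal(sig$value, 3)
  expect_true(sig$is_signal)
})

test_that("transaction cache round-trips and leaves results unchanged", {
  r <- table5_reports()
  ts <- build_transactions(r, 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_transactions(ts, f)
  back <- read_transactions(f)
  expect_equal(items_str(back), items_str(ts))
  expect_equal(item_order(back)$item, item_order(ts)$item)
  q <- query_spec("drug-interaction", attributes = "Age")
  expect_equal(tidy(run_acm_ms(r, q, transactions = back)),
               tidy(run_acm_ms(r, q)))
})

test_that("singleton-drug patterns agree with the cube-based miner", {
  for (seed in 91:93) {
    r <- random_reports(seed, n = 80)
    q1 <- query_spec("single-drug", attributes = "Age", measure = "PRR",
                     min_count = 3)
    qa <- query_spec("drug-interaction", attributes = "Age", measure = "PRR",
                     min_count = 3, min_drugs = 1)
    cbm <- run_cbm_ss(r, q1)
    acm <- run_acm_ms(r, qa)
    one <- lengths(acm$drugs) == 1
    key <- function(age, drugs, sym) paste(age, drugs, sym)
    acm_keys <- key(acm$Age[one], purrr::map_chr(acm$drugs[one], 1),
                    acm$symptom[one])
    cbm_keys <- key(cbm$Age, purrr::map_chr(cbm$drugs, 1), cbm$symptom)
    expect_setequal(acm_keys, cbm_keys)
    m <- match(acm_keys, cbm_keys)
    expect_equal(acm$a[one], cbm$a[m])
    expect_equal(acm$value[one], cbm$value[m])
  }
})
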