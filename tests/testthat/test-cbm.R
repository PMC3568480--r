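test_that("candidate generation instantiates every selected attribute", {
  r <- table5_reports()
  cube <- build_cube(r, c("Age", "Drug", "PT"))
  q <- query_spec("single-drug", attributes = "Age", min_count = 3)
  cands <- generate_candidates(cube, q)
  expect_equal(nrow(cands), 2)
  expect_setequal(paste(cands$Age, cands$drug, cands$symptom),
                  c("a2 d1 s1", "a2 d3 s1"))
  expect_true(all(cands$a == 3))
  # min_count above the report count leaves no candidates
  q99 <- query_spec("single-drug", attributes = "Age", min_count = 99)
  expect_equal(nrow(generate_candidates(cube, q99)), 0)
})

test_that("without attributes there is one candidate per nonzero pair", {
  r <- table5_reports()
  cube <- build_cube(r, c("Drug", "PT"))
  q <- query_spec("single-drug", min_count = 1)
  cands <- generate_candidates(cube, q)
  reps <- o_group(table5_df())
  pairs <- unique(unlist(lapply(reps, function(x) {
    as.vector(outer(x$drugs, x$symptoms, paste))
  })))
  expect_equal(nrow(cands), length(pairs))   # brute force: 7 distinct pairs
  expect_setequal(paste(cands$drug, cands$symptom), pairs)
})

test_that("fixed drug and symptom restrict the candidate space", {
  cube <- build_cube(table5_reports(), c("Drug", "PT"))
  q <- query_spec("single-drug", min_count = 1, fixed_drug = "d2")
  expect_true(all(generate_candidates(cube, q)$drug == "d2"))
  q2 <- query_spec("single-drug", min_count = 1, fixed_symptom = "s2")
  expect_true(all(generate_candidates(cube, q2)$symptom == "s2"))
})

test_that("the worked example emits two PRR-3 signals", {
  r <- table5_reports()
  sig <- run_cbm_ss(r, query_spec("single-drug", attributes = "Age",
                                  measure = "PRR", min_count = 3))
  expect_s3_class(sig, "adr_signals")
  expect_equal(nrow(sig), 2)
  expect_equal(sig$Age, c("a2", "a2"))
  expect_equal(unlist(sig$drugs), c("d1", "d3"))
  expect_equal(sig$symptom, c("s1", "s1"))
  expect_true(all(sig$a == 3 & sig$b == 0 & sig$c == 0 & sig$d == 1))
  expect_equal(sig$value, c(3, 3))
  expect_true(all(sig$is_signal))
  expect_equal(sig$rank, 1:2)
})

test_that("degenerate and empty inputs give empty signal lists", {
  r <- table5_reports()
  empty <- filter_reports(r, constraints = list(Age = "no-such-age"))
  expect_equal(nrow(run_cbm_ss(empty, query_spec("single-drug"))), 0)
  q <- query_spec("single-drug", attributes = "Age", min_count = 99)
  expect_equal(nrow(run_cbm_ss(r, q)), 0)
})

test_that("output is invariant to report order", {
  r <- table5_reports()
  set.seed(3)
  shuffled <- r[sample(nrow(r)), ]
  attr(shuffled, "schema") <- report_schema(r)
  class(shuffled) <- class(r)
  q <- query_spec("single-drug", attributes = "Age")
  expect_equal(tidy(run_cbm_ss(r, q)), tidy(run_cbm_ss(shuffled, q)))
})

test_that("raising min_count only removes signals; top_k is a prefix", {
  r <- random_reports(31, n = 120)
  q1 <- query_spec("single-drug", attributes = "Age", min_count = 1,
                   measure = "PRR")
  q3 <- query_spec("single-drug", attributes = "Age", min_count = 5,
                   measure = "PRR")
  s1 <- run_cbm_ss(r, q1)
  s3 <- run_cbm_ss(r, q3)
  key <- function(s) paste(s$Age, purrr::map_chr(s$drugs, paste, collapse = ";"),
                           s$symptom)
  expect_true(all(key(s3) %in% key(s1)))
  qk <- query_spec("single-drug", attributes = "Age", min_count = 1,
                   measure = "PRR", top_k = 3)
  sk <- run_cbm_ss(r, qk)
  expect_equal(tidy(sk), head(tidy(s1), 3) |>
                 (\(x) { x$rank <- seq_len(nrow(x)); x })())
})

test_that("the miner equals a brute-force enumeration on random data", {
  for (seed in 41:50) {
    r <- random_reports(seed, n = 50)
    reps <- o_reports(r)
    q <- query_spec("single-drug", attributes = "Age", min_count = 3,
                    measure = "PRR")
    sig <- run_cbm_ss(r, q)
    oc <- o_cbm_candidates(reps, "Age", 3)
    # same candidates and cells
    ocells <- do.call(rbind, lapply(oc, function(x) x$cells))
    okeys <- vapply(oc, o_cand_key, "")
    # recompute signals from the oracle cells with direct arithmetic
    o_sig <- vapply(seq_along(oc), function(i) {
      a <- ocells[i, "a"]; b <- ocells[i, "b"]
      c <- ocells[i, "c"]; d <- ocells[i, "d"]
      pb <- if (c == 0) 0.5 / (c + d + 0.5) else c / (c + d)
      val <- (a / (a + b)) / pb
      inv <- function(x) if (x == 0) 2 else 1 / x
      se <- sqrt(max(inv(a) - inv(a + b) + inv(c) - inv(c + d), 0))
      val - 1.96 * se > 1
    }, TRUE)
    got <- paste0("Age=", sig$Age, " | ", purrr::map_chr(sig$drugs, 1),
                  " | ", sig$symptom)
    expect_setequal(got, okeys[o_sig])
    # cells agree for every emitted signal
    for (i in seq_len(nrow(sig))) {
      j <- match(got[i], okeys)
      expect_equal(c(a = sig$a[i], b = sig$b[i], c = sig$c[i], d = sig$d[i]),
                   ocells[j, ])
    }
  }
})

test_that("glance and autoplot summarize a signal table", {
  sig <- run_cbm_ss(table5_reports(),
                    query_spec("single-drug", attributes = "Age"))
  g <- glance(sig)
  expect_equal(g$n_signals, 2)
  expect_equal(g$measure, "PRR")
  p <- autoplot(sig)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(build_cube(table5_reports(), c("Drug", "PT")))
  expect_s3_class(p2, "ggplot")
})
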