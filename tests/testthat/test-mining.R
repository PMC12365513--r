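test_that("find_instances enumerates every realisation; row count gives HS", {
  txn <- tibble::tibble(symbol = c("A", "A", "B", "B"),
                        start = c(1, 10, 3, 12), end = c(2, 11, 4, 13))
  inst <- find_instances(txn, c("A", "B"), "b", max_gap = 20)
  expect_equal(dplyr::n_distinct(inst$instance), 3) # 1-2/3-4, 1-2/12-13, 10-11/12-13
  durations <- inst |>
    dplyr::summarise(d = max(end) - min(start), .by = "instance")
  expect_setequal(durations$d, c(3, 12, 3))

  one <- find_instances(tibble::tibble(symbol = c("A", "B"),
                                       start = c(1, 3), end = c(2, 4)),
                        c("A", "B"), "b", max_gap = 20)
  expect_equal(dplyr::n_distinct(one$instance), 1)
  none <- find_instances(tibble::tibble(symbol = "A", start = 1, end = 2),
                         c("A", "B"), "b", max_gap = 20)
  expect_equal(nrow(none), 0)
})

test_that("tirp_metrics averages HS and MD per transaction, then across", {
  # txn1: HS 3, durations 3/12/3 (MD 6); txn2: HS 1, duration 4
  inst <- tibble::tibble(
    entity_id = c(rep("t1", 3), "t2"),
    instance = c(1, 2, 3, 4),
    start = c(0, 0, 9, 1), end = c(3, 12, 12, 5)
  )
  m <- tirp_metrics(inst, n_transactions = 2)
  expect_equal(m$vs, 2)
  expect_equal(m$mhs, 2.0)
  expect_equal(m$mmd, 5.0)
  expect_error(tirp_metrics(inst[0, ], 2), class = "tirpscope_metrics_error")
})

test_that("mine_tirps handles the hand-enumerable databases", {
  db3 <- tibble::tibble(
    entity_id = rep(c("a", "b", "c"), each = 2),
    symbol = rep(c("A", "B"), 3),
    start = rep(c(1, 5), 3), end = rep(c(3, 7), 3)
  )
  tr <- mine_tirps(db3, min_vs = 2, max_gap = 20)
  td <- tidy(tr)
  expect_setequal(td$pattern, c("A", "B", "A B"))
  expect_true(all(td$vs == 3))
  expect_identical(td$relations[td$pattern == "A B"], "b")

  expect_equal(n_patterns(mine_tirps(db3[0, ], min_vs = 1, max_gap = 20)), 0)

  single <- mine_tirps(tibble::tibble(entity_id = "a", symbol = "A",
                                      start = 1, end = 3),
                       min_vs = 1, max_gap = 20)
  expect_equal(tidy(single)$vs, 1)
  expect_equal(tidy(single)$mhs, 1)

  expect_warning(mine_tirps(db3, min_vs = 10, max_gap = 20), "min_vs")
  expect_error(mine_tirps(db3, min_vs = 0, max_gap = 20),
               class = "tirpscope_config_error")
})

test_that("fractional min_vs converts with ceiling", {
  db <- tibble::tibble(entity_id = as.character(1:5), symbol = "A",
                       start = 1, end = 2)
  # 0.41 * 5 = 2.05 -> threshold 3
  tr <- mine_tirps(db[db$entity_id %in% 1:2, ], min_vs = 0.41, max_gap = 20)
  expect_equal(tr$config$threshold, 1L)
  tr5 <- mine_tirps(db, min_vs = 0.41, max_gap = 20)
  expect_equal(tr5$config$threshold, 3L)
})

test_that("mined trees equal the exhaustive subset-enumeration oracle", {
  for (seed in 1:8) {
    db <- random_sti_db(n_txn = 5, max_stis = 10, n_symbols = 5, seed = seed)
    tr <- mine_tirps(db, min_vs = 2, max_gap = 15, max_size = 4)
    got <- tree_pattern_table(tr)
    want <- oracle_mine(db, min_count = 2, max_gap = 15, max_size = 4)
    expect_equal(got$pattern, want$pattern, info = paste("seed", seed))
    expect_equal(got$relations, want$relations)
    expect_equal(got$vs, want$vs)
    expect_equal(got$mhs, want$mhs)
    expect_equal(got$hs_table, want$hs_table)
    validate_tree(tr) # includes VS anti-monotonicity on every edge
  }
})

test_that("mining is deterministic: identical input gives identical trees", {
  db <- random_sti_db(seed = 99)
  t1 <- mine_tirps(db, min_vs = 2, max_gap = 15)
  t2 <- mine_tirps(db, min_vs = 2, max_gap = 15)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_tree(t1, f1); write_tree(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every stored instance validates against its node's pattern", {
  db <- random_sti_db(seed = 3)
  tr <- mine_tirps(db, min_vs = 2, max_gap = 15, max_size = 3)
  for (r in seq_len(nrow(tr$nodes))) {
    inst <- tr$nodes$instances[[r]]
    ok <- inst |>
      dplyr::group_by(entity_id, instance) |>
      dplyr::group_map(function(df, key) {
        validate_instance(tr$nodes$symbols[[r]], tr$nodes$relations[[r]],
                          df$symbol, df$start, df$end, max_gap = 15)
      })
    expect_true(all(unlist(ok)))
  }
})
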