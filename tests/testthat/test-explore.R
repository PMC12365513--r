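tree <- toy_falls_tree()
idx <- build_tirp_index(tree)

test_that("start_session shows both panels around the focus STI", {
  s <- start_session(tree, idx, "Fall.Event")
  expect_gt(nrow(s$panels$earlier), 0)
  expect_gt(nrow(s$panels$later), 0)
  expect_equal(glance(s)$size_label, "1/1")
  # the 4-sized pattern whose first STI overlaps the focus appears on the
  # left with R = o and size label 1/4
  p17 <- s$panels$earlier[s$panels$earlier$node == "P17", ]
  expect_equal(p17$symbol, "Happiness.Decreased")
  expect_equal(p17$relation, "o")
  expect_equal(p17$size_label, "1/4")
  expect_error(start_session(tree, idx, "Nope"),
               class = "tirpscope_unknown_symbol_error")
  # a tree holding only the focus symbol has empty panels
  lone <- random_tirp_tree(1, 1, max_size = 1, seed = 1)
  s1 <- start_session(lone, build_tirp_index(lone), "S01")
  expect_equal(nrow(s1$panels$earlier) + nrow(s1$panels$later), 0)
})

test_that("selection fixes the sequence and updates the opposite panel", {
  s <- start_session(tree, idx, "Fall.Event")
  i <- which(s$panels$later$node == "P13" &
               s$panels$later$symbol == "Happiness.Decreased")
  s2 <- select_extension(s, "later", i)
  expect_identical(s2$fixed$symbols, c("Fall.Event", "Happiness.Decreased"))
  expect_identical(s2$fixed$relations, "b")
  expect_equal(s2$selected_node, "P13")
  # center STI is the 2nd of P13's 3 STIs
  expect_equal(glance(s2)$size_label, "2/3")
  # only P13 precedes the fixed pair, via Fluids.Low
  expect_equal(s2$panels$earlier$node, "P13")
  expect_equal(s2$panels$earlier$symbol, "Fluids.Low")
  # same-side panel retained with the chosen row marked
  expect_equal(nrow(s2$panels$later), nrow(s$panels$later))
  expect_true(s2$panels$later$selected[i])
  # prepending via a backward selection puts the new symbol first
  j <- which(s2$panels$earlier$node == "P13")
  s3 <- select_extension(s2, "earlier", j)
  expect_identical(s3$fixed$symbols,
                   c("Fluids.Low", "Fall.Event", "Happiness.Decreased"))
  expect_equal(s3$center, 2L) # center re-based, still Fall.Event
  expect_identical(s3$fixed$symbols[s3$center], "Fall.Event")
  expect_error(select_extension(s, "later", 99),
               class = "tirpscope_stale_selection_error")
})

test_that("shifts move the center but never the fixed sequence", {
  s <- start_session(tree, idx, "Fall.Event")
  i <- which(s$panels$later$node == "P13" &
               s$panels$later$symbol == "Happiness.Decreased")
  s2 <- select_extension(s, "later", i)
  s3 <- shift_forward(s2)
  expect_identical(s3$fixed, s2$fixed)
  expect_identical(s3$selected_node, s2$selected_node)
  expect_equal(s3$center, 2L)
  # nothing continues the fixed pair: the right panel is empty
  expect_equal(nrow(s3$panels$later), 0)
  # the left panel collapses to the fixed neighbor, marked
  expect_equal(s3$panels$earlier$symbol, "Fall.Event")
  expect_true(s3$panels$earlier$selected)
  expect_equal(s3$panels$earlier$node, "P13")
  s4 <- shift_backward(s3)
  expect_equal(s4$center, 1L)
  expect_identical(s4$fixed, s2$fixed)
  expect_error(shift_backward(s4), class = "tirpscope_shift_error")
  expect_error(shift_forward(s3), class = "tirpscope_shift_error")
})

test_that("undo pops back to the previous state; re-selecting is identity", {
  s <- start_session(tree, idx, "Fall.Event")
  i <- which(s$panels$later$node == "P13" &
               s$panels$later$symbol == "Happiness.Decreased")
  s2 <- select_extension(s, "later", i)
  back <- undo_selection(s2)
  expect_identical(back$fixed, s$fixed)
  expect_identical(back$panels, s$panels)
  again <- select_extension(back, "later", i)
  expect_identical(again$fixed, s2$fixed)
  expect_identical(again$panels, s2$panels)
  expect_error(undo_selection(s), class = "tirpscope_undo_error")
})

test_that("panel rows are re-derivable from their node's matrix alone", {
  s <- start_session(tree, idx, "Fall.Event")
  rows <- tidy(s)
  for (r in seq_len(nrow(rows))) {
    nd <- tree_node(tree, rows$node[r])
    q <- rows$position[r]
    expect_identical(nd$symbols[[1]][q], rows$symbol[r])
    expect_equal(rows$size[r], nd$size)
    cpos <- rows$match_pos[r] + s$center - 1L
    expect_identical(
      pair_relation(nd$relations[[1]], min(cpos, q), max(cpos, q)),
      rows$relation[r])
  }
})

test_that("positional query filters on first, interior and last symbols", {
  # patterns ending with the fall event that contain low fluids earlier
  res <- positional_query(tree, intermediate = "Fluids.Low",
                              last = "Fall.Event")
  expect_true("P16" %in% res$id)
  # query returns interior matches anywhere, not only immediate neighbors
  expect_true(all(vapply(strsplit(res$pattern, " "), function(s)
    s[length(s)] == "Fall.Event", logical(1))))
  one <- positional_query(tree, first = "Fall.Event", last = "Fall.Event")
  expect_equal(one$id, "P1")
  pair_tree <- random_tirp_tree(3, 6, max_size = 2, seed = 2)
  expect_equal(nrow(positional_query(pair_tree, intermediate = "S01")), 0)
  expect_error(positional_query(tree), class = "tirpscope_config_error")
})

test_that("backward rows whose match ends the pattern appear in the query", {
  for (seed in 1:6) {
    rt <- random_tirp_tree(4, 50, max_size = 5, seed = seed)
    ridx <- build_tirp_index(rt)
    for (seq in all_windows(rt, max_len = 3L)) {
      m <- length(seq$symbols)
      if (m < 2L) next
      bw <- backward_lookup(rt, ridx, seq)
      if (nrow(bw) == 0) next
      res <- positional_query(rt, intermediate = seq$symbols[m - 1L],
                                  last = seq$symbols[m])
      ends_at_last <- vapply(seq_len(nrow(bw)), function(r) {
        bw$match_pos[r] + m - 1L == tree_node(rt, bw$node[r])$size
      }, logical(1))
      expect_true(all(bw$node[ends_at_last] %in% res$id))
    }
  }
})
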