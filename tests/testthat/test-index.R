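demo_tree <- toy_falls_tree()
demo_idx <- build_tirp_index(demo_tree)

test_that("pair buckets hold every TIRP containing the pair consecutively", {
  bucket <- index_bucket(demo_idx, "forward", "Fluids.Low", "Fall.Event")
  expect_true(all(c("P7", "P12", "P13", "P18") %in% bucket$node))
  # backward bucket keyed (later, earlier) holds the same entries
  back <- index_bucket(demo_idx, "backward", "Fall.Event", "Fluids.Low")
  expect_equal(dplyr::arrange(bucket, node, position),
               dplyr::arrange(back, node, position))
})

test_that("per-node entry counts equal size - 1; a size-1 tree indexes nothing", {
  counts <- table(demo_idx$entries$node)
  for (r in seq_len(nrow(demo_tree$nodes))) {
    id <- demo_tree$nodes$id[r]
    k <- demo_tree$nodes$size[r]
    expect_equal(if (id %in% names(counts)) counts[[id]] else 0L, k - 1L)
  }
  roots_only <- random_tirp_tree(4, 4, max_size = 1, seed = 1)
  idx <- build_tirp_index(roots_only)
  expect_equal(nrow(idx$entries), 0)
  expect_length(idx$forward, 0)
})

test_that("matches_consecutively respects order and the relation sub-matrix", {
  p18 <- tree_node(demo_tree, "P18")
  seq_lf <- fixed_sequence(c("Fluids.Low", "Fall.Event"), "b")
  expect_identical(
    matches_consecutively(p18$symbols[[1]], p18$relations[[1]], seq_lf), 2L)
  # a TIRP matches its own full sequence at position 1
  expect_identical(
    matches_consecutively(p18$symbols[[1]], p18$relations[[1]],
                          fixed_sequence(p18$symbols[[1]],
                                         p18$relations[[1]])), 1L)
  # order matters
  p12 <- tree_node(demo_tree, "P12")
  expect_length(
    matches_consecutively(p12$symbols[[1]], p12$relations[[1]],
                          fixed_sequence(c("Fall.Event", "Fluids.Low"), "b")),
    0)
  # relation mismatch rejected unless relation matching is disabled
  seq_o <- fixed_sequence(c("Fluids.Low", "Fall.Event"), "o")
  expect_length(
    matches_consecutively(p18$symbols[[1]], p18$relations[[1]], seq_o), 0)
  expect_identical(
    matches_consecutively(p18$symbols[[1]], p18$relations[[1]], seq_o,
                          match_relations = FALSE), 2L)
})

test_that("demo-tree lookups return the documented extension sets", {
  p7 <- fixed_sequence(c("Fluids.Low", "Fall.Event"), "b")
  expect_setequal(forward_lookup(demo_tree, demo_idx, p7)$node,
                  c("P12", "P13", "P18"))
  expect_setequal(backward_lookup(demo_tree, demo_idx, p7)$node,
                  c("P16", "P18"))
  # no pattern continues <Fall.Event, Happiness.Decreased> forward
  fh <- fixed_sequence(c("Fall.Event", "Happiness.Decreased"), "b")
  expect_equal(nrow(forward_lookup(demo_tree, demo_idx, fh)), 0)
  bw <- backward_lookup(demo_tree, demo_idx, fh)
  expect_equal(bw$node, "P13")
  expect_equal(bw$symbol, "Fluids.Low")
  expect_warning(out <- forward_lookup(demo_tree, demo_idx, "NoSuch"),
                 "not in tree alphabet")
  expect_equal(nrow(out), 0)
})

test_that("indexed lookups equal a full-tree scan on random trees", {
  agree <- 0L; total <- 0L
  for (seed in 1:12) {
    tree <- random_tirp_tree(n_symbols = sample(3:8, 1),
                             n_nodes = sample(30:80, 1),
                             max_size = sample(3:6, 1), seed = seed)
    idx <- build_tirp_index(tree)
    for (seq in all_windows(tree)) {
      for (dir in c("later", "earlier")) {
        f <- if (dir == "later") forward_lookup else backward_lookup
        got <- f(tree, idx, seq)
        got_keys <- row_keys(got)
        want <- scan_lookup(tree, seq, dir)
        total <- total + 1L
        if (identical(got_keys, want)) agree <- agree + 1L
      }
    }
  }
  expect_gt(total, 100)
  expect_equal(agree, total)
})

test_that("forward and backward buckets are mirror images for all pairs", {
  for (seed in 1:5) {
    tree <- random_tirp_tree(5, 60, max_size = 5, seed = seed)
    idx <- build_tirp_index(tree)
    for (a in tree$alphabet) for (b in tree$alphabet) {
      f <- index_bucket(idx, "forward", a, b)
      bk <- index_bucket(idx, "backward", b, a)
      expect_equal(dplyr::arrange(f, node, position),
                   dplyr::arrange(bk, node, position))
    }
    expect_equal(nrow(idx$entries), sum(pmax(tree$nodes$size - 1L, 0L)))
  }
})

test_that("rebuilding the index from the same tree is idempotent", {
  i1 <- build_tirp_index(demo_tree)
  i2 <- build_tirp_index(demo_tree)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_index(i1, f1); write_index(i2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
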