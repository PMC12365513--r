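test_that("ewd_cutoffs splits the observed range into equal-width bins", {
  expect_equal(ewd_cutoffs(c(0, 3, 10), 2), 5)
  expect_equal(ewd_cutoffs(c(0, 10), 4), c(2.5, 5, 7.5))
  expect_error(ewd_cutoffs(rep(7, 5), 2),
               class = "tirpscope_degenerate_range_error")
})

test_that("label_states uses left-closed bins with a right-closed top bin", {
  expect_identical(label_states(c(1, 6), 5, c("Low", "High"), "Var"),
                   c("Var.Low", "Var.High"))
  expect_identical(label_states(5, 5, c("Low", "High"), "Var"), "Var.High")
  expect_identical(label_states(numeric(0), 5, c("Low", "High"), "Var"),
                   character(0))
})

test_that("label_gradients classifies slopes against theta", {
  out <- label_gradients(c(0, 1, 2), c(1, 2, 2), theta = 0.1,
                         variable = "Var")
  expect_identical(out$symbol, c("Var.Increasing", "Var.Stable"))
  expect_equal(out$start, c(0, 1))
  expect_equal(out$end, c(1, 2))
  dec <- label_gradients(c(0, 1, 2, 3), c(9, 7, 4, 0))
  expect_true(all(dec$symbol == "Decreasing"))
  inf <- label_gradients(c(0, 1, 2), c(0, 100, -100), theta = Inf)
  expect_true(all(inf$symbol == "Stable"))
  expect_error(label_gradients(0, 1),
               class = "tirpscope_insufficient_data_error")
})

test_that("runs_to_stis merges maximal runs and honours the gap break", {
  out <- runs_to_stis(tibble::tibble(symbol = c("A", "A", "B"),
                                     start = c(1, 2, 3), end = c(1, 2, 3)))
  expect_equal(out, tibble::tibble(symbol = c("A", "B"),
                                   start = c(1, 3), end = c(2, 3)))
  gap <- runs_to_stis(tibble::tibble(symbol = c("A", "A"),
                                     start = c(1, 50), end = c(1, 50)),
                      max_sample_gap = 10)
  expect_equal(gap$start, c(1, 50))
  expect_equal(gap$end, c(1, 50))
  seg <- runs_to_stis(tibble::tibble(symbol = c("V.Inc", "V.Inc"),
                                     start = c(0, 1), end = c(1, 2)))
  expect_equal(seg, tibble::tibble(symbol = "V.Inc", start = 0, end = 2))
})

test_that("run merging never leaves adjacent same-symbol STIs", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    t <- cumsum(sample(1:5, n, replace = TRUE))
    lab <- tibble::tibble(symbol = sample(c("X", "Y"), n, replace = TRUE),
                          start = t, end = t)
    out <- runs_to_stis(lab, max_sample_gap = 6)
    expect_lte(nrow(out), n)
    same <- which(out$symbol[-1] == out$symbol[-nrow(out)])
    # consecutive same-symbol STIs must be separated by a gap break
    for (i in same) expect_gt(out$start[i + 1] - out$end[i], 6)
  }
})

test_that("abstract_timeseries runs the full pipeline per variable", {
  raw <- tibble::tibble(
    entity_id = "p1",
    variable = rep(c("Glucose", "Weight"), each = 4),
    timestamp = rep(1:4, 2),
    value = c(80, 90, 160, 170, 70, 72, 71, 69)
  )
  cfgs <- list(
    abstraction_config("Glucose", "state", cutoffs = 120,
                       labels = c("Normal", "High")),
    abstraction_config("Weight", "gradient", theta = 1.5)
  )
  out <- abstract_timeseries(raw, cfgs)
  # sorted by entity then sti_order
  expect_identical(
    out$symbol,
    c("Glucose.Normal", "Weight.Increasing", "Weight.Stable",
      "Glucose.High", "Weight.Decreasing"))
  # state runs keep observed bounds: Normal spans samples 1-2, High 3-4
  expect_equal(out$start[out$symbol == "Glucose.Normal"], 1)
  expect_equal(out$end[out$symbol == "Glucose.Normal"], 2)
  # per-sample labelling drops no sample
  expect_equal(sum(out$symbol %in% c("Glucose.Normal", "Glucose.High")), 2)
  expect_warning(
    abstract_timeseries(dplyr::mutate(raw, variable = "Other"), cfgs),
    "no abstraction config")
})
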