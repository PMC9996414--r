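test_that("annotation files round-trip through CSV and JSON with sorting and type mapping", {
  ev <- respiratory_events(
    c("hypopnea", "obstructive_apnea", "weird_type"),
    onset = c(40, 5, 100), duration = c(8, 12, 20))
  expect_equal(ev$onset, c(5, 40, 100))          # sorted ascending
  expect_equal(ev$event_type[3], "other")        # unknown mapped

  csv <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, csv)
  expect_equal(read_events(csv), ev)

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(event_type = "obstructive_apnea",
                                  onset_sec = 5, duration_sec = 12),
                       js, auto_unbox = TRUE)
  one <- read_events(js)
  expect_equal(nrow(one), 1L)
  expect_equal(one$duration, 12)
})

test_that("invalid annotations are rejected with informative errors", {
  expect_error(respiratory_events("hypopnea", -1, 10), "onset")
  expect_error(respiratory_events("hypopnea", 5, 0), "duration")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("event_type,onset_sec,duration_sec",
               "hypopnea,abc,10"), csv)
  expect_error(read_events(csv), "line 1")
})

test_that("filter_obstructive keeps only obstructive apneas and hypopneas", {
  ev <- respiratory_events(
    c("obstructive_apnea", "central_apnea", "hypopnea", "mixed_apnea", "other"),
    onset = 1:5 * 10, duration = rep(10, 5))
  kept <- filter_obstructive(ev)
  expect_equal(kept$event_type, c("obstructive_apnea", "hypopnea"))
  expect_equal(nrow(filter_obstructive(respiratory_events())), 0L)
  all_central <- respiratory_events(rep("central_apnea", 3), c(0, 20, 40), rep(5, 3))
  expect_equal(nrow(filter_obstructive(all_central)), 0L)
})

test_that("label_epochs implements the longer-overlap rule with apnea tie-break", {
  grid <- epoch_grid(60)
  # apnea overlap 12 s beats hypopnea overlap 8 s in epoch 0
  ev <- respiratory_events(c("obstructive_apnea", "hypopnea"),
                           c(5, 20), c(12, 8))
  lab <- label_epochs(ev, grid)
  expect_equal(as.character(lab$label), c("apnea", "no_event"))
  expect_equal(lab$overlap_apnea[1], 12)
  expect_equal(lab$overlap_hypopnea[1], 8)

  # single hypopnea in the second epoch
  lab2 <- label_epochs(respiratory_events("hypopnea", 40, 15), grid)
  expect_equal(as.character(lab2$label), c("no_event", "hypopnea"))

  # event crossing an epoch boundary credits overlap to both epochs
  lab3 <- label_epochs(respiratory_events("obstructive_apnea", 25, 20), grid)
  expect_equal(lab3$overlap_apnea, c(5, 15))
  expect_equal(as.character(lab3$label), c("apnea", "apnea"))

  # exact tie goes to apnea (the more severe class)
  lab4 <- label_epochs(respiratory_events(c("obstructive_apnea", "hypopnea"),
                                          c(0, 10), c(10, 10)), grid)
  expect_equal(as.character(lab4$label)[1], "apnea")

  # empty grid and no events
  expect_equal(nrow(label_epochs(respiratory_events(), epoch_grid(10))), 0L)
  lab5 <- label_epochs(respiratory_events(), grid)
  expect_true(all(lab5$label == "no_event"))
})

test_that("labels are invariant to the input order of events", {
  grid <- epoch_grid(300)
  ev <- random_events(12, 300, seed = 7)
  shuffled <- ev[rev(seq_len(nrow(ev))), ]
  class(shuffled) <- class(ev)
  expect_equal(label_epochs(ev, grid)$label,
               label_epochs(shuffled, grid)$label)
})

test_that("label_epochs matches the rasterization oracle on random layouts", {
  grid <- epoch_grid(600)
  for (s in 1:120) {
    ev <- random_events(sample(1:8, 1), 600, seed = s)
    got <- as.character(label_epochs(ev, grid)$label)
    want <- raster_label_oracle(ev, grid)
    expect_identical(got, want, info = paste("layout seed", s))
  }
})

test_that("total-duration overlap mode compares whole-event durations", {
  grid <- epoch_grid(60)
  # hypopnea has the longer total duration but smaller within-epoch overlap
  ev <- respiratory_events(c("obstructive_apnea", "hypopnea"),
                           c(0, 25), c(12, 35))
  within <- label_epochs(ev, grid)
  total <- label_epochs(ev, grid, overlap = "total_duration")
  expect_equal(as.character(within$label)[1], "apnea")    # 12 s > 5 s overlap
  expect_equal(as.character(total$label)[1], "hypopnea")  # 35 s > 12 s event
})

test_that("epoch grid drops the trailing partial epoch", {
  expect_equal(epoch_grid(95)$n_epochs, 3L)
  expect_equal(epoch_grid(29.9)$n_epochs, 0L)
  expect_equal(epoch_grid(30)$n_epochs, 1L)
})
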