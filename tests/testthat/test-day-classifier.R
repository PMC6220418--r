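test_that("training-set assembly hits exact per-class targets or errors", {
  scenes <- tiny_scene_pool()
  ts <- build_training_set(scenes, c(background = 100, closed = 30, open = 20),
                           validation_counts = c(background = 20, closed = 10,
                                                 open = 10), seed = 42)
  expect_equal(as.integer(ts$class_counts), c(100, 30, 20))
  expect_equal(as.integer(ts$validation$class_counts), c(20, 10, 10))
  expect_length(ts$crops, 150)
  expect_true(all(vapply(ts$crops, function(x) all(dim(x) == c(34, 34, 3)),
                         logical(1))))

  empty <- build_training_set(scenes, c(background = 0, closed = 0, open = 0))
  expect_length(empty$crops, 0)

  expect_error(build_training_set(scenes, c(background = 10, closed = 5,
                                            open = 10000)),
               "not enough 'open'.*deficit", perl = TRUE)
})

test_that("training is seeded, reproducible, and refuses one-class sets", {
  scenes <- tiny_scene_pool()
  ts <- build_training_set(scenes, c(background = 60, closed = 25, open = 15),
                           seed = 7)
  m1 <- train_classifier(ts, seed = 3)
  m2 <- train_classifier(ts, seed = 3)
  p1 <- predict(m1, ts$crops[1:10])
  p2 <- predict(m2, ts$crops[1:10])
  expect_identical(p1, p2)

  single <- build_training_set(scenes, c(background = 30, closed = 0, open = 0))
  expect_error(train_classifier(single), "single class")
})

test_that("classifier separates the classes like a nearest-centroid oracle", {
  scenes <- tiny_scene_pool()
  ts <- build_training_set(scenes, c(background = 80, closed = 30, open = 20),
                           seed = 9)
  model <- train_classifier(ts, seed = 1)
  expect_equal(model$training_accuracy, 1)
  oracle <- oracle_nearest_centroid(ts$crops, ts$labels, ts$crops)
  expect_equal(mean(oracle == ts$labels), 1)
  probs <- predict(model, ts$crops)
  expect_equal(colnames(probs)[max.col(probs)], oracle)
})

test_that("both backends emit normalised probability triples", {
  scenes <- tiny_scene_pool()
  ts <- build_training_set(scenes, c(background = 40, closed = 20, open = 15),
                           seed = 2)
  for (bk in c("multinom", "nnet")) {
    m <- train_classifier(ts, backend = bk, seed = 5)
    p <- predict(m, ts$crops[seq(1, 70, by = 7)])
    expect_equal(dim(p), c(10, 3))
    expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("whole-image classification tiles, counts and errors correctly", {
  scenes <- tiny_scene_pool()
  ts <- build_training_set(scenes, c(background = 80, closed = 30, open = 20),
                           seed = 9)
  model <- train_classifier(ts, seed = 1)

  px <- array(runif(986 * 476 * 3) * 255, c(986, 476, 3))
  calls <- classify_image(model, px)
  expect_length(calls$labels, 406)
  expect_equal(sum(calls$counts), 406)
  expect_equal(unname(rowSums(calls$probs)), rep(1, 406), tolerance = 1e-6)
  expect_equal(calls$labels,
               colnames(calls$probs)[max.col(calls$probs, ties.method = "first")])

  # pure background scene: no spikelet calls
  bg <- make_day_scene(day_scene_spec(seed = 50, n_closed = 0, n_open = 0,
                                      n_background = 1))
  bg_calls <- classify_image(model, bg$frame)
  expect_equal(as.integer(bg_calls$counts[c("closed", "open")]), c(0, 0))
  expect_error(open_ratio(bg_calls), "undefined")

  expect_error(classify_image(model, matrix(0, 100, 100)), "night")
})

test_that("open ratio excludes background tiles", {
  fake <- structure(list(counts = table(factor(
    c(rep("background", 8), rep("closed", 9), rep("open", 3)),
    levels = c("background", "closed", "open")))),
    class = "taa_tile_calls")
  expect_equal(open_ratio(fake), 0.25)
  fake$counts <- table(factor(rep("closed", 10),
                              levels = c("background", "closed", "open")))
  expect_equal(open_ratio(fake), 0)
  fake$counts <- table(factor(rep("open", 10),
                              levels = c("background", "closed", "open")))
  expect_equal(open_ratio(fake), 1)
})

test_that("evaluation reports overall and open-vs-closed accuracy with a coherent confusion table", {
  scenes <- tiny_scene_pool()
  ts <- build_training_set(scenes, c(background = 80, closed = 30, open = 20),
                           validation_counts = c(background = 30, closed = 12,
                                                 open = 10), seed = 4)
  model <- train_classifier(ts, seed = 1)
  ev <- evaluate_classifier(model, ts$validation)
  expect_equal(unname(rowSums(ev$confusion)), c(30, 12, 10))
  # hand-count accuracy from the confusion table
  expect_equal(ev$overall_accuracy, sum(diag(ev$confusion)) / 52)
  oc <- ev$confusion[c("closed", "open"), ]
  expect_equal(ev$open_vs_closed_accuracy,
               (oc["closed", "closed"] + oc["open", "open"]) / sum(oc))
  expect_error(evaluate_classifier(model, new_empty <- structure(
    list(crops = list(), labels = character(0)), class = "taa_training_set")),
    "empty")
})

test_that("classifier archives round-trip through disk", {
  scenes <- tiny_scene_pool()
  ts <- build_training_set(scenes, c(background = 40, closed = 15, open = 10),
                           seed = 6)
  m <- train_classifier(ts, seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  expect_identical(predict(m2, ts$crops[1:5]), predict(m, ts$crops[1:5]))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_classifier(bad), "archive")
})
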