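test_that("feature scaling maps the receiver range onto the unit interval", {
  m <- matrix(c(-100, -50, -75), 1)
  tr <- clip_rss(structure(list(rss = m, time_s = 0, clipped = FALSE),
                           class = "rss_trace"))
  expect_equal(as.numeric(scale_inputs(tr)), c(0, 1, 0.5))
  raw <- structure(list(rss = matrix(-120, 1), time_s = 0, clipped = FALSE),
                   class = "rss_trace")
  expect_error(scale_inputs(raw), "clip")
})

test_that("accuracy metrics match the confusion-matrix oracle and identity", {
  set.seed(71)
  truth <- matrix(rbinom(200, 1, 0.3), 20)
  pred <- matrix(rbinom(200, 1, 0.5), 20)
  m <- proximity_metrics(pred, truth)
  tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
  expect_equal(m$proximity, tp / (tp + fn))
  expect_equal(m$distance, tn / (tn + fp))
  expect_equal(m$overall, (tp + tn) / 200)
  ## overall is exactly the label-weighted combination
  expect_equal(m$overall,
               (m$n_pos * m$proximity + m$n_neg * m$distance) / (m$n_pos + m$n_neg))
  expect_equal(proximity_metrics(truth, truth),
               list(proximity = 1, distance = 1, overall = 1,
                    n_pos = sum(truth), n_neg = 200 - sum(truth)))
  z <- matrix(0, 20, 10)
  mz <- proximity_metrics(z, truth)
  expect_equal(mz$proximity, 0)
  expect_equal(mz$distance, 1)
  all1 <- matrix(1, 2, 2)
  expect_true(is.na(proximity_metrics(all1, all1 * 0)$proximity))
})

test_that("prediction thresholds strictly above one half", {
  cfg <- proximity_config("dnn", hidden = c(2, 2))
  set.seed(72)
  model <- train_proximity(matrix(stats::runif(40), 10, 4),
                           matrix(rbinom(40, 1, 0.5), 10, 4),
                           proximity_config("dnn", hidden = c(2, 2), epochs = 2),
                           seed = 1)
  ## force the final layer to produce exactly 0.5 and above/below
  nl <- length(model$layers)
  model$layers[[nl]]$W$value[] <- 0
  model$layers[[nl]]$b$value[] <- 0          # logit 0 -> p = 0.5 -> class 0
  p <- predict_proximity(model, matrix(stats::runif(8), 2, 4))
  expect_equal(p, matrix(0, 2, 4))
  model$layers[[nl]]$b$value[] <- 3          # p = 0.95 -> class 1
  expect_equal(predict_proximity(model, matrix(stats::runif(8), 2, 4)),
               matrix(1, 2, 4))
  expect_error(predict_proximity(model, matrix(0.5, 2, 3)), "dimension")
})

test_that("both classifiers solve a separable two-anchor scene", {
  ## two far-apart anchors, no shadowing; samples within 2 m of the vicinity
  ## boundary are excluded so the classes carry a margin
  sc <- anchor_scene(rbind(c(10, 25), c(40, 25)), c(0, 50, 0, 50),
                     data.frame(pt_dbm = 0, pl0_db = 40, d0_m = 1,
                                exponent = c(2.5, 2.5), sigma_db = 0))
  walk <- bounded_random_walk(sc$bounds, 900, step_sd = 3, seed = 73)
  keep <- apply(abs(anchor_distances(sc, walk) - 15) > 2, 1, all)
  x <- scale_inputs(clip_rss(suppressWarnings(simulate_rss(sc, walk, seed = 74))))[keep, ]
  y <- vicinity_labels(sc, walk)[keep, ]
  cfgs <- list(dnn = proximity_config("dnn", epochs = 300, batch_size = 64,
                                      learning_rate = 0.05),
               lstm = proximity_config("lstm", t_lstm = 3, epochs = 600,
                                       batch_size = 64, learning_rate = 0.2))
  for (arch in names(cfgs)) {
    model <- train_proximity(x, y, cfgs[[arch]], seed = 2)
    m <- proximity_metrics(predict_proximity(model, x), y)
    expect_gte(m$overall, 0.99)
    ## convergence trend on the separable scene
    expect_lt(tail(model$loss, 1), model$loss[1])
  }
})

test_that("training is deterministic given the seed", {
  set.seed(75)
  x <- matrix(stats::runif(200), 50, 4)
  y <- matrix(rbinom(200, 1, 0.4), 50, 4)
  for (arch in c("dnn", "lstm")) {
    cfg <- proximity_config(arch, epochs = 10, batch_size = 25)
    m1 <- train_proximity(x, y, cfg, seed = 7)
    m2 <- train_proximity(x, y, cfg, seed = 7)
    expect_identical(m1$loss, m2$loss)
  }
})

test_that("windowed mean RSS matches direct averaging", {
  rss <- matrix(stats::rnorm(60), 30, 2)
  tr <- structure(list(rss = rss, time_s = (0:29) * 0.1, clipped = FALSE),
                  class = "rss_trace")
  wm <- window_mean_rss(tr, window_s = 0.5)
  expect_equal(nrow(wm$features), 6)
  for (w in 1:6)
    expect_equal(wm$features[w, ], colMeans(rss[((w - 1) * 5 + 1):(w * 5), ]))
})

test_that("the region classifier separates well-separated regions without noise", {
  regions <- data.frame(name = c("A", "B", "C", "D"),
                        xmin = c(0, 25, 0, 25), xmax = c(25, 50, 25, 50),
                        ymin = c(0, 0, 25, 25), ymax = c(25, 25, 50, 50))
  sc <- default_anchor_scene(sigma_db = 0)
  walk <- bounded_random_walk(sc$bounds, 800, step_sd = 4, seed = 76)
  tr <- suppressWarnings(simulate_rss(sc, walk, seed = 77))
  wm <- window_mean_rss(tr, window_s = 0.5)
  labs <- label_regions(walk, regions, wm$window_index)
  expect_gte(length(unique(labs)), 3)
  feats <- scale_inputs(clip_rss(structure(list(rss = wm$features, time_s = wm$centers,
                                                clipped = FALSE), class = "rss_trace")))
  model <- train_roi_classifier(feats, labs, n_regions = 4, learning_rate = 0.3,
                                epochs = 400, seed = 3)
  pred <- classify_roi(model, feats)
  cm <- roi_confusion(pred, labs, 4)
  expect_gte(sum(diag(cm)) / sum(cm), 0.95)
  ## single-region labeling is trivially perfect
  one <- rep(1L, length(labs))
  m1 <- train_roi_classifier(feats, one, n_regions = 1, epochs = 5, seed = 1)
  expect_equal(classify_roi(m1, feats), one)
  ## points outside every region are rejected
  bad <- regions[1:2, ]
  expect_error(label_regions(walk, bad[bad$xmin > 100, , drop = FALSE],
                             wm$window_index), "outside")
})
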