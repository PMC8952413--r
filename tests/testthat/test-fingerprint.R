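test_that("codebook stores time-mean fingerprints", {
  rec <- list(matrix(-70, 50, 4),
              matrix(-70, 50, 4),
              matrix(rep(c(-60, -65, -80, -90), each = 50), 50))
  cb <- build_codebook(rec, coordinates = cbind(c(0, 1, 2), 0, 0))
  expect_equal(cb$fingerprints[1, ], rep(-70, 4))
  ## identical traces give identical fingerprints at distinct coordinates
  expect_equal(cb$fingerprints[1, ], cb$fingerprints[2, ])
  expect_false(all(cb$coordinates[1, ] == cb$coordinates[2, ]))
  expect_equal(cb$fingerprints[3, ], c(-60, -65, -80, -90))
})

test_that("noisy reference recordings average close to the true mean", {
  set.seed(31)
  n <- 1e4
  rec <- list(matrix(-72 + stats::rnorm(n * 3, sd = 5), n, 3))
  cb <- build_codebook(rec, coordinates = matrix(0, 1, 3))
  expect_true(all(abs(cb$fingerprints[1, ] + 72) < 3 * 5 / 100))
})

test_that("silent anchors are stored at nu_min with a warning", {
  rec <- list(cbind(matrix(-70, 10, 2), NA))
  expect_warning(cb <- build_codebook(rec, matrix(0, 1, 3)), "nu_min")
  expect_equal(cb$fingerprints[1, 3], -100)
})

test_that("test preprocessing averages per 0.25 s bin and fills gaps", {
  pk <- data.frame(time_s = c(0.0, 0.1, 0.2, 0.3, 0.55),
                   anchor = c(1, 1, 1, 2, 1),
                   rss_dbm = c(-60, -62, -64, -70, -50))
  out <- preprocess_test_rss(pk, n_anchors = 2)
  expect_equal(out$fingerprints[1, 1], mean(c(-60, -62, -64)))
  expect_equal(out$fingerprints[2, 2], -70)
  expect_equal(out$fingerprints[2, 1], -100)   # silent anchor -> nu_min
  expect_equal(out$fingerprints[3, 1], -50)
  ## 8 packets in one bin average exactly
  pk8 <- data.frame(time_s = seq(0, 0.24, length.out = 8), anchor = 1,
                    rss_dbm = seq(-80, -66, by = 2))
  expect_equal(preprocess_test_rss(pk8, 1)$fingerprints[1, 1], -73)
  expect_error(preprocess_test_rss(pk[0, ], 2))
})

test_that("closest fingerprints match an exhaustive-sort oracle", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(5:30, 1); u <- sample(3:8, 1)
    fp <- matrix(stats::runif(n * u, -95, -55), n, u)
    cb <- build_codebook(lapply(seq_len(n), function(i) fp[i, , drop = FALSE]),
                         coordinates = cbind(stats::runif(n), stats::runif(n), 0))
    g <- stats::runif(u, -95, -55)
    w <- sample(1:min(5, n), 1)
    d <- sqrt(colSums((t(cb$fingerprints) - g)^2))
    expect_identical(closest_fingerprints(cb, g, w), order(d)[seq_len(w)])
  }
})

test_that("ties break by insertion order and W bounds are enforced", {
  fp <- rbind(c(-70, -70), c(-70, -70), c(-60, -60))
  cb <- build_codebook(lapply(1:3, function(i) fp[i, , drop = FALSE]),
                       coordinates = cbind(1:3, 0, 0))
  expect_identical(closest_fingerprints(cb, c(-70, -70), 2), c(1L, 2L))
  expect_identical(closest_fingerprints(cb, c(-70, -70), 3), c(1L, 2L, 3L))
  expect_error(closest_fingerprints(cb, c(-70, -70), 4), "exceeds")
})

test_that("position estimate is the centroid of selected references", {
  cb <- build_codebook(lapply(1:3, function(i) matrix(-70, 1, 2)),
                       coordinates = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)))
  expect_equal(position_estimate(cb, 1), c(0, 0, 0))
  expect_equal(position_estimate(cb, 1:3), c(1, 1, 0))
  set.seed(33)
  idx <- sample(1:3, 2)
  expect_equal(position_estimate(cb, idx), colMeans(cb$coordinates[idx, ]))
  expect_error(position_estimate(cb, integer(0)))
})

test_that("estimates lie in the convex hull of the selected references", {
  set.seed(34)
  n <- 12
  coords <- cbind(stats::runif(n, 0, 10), stats::runif(n, 0, 10), 0)
  fp <- matrix(stats::runif(n * 4, -95, -55), n, 4)
  cb <- build_codebook(lapply(seq_len(n), function(i) fp[i, , drop = FALSE]), coords)
  for (rep in 1:10) {
    g <- stats::runif(4, -95, -55)
    idx <- closest_fingerprints(cb, g, 3)
    est <- position_estimate(cb, idx)
    sel <- cb$coordinates[idx, ]
    expect_true(all(est >= apply(sel, 2, min) - 1e-12))
    expect_true(all(est <= apply(sel, 2, max) + 1e-12))
  }
})

test_that("noiseless grid queries return the queried reference point", {
  sc <- default_anchor_scene(sigma_db = 0)
  pts <- as.matrix(expand.grid(x = seq(5, 45, by = 10), y = seq(5, 45, by = 10)))
  traj1 <- function(p) structure(list(positions = matrix(p, 1, 2), time_s = 0,
                                      dt = 0.1), class = "trajectory")
  rec <- lapply(seq_len(nrow(pts)), function(i)
    clip_rss(simulate_rss(sc, traj1(pts[i, ])))$rss)
  cb <- build_codebook(rec, cbind(pts, 0))
  for (i in c(1, 7, 25)) {
    g <- clip_rss(simulate_rss(sc, traj1(pts[i, ])))$rss[1, ]
    expect_equal(closest_fingerprints(cb, g, 1), i)
    expect_equal(position_estimate(cb, closest_fingerprints(cb, g, 1)),
                 c(pts[i, ], 0))
  }
})

test_that("localization error summary matches direct recomputation", {
  est <- rbind(c(0, 0, 0), c(2, 0, 0))
  tru <- rbind(c(0, 0, 0), c(0, 0, 0))
  ev <- evaluate_localization(est, tru)
  expect_equal(ev$mse, 2)            # (0 + 4) / 2
  expect_equal(ev$errors, c(0, 2))
  ev2 <- evaluate_localization(tru, tru)
  expect_equal(ev2$mse, 0)
  set.seed(35)
  a <- matrix(stats::rnorm(30), 10)
  b <- matrix(stats::rnorm(30), 10)
  ev3 <- evaluate_localization(a, b)
  expect_equal(ev3$mse, mean(rowSums((a - b)^2)))
  expect_error(evaluate_localization(a[1:3, ], b), "lengths differ")
})

test_that("codebook JSON round-trips", {
  fp <- matrix(stats::runif(8, -90, -60), 2, 4)
  cb <- build_codebook(lapply(1:2, function(i) fp[i, , drop = FALSE]),
                       coordinates = rbind(c(1, 2, 0), c(3, 4, 0)),
                       rooms = c(1L, 2L), grid_ij = rbind(c(1, 1), c(1, 2)))
  path <- tempfile(fileext = ".json")
  write_codebook_json(cb, path)
  rt <- read_codebook_json(path)
  expect_equal(rt$fingerprints, cb$fingerprints)
  expect_equal(rt$coordinates, cb$coordinates)
  expect_equal(rt$rooms, cb$rooms)
})

test_that("permuting codebook entries only affects tie resolution", {
  set.seed(36)
  n <- 10
  fp <- matrix(stats::runif(n * 4, -95, -55), n, 4)
  coords <- cbind(stats::runif(n), stats::runif(n), 0)
  cb <- build_codebook(lapply(seq_len(n), function(i) fp[i, , drop = FALSE]), coords)
  perm <- sample.int(n)
  cb2 <- build_codebook(lapply(perm, function(i) fp[i, , drop = FALSE]),
                        coords[perm, ])
  for (rep in 1:10) {
    g <- stats::runif(4, -95, -55)   # distinct distances almost surely
    i1 <- closest_fingerprints(cb, g, 3)
    i2 <- closest_fingerprints(cb2, g, 3)
    expect_equal(position_estimate(cb, i1), position_estimate(cb2, i2),
                 tolerance = 1e-12)
  }
})
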