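## Reference simulation protocols: the proximity-reporting study on the
## 50 m x 50 m ten-anchor scene.

#' Run one proximity-reporting simulation
#'
#' The reference protocol on the default rehabilitation-centre scene: a
#' bounded random walk is simulated for the training period (10 Hz beacon
#' rate) under the training shadowing variance, RSS is clipped and scaled,
#' and a classifier is trained per its configuration. A second, independent
#' walk is then simulated under the test shadowing variance and the
#' vicinity reports (15 m radius) are scored with
#' [proximity_metrics()].
#'
#' @param arch `"dnn"` or `"lstm"`.
#' @param seed Integer seed; all walks, shadowing draws and training
#'   randomness derive from it.
#' @param test_shadowing_var Shadowing variance (dB^2) of the test walk.
#' @param cfg A `proximity_config` (training protocol).
#' @param scene An `anchor_scene`.
#' @param train_duration_s Duration of the training walk in seconds
#'   (10 Hz sampling).
#' @param test_steps Number of test-walk steps.
#' @param step_sd Random-walk step standard deviation (metres).
#' @param radius_m Vicinity radius (metres).
#' @return List with `metrics` (on the test walk), the trained `model`,
#'   and the evaluation inputs `features` / `labels`.
#' @export
proximity_experiment <- function(arch = c("dnn", "lstm"), seed = 1,
                                 test_shadowing_var = 15,
                                 cfg = proximity_config(arch),
                                 scene = default_anchor_scene(),
                                 train_duration_s = 500, test_steps = 1000,
                                 step_sd = 2, radius_m = 15) {
  arch <- match.arg(arch)
  rate_hz <- 10
  train_walk <- bounded_random_walk(scene$bounds, round(train_duration_s * rate_hz),
                                    step_sd, seed = seed * 1000 + 1, dt = 1 / rate_hz)
  xtr <- scale_inputs(clip_rss(simulate_rss(
    scene, train_walk, seed = seed * 1000 + 2,
    sigma_db = sqrt(cfg$train_shadowing_var))))
  ytr <- vicinity_labels(scene, train_walk, radius_m)
  model <- train_proximity(xtr, ytr, cfg, seed = seed)
  ev <- evaluate_proximity_model(model, seed, test_shadowing_var, scene,
                                 test_steps, step_sd, radius_m)
  c(list(model = model), ev)
}

#' Evaluate a trained proximity model on a fresh test walk
#'
#' @param model A trained `proximity_model`.
#' @param seed Integer seed for the test walk and its shadowing.
#' @param test_shadowing_var Shadowing variance (dB^2) of the test walk.
#' @param scene,test_steps,step_sd,radius_m As in
#'   [proximity_experiment()].
#' @return List with `metrics`, `features`, `labels`.
#' @export
evaluate_proximity_model <- function(model, seed, test_shadowing_var = 15,
                                     scene = default_anchor_scene(),
                                     test_steps = 1000, step_sd = 2,
                                     radius_m = 15) {
  test_walk <- bounded_random_walk(scene$bounds, test_steps, step_sd,
                                   seed = seed * 1000 + 3, dt = 0.1)
  xte <- scale_inputs(clip_rss(simulate_rss(
    scene, test_walk, seed = seed * 1000 + 4,
    sigma_db = sqrt(test_shadowing_var))))
  yte <- vicinity_labels(scene, test_walk, radius_m)
  list(metrics = proximity_metrics(predict_proximity(model, xte), yte),
       features = xte, labels = yte)
}

#' Accuracy of both classifiers across seeds and test severities
#'
#' Trains one model per architecture and seed under the training protocol,
#' then evaluates it at each requested test shadowing variance (each
#' evaluation uses an independent test walk).
#'
#' @param seeds Integer seeds (one model per architecture per seed).
#' @param test_vars Test shadowing variances (dB^2).
#' @param archs Architectures to run.
#' @param ... Passed to [proximity_experiment()].
#' @return Data frame with columns `arch`, `seed`, `test_var`,
#'   `proximity`, `distance`, `overall`.
#' @export
proximity_accuracy_sweep <- function(seeds = 1:10, test_vars = 15,
                                     archs = c("dnn", "lstm"), ...) {
  rows <- list()
  for (arch in archs) for (seed in seeds) {
    first <- proximity_experiment(arch, seed, test_shadowing_var = test_vars[1], ...)
    res <- list(first$metrics)
    if (length(test_vars) > 1) {
      for (v in test_vars[-1])
        res <- c(res, list(evaluate_proximity_model(
          first$model, seed + round(1e4 * v), test_shadowing_var = v)$metrics))
    }
    for (k in seq_along(test_vars)) {
      m <- res[[k]]
      rows[[length(rows) + 1]] <- data.frame(
        arch = arch, seed = seed, test_var = test_vars[k],
        proximity = m$proximity, distance = m$distance, overall = m$overall)
    }
  }
  do.call(rbind, rows)
}
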