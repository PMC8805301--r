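test_that("the layer census matches the fixed block structure", {
  lay <- icering:::network_layers(architecture_config())
  expect_identical(sum(lay == "conv"), 8L)
  expect_identical(sum(lay == "max_pool"), 4L)
  expect_identical(sum(lay == "batch_norm"), 8L)
  expect_identical(sum(lay == "dense"), 2L)
  expect_identical(sum(lay == "dropout"), 2L)
  expect_identical(sum(lay == "sigmoid_output"), 1L)
  # pooling halves 80 four times; the flatten input is 5x5xfilters[4]
  expect_identical(tail(lay, 1), "sigmoid_output")
})

# independent arithmetic oracle over layer shapes
param_oracle <- function(filters, dense, k = 3, input = 80) {
  cin <- c(1, filters[1], filters[1], filters[2], filters[2],
           filters[3], filters[3], filters[4])
  cout <- rep(filters, each = 2)
  conv <- sum(cout * (cin * k * k + 1))
  bn <- sum(2 * cout)
  flat <- (input / 16)^2 * filters[4]
  fc <- dense[1] * (flat + 1) + dense[2] * (dense[1] + 1) + 1 * (dense[2] + 1)
  conv + bn + fc
}

test_that("trainable parameter counts equal the hand-computed total", {
  for (cfgs in list(list(f = c(6, 12, 24, 48), d = c(48, 24)),
                    list(f = c(32, 64, 128, 256), d = c(256, 64)),
                    list(f = c(2, 3, 4, 5), d = c(8, 4)))) {
    arch <- architecture_config(filters = cfgs$f, dense_units = cfgs$d)
    net <- build_network(arch, seed = 1)
    expect_identical(n_parameters(net), param_oracle(cfgs$f, cfgs$d))
  }
})

test_that("scores are sigmoid-bounded for arbitrary finite inputs", {
  net <- build_network(tiny_arch(), seed = 2)
  zero <- array(0, c(80, 80, 1))
  set.seed(3)
  wild <- array(rnorm(80 * 80 * 4, 0, 50), c(80, 80, 4))
  s <- predict_scores(net, zero)
  expect_true(s >= 0 && s <= 1)
  s2 <- predict_scores(net, wild)
  expect_true(all(s2 >= 0 & s2 <= 1))
})

test_that("zero-epoch training leaves predictions identical to the fresh network", {
  tp <- toy_plots(20)
  tc <- training_config(epochs = 0, seed = 5)
  trained <- train_network(tp$x, tp$y, arch = tiny_arch(), tc = tc)
  fresh <- build_network(tiny_arch(), seed = 5)
  expect_equal(predict_scores(trained, tp$x), predict_scores(fresh, tp$x))
})

test_that("training is seed-reproducible and reduces the training loss", {
  tp <- toy_plots(80)
  tc <- training_config(epochs = 5, seed = 11, learning_rate = 3e-3)
  m1 <- train_network(tp$x, tp$y, arch = tiny_arch(), tc = tc)
  m2 <- train_network(tp$x, tp$y, arch = tiny_arch(), tc = tc)
  expect_identical(m1$history, m2$history)
  expect_lt(tail(m1$history$loss, 1), m1$history$loss[1])
})

test_that("single-class labels are rejected for non-trivial training", {
  tp <- toy_plots(10)
  expect_error(
    train_network(tp$x, rep(TRUE, 10), arch = tiny_arch(),
                  tc = training_config(epochs = 1)),
    "degenerate")
})

test_that("a score at the threshold counts as contaminated; blanks bypass the network", {
  win <- ice_ring_windows()[4, ]
  set.seed(8)
  s <- fake_set(runif(400, 2.5, 2.9), rexp(400))
  pl <- make_plot(s, win)
  net <- build_network(tiny_arch(), seed = 3)
  net$trained <- TRUE
  pr <- predict_plot(net, pl)
  expect_true(pr$predictable)
  # the >= tie rule: a threshold exactly at the score still flags the plot
  net$threshold <- pr$score
  expect_true(predict_plot(net, pl)$contaminated)
  net$threshold <- pr$score + 1e-9
  expect_false(predict_plot(net, pl)$contaminated)

  blank_set <- fake_set(seq(5, 30, length.out = 100), rexp(100))
  blank_plot <- make_plot(blank_set, win)
  expect_warning(prb <- predict_plot(net, blank_plot), "nonpredictable")
  expect_false(prb$predictable)
  expect_true(is.na(prb$score))
})

test_that("kind mismatch warns but still predicts", {
  win <- ice_ring_windows()[4, ]
  s <- fake_set(runif(200, 2.5, 2.9), rexp(200), kind = "amplitude")
  pl <- make_plot(s, win)
  net <- build_network(tiny_arch(), seed = 3)
  net$kind <- "intensity"
  expect_warning(pr <- predict_plot(net, pl), "differs")
  expect_true(is.finite(pr$score))
})

test_that("dataset aggregation ORs the predictable windows and handles all-blank sets", {
  net <- build_network(tiny_arch(), seed = 4)
  net$trained <- TRUE
  cc <- unit_cell(40, 40, 44)
  sim <- simulate_reflections(simulation_params(cc, d_min = 1.7, n_target = 8000, seed = 2))
  pred <- suppressWarnings(predict_dataset(net, sim$set))
  w <- pred$windows
  expect_identical(nrow(w), 8L)
  expected <- if (!any(w$predictable)) "nonpredictable" else
    if (any(w$contaminated[w$predictable])) "contaminated" else "clean"
  expect_identical(pred$verdict, expected)
  # OR-monotonicity: forcing any one window positive can only keep/raise the verdict
  if (pred$verdict == "contaminated") {
    expect_true(any(w$score[w$predictable] >= net$threshold))
  }

  # a set whose every window shell was omitted is nonpredictable as a whole
  blanked <- simulate_reflections(
    simulation_params(cc, d_min = 1.7, blank_ranges = LETTERS[1:8],
                      n_target = 8000, seed = 3))
  predb <- suppressWarnings(predict_dataset(net, blanked$set))
  expect_identical(predb$verdict, "nonpredictable")
  expect_false(any(predb$windows$predictable))
})

test_that("smoothgrad returns input-shaped maps and degenerates to the plain gradient", {
  net <- build_network(tiny_arch(), seed = 6)
  win <- ice_ring_windows()[4, ]
  set.seed(13)
  s <- fake_set(runif(300, 2.5, 2.9), rexp(300))
  pl <- make_plot(s, win)
  expect_error(smoothgrad(net, pl, n_samples = 0), "n_samples")
  m <- smoothgrad(net, pl, n_samples = 4, noise_sigma = 0.1, seed = 2)
  expect_identical(dim(m), c(80L, 80L))
  expect_true(all(is.finite(m)) && all(m >= 0))
  plain <- abs(icering:::cnn_input_grad_core(net$weights, unclass(net$arch),
                                             array(pl$grid, c(80, 80, 1)))[, , 1])
  expect_equal(smoothgrad(net, pl, n_samples = 1, noise_sigma = 0), plain)
})

test_that("zero-epoch transfer is the identity on predictions and uses rate 0.0005", {
  expect_identical(training_config()$transfer_learning_rate, 5e-4)
  tp <- toy_plots(16)
  base <- train_network(tp$x, tp$y, arch = tiny_arch(),
                        tc = training_config(epochs = 2, seed = 9))
  moved <- transfer_network(base, tp$x, tp$y,
                            tc = training_config(epochs = 0, seed = 10))
  expect_equal(predict_scores(moved, tp$x), predict_scores(base, tp$x))
})

test_that("classifier bundles round-trip through disk with their featurization config", {
  tp <- toy_plots(16)
  m <- train_network(tp$x, tp$y, arch = tiny_arch(),
                     tc = training_config(epochs = 1, seed = 2), kind = "intensity")
  path <- tempfile(fileext = ".rds")
  save_classifier(m, path, plot_cfg = plot_config(min_reflections = 40))
  r <- load_classifier(path)
  expect_identical(r$kind, "intensity")
  expect_identical(r$plot_cfg$min_reflections, 40L)
  expect_equal(predict_scores(r, tp$x), predict_scores(m, tp$x))
})
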