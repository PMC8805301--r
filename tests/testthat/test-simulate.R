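test_that("lattice enumeration matches a brute-force count on a toy cell", {
  cc <- unit_cell(10, 10, 10)
  g <- icering:::enumerate_indices(cc, 2)
  # oracle: loop the full index cube, keep the Friedel-unique half with d >= 2
  cnt <- 0L
  for (h in -6:6) for (k in -6:6) for (l in -6:6) {
    if (h == 0 && k == 0 && l == 0) next
    if (!(h > 0 || (h == 0 && k > 0) || (h == 0 && k == 0 && l > 0))) next
    if (10 / sqrt(h^2 + k^2 + l^2) >= 2) cnt <- cnt + 1L
  }
  expect_identical(nrow(g), cnt)
  expect_true(all(g$d >= 2))
})

test_that("uncontaminated simulations are labelled clean everywhere", {
  cc <- unit_cell(38, 40, 42)
  sim <- simulate_reflections(simulation_params(cc, d_min = 1.7, n_target = 6000, seed = 4))
  expect_identical(length(sim$labels), 8L)
  expect_true(all(!sim$labels))
  expect_true(all(is.finite(sim$set$value)))
  expect_true(all(sim$set$d >= 1.7))
  # spike factor exactly 1 is no contamination either
  sim1 <- simulate_reflections(simulation_params(
    cc, d_min = 1.7, n_target = 6000, seed = 4,
    contaminated_ranges = data.frame(label = "D", spike_factor = 1, affected_fraction = 1)))
  expect_true(all(!sim1$labels))
})

test_that("the injected spike scales the in-window mean by the spike factor", {
  cc <- unit_cell(55, 60, 58)
  p <- simulation_params(cc, d_min = 1.7, scale = 200, wilson_B = 20,
                         sigma_fraction = 0.1,
                         contaminated_ranges = data.frame(
                           label = "E", spike_factor = 5, affected_fraction = 1),
                         n_target = 50000, seed = 6)
  sim <- simulate_reflections(p)
  win <- sim$windows[sim$windows$label == "E", ]
  inw <- sim$set$d >= win$d_low & sim$set$d <= win$d_high
  n <- sum(inw)
  pred <- mean(200 * exp(-20 / (2 * sim$set$d[inw]^2)))
  ratio <- mean(sim$set$value[inw]) / pred
  se <- 5 / sqrt(n)  # exponential: sd of the mean ratio ~ s/sqrt(n)
  expect_lt(abs(ratio - 5), 3 * se)
  expect_true(sim$labels[["E"]])
})

test_that("blank shells are omitted and labelled nonpredictable", {
  cc <- unit_cell(40, 40, 40)
  sim <- simulate_reflections(simulation_params(
    cc, d_min = 1.7, blank_ranges = c("C", "F"), n_target = 8000, seed = 8))
  for (lab in c("C", "F")) {
    win <- sim$windows[sim$windows$label == lab, ]
    expect_false(any(sim$set$d >= win$d_low & sim$set$d <= win$d_high))
    expect_true(is.na(sim$labels[[lab]]))
  }
})

test_that("simulation and corpus generation are seed-deterministic", {
  cc <- unit_cell(36, 38, 40)
  p <- simulation_params(cc, d_min = 1.8, n_target = 3000, seed = 12,
                         contaminated_ranges = data.frame(
                           label = "B", spike_factor = 4, affected_fraction = 0.5))
  s1 <- simulate_reflections(p)
  s2 <- simulate_reflections(p)
  expect_identical(s1$set$value, s2$set$value)
  expect_identical(s1$labels, s2$labels)

  c1 <- make_corpus(4, seed = 33)
  c2 <- make_corpus(4, seed = 33)
  expect_identical(lapply(c1$plots, function(p) p$grid),
                   lapply(c2$plots, function(p) p$grid))
  expect_identical(c1$labels, c2$labels)
})

test_that("corpus labels track the requested contamination fraction", {
  corpus <- make_corpus(100, fraction_contaminated = 0.075,
                        spike_range = c(3, 8), blank_fraction = 0, seed = 44)
  frac <- mean(corpus$labels, na.rm = TRUE)
  expect_lt(abs(frac - 0.075), 0.02)

  clean <- make_corpus(10, fraction_contaminated = 0, seed = 45)
  expect_true(all(!clean$labels, na.rm = TRUE))
  expect_error(make_corpus(1), "n_sets")
  expect_error(make_corpus(5, difficulty = c(bogus = 1)), "difficulty")
})

test_that("strong full-window spikes almost always satisfy the visibility labelling rule", {
  corpus <- make_corpus(40, fraction_contaminated = 0.2, spike_range = c(4, 8),
                        difficulty = c(strong = 1), blank_fraction = 0, seed = 46)
  mf <- corpus$manifest
  strong <- mf$spike_factor >= 4 & mf$affected_fraction == 1 & !is.na(mf$label)
  expect_gte(mean(mf$label[strong]), 0.9)
  # the rare invisible strong spikes are confined to sparsely populated windows
  misses <- strong & !mf$label
  if (any(misses)) expect_lt(max(mf$n_in_range[misses]), 200)
})

test_that("averaged contaminated plots exceed clean ones in the central upper region", {
  # matched pairs: same windows, with and without a strong central spike
  mk <- function(contaminate, seed) {
    cc <- unit_cell(42, 44, 40)
    cr <- if (contaminate) {
      data.frame(label = "E", spike_factor = 6, affected_fraction = 1)
    } else NULL
    sim <- simulate_reflections(simulation_params(
      cc, d_min = 1.9, contaminated_ranges = cr, n_target = 6000, seed = seed))
    make_plot(sim$set, sim$windows[sim$windows$label == "E", ])
  }
  cont <- lapply(1:12, function(i) mk(TRUE, 100 + i))
  clean <- lapply(1:12, function(i) mk(FALSE, 100 + i))
  dif <- average_plots(cont) - average_plots(clean)
  # in the upper half of the plot the maximum excess of the contaminated
  # average sits in the central columns, and nearly all upper-half excess
  # mass is central: the averaged spike signature
  up <- dif[41:80, ]
  pos <- which(up == max(up), arr.ind = TRUE)[1, ]
  expect_gte(unname(pos["col"]), 28)
  expect_lte(unname(pos["col"]), 53)
  excess <- colSums(pmax(up, 0))
  expect_gt(sum(excess[28:53]), 5 * sum(excess[c(1:27, 54:80)]))
})
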