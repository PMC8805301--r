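test_that("window selection keeps exactly the fully contained windows", {
  # data spanning ~50-1.5 A covers all eight default windows
  full <- fake_set(d = seq(1.5, 50, length.out = 500), value = rexp(500))
  expect_identical(select_ranges(full)$label, LETTERS[1:8])

  low_res <- fake_set(d = seq(8, 20, length.out = 100), value = rexp(100))
  expect_identical(nrow(select_ranges(low_res)), 0L)

  toy <- data.frame(label = "Z", d_high = 3.9, d_low = 3.6)
  partial <- fake_set(d = seq(3.7, 10, length.out = 100), value = rexp(100))
  expect_identical(nrow(select_ranges(partial, toy)), 0L)
  containing <- fake_set(d = seq(3.5, 10, length.out = 100), value = rexp(100))
  expect_identical(select_ranges(containing, toy)$label, "Z")
})

test_that("clip limits follow the linear-interpolation percentile convention", {
  expect_equal(unname(clip_limits(0:1000)), c(5.0, 950.0))
  expect_equal(unname(clip_limits(rep(3.7, 40))), c(3.7, 3.7))
  # matches R's type-7 quantile on irregular data
  set.seed(1)
  v <- rlnorm(313)
  expect_equal(unname(clip_limits(v)),
               unname(quantile(v, c(0.005, 0.95), type = 7)))
})

test_that("the histogram matches a brute-force nested-loop binning exactly", {
  set.seed(99)
  cfg <- plot_config()
  win <- ice_ring_windows()[5, ]  # window E
  for (rep in 1:25) {
    n <- sample(5:100, 1)
    # scatter reflections around the window, some outside the padded extent
    d <- runif(n, win$d_low * 0.85, win$d_high * 1.2)
    v <- rexp(n, 1 / 100) - 5
    s <- fake_set(d, v)
    p <- make_plot(s, win, cfg)
    expect_identical(p$raw, oracle_grid(d, v, win, cfg))
  }
})

test_that("histogram counts conserve the in-extent, in-clip reflection mass", {
  set.seed(5)
  cfg <- plot_config()
  win <- ice_ring_windows()[3, ]
  geom <- icering:::plot_x_geometry(win, cfg)
  for (rep in 1:30) {
    n <- sample(50:2000, 1)
    d <- runif(n, 1.6, 6)
    v <- rexp(n, 1 / 50)
    s <- fake_set(d, v)
    p <- make_plot(s, win, cfg)
    x <- 1 / d^2
    inx <- x >= geom$lo & x <= geom$hi
    expect_identical(p$n_in_range, sum(inx))
    in_clip <- sum(v[inx] >= p$clip_lo & v[inx] <= p$clip_hi)
    expect_identical(sum(p$raw), in_clip)
  }
})

test_that("x binning is monotone in 1/d^2 and identical inputs give identical grids", {
  cfg <- plot_config()
  win <- ice_ring_windows()[1, ]
  set.seed(12)
  d <- runif(400, 3.5, 4.4)
  v <- rexp(400)
  s <- fake_set(d, v)
  p1 <- make_plot(s, win, cfg)
  p2 <- make_plot(s, win, cfg)
  expect_identical(p1$grid, p2$grid)

  # column index recovered per reflection must be non-decreasing in 1/d^2
  geom <- icering:::plot_x_geometry(win, cfg)
  x <- 1 / d^2
  keep <- x >= geom$lo & x <= geom$hi
  ix <- pmin(floor((x[keep] - geom$lo) / (geom$hi - geom$lo) * cfg$n_bins_x) + 1, cfg$n_bins_x)
  o <- order(x[keep])
  expect_true(all(diff(ix[o]) >= 0))
})

test_that("empty windows give a blank all-zero plot", {
  win <- ice_ring_windows()[8, ]
  s <- fake_set(d = seq(5, 30, length.out = 300), value = rexp(300))
  p <- make_plot(s, win)
  expect_true(p$blank)
  expect_false(p$predictable)
  expect_identical(sum(p$raw), 0L)
  expect_identical(p$n_in_range, 0L)
  expect_true(all(p$grid == 0))
})

test_that("normalized grids live in [0,1] with maximum exactly 1 when occupied", {
  set.seed(2)
  win <- ice_ring_windows()[4, ]
  s <- fake_set(runif(500, 2.5, 2.9), rexp(500))
  p <- make_plot(s, win)
  expect_true(all(p$grid >= 0 & p$grid <= 1))
  expect_equal(max(p$grid), 1)
})

test_that("blank discrimination flags zeroed and missing shells, passes healthy ones", {
  win <- ice_ring_windows()[5, ]
  d_all <- seq(1.9, 3.0, length.out = 3000)
  healthy <- fake_set(d_all, rexp(3000, 1 / 40))
  expect_false(is_blank(healthy, win))

  zeroed <- healthy
  zeroed$value[d_all >= win$d_low & d_all <= win$d_high] <- 0
  expect_true(is_blank(zeroed, win))

  inwin <- d_all >= win$d_low & d_all <= win$d_high
  missing <- fake_set(d_all[!inwin], rexp(sum(!inwin), 1 / 40))
  expect_true(is_blank(missing, win))

  # partially omitted shells (half the window) are also caught
  half <- d_all >= win$d_low & d_all <= (win$d_low + win$d_high) / 2
  partial <- fake_set(d_all[!half], rexp(sum(!half), 1 / 40))
  expect_true(is_blank(partial, win))
})

test_that("plot averaging is the element-wise mean and validates its inputs", {
  set.seed(4)
  win <- ice_ring_windows()[2, ]
  s1 <- fake_set(runif(300, 3.4, 3.9), rexp(300))
  s2 <- fake_set(runif(300, 3.4, 3.9), rexp(300, 1 / 3))
  p1 <- make_plot(s1, win); p2 <- make_plot(s2, win)
  expect_identical(average_plots(list(p1, p1, p1)), p1$grid)
  expect_equal(average_plots(list(p1, p2)), (p1$grid + p2$grid) / 2)
  expect_error(average_plots(list()), "empty")
  p2f <- p2; p2f$kind <- "amplitude"
  expect_error(average_plots(list(p1, p2f)), "mix")
})
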