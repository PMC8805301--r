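make_toy_set <- function(kind = "intensity", n = 200, seed = 3) {
  set.seed(seed)
  cc <- unit_cell(30, 35, 40)
  h <- sample(1:8, n, TRUE); k <- sample(-8:8, n, TRUE); l <- sample(-8:8, n, TRUE)
  reflection_set(h, k, l, value = rexp(n, 1 / 50) - 2, sigma = runif(n, 0.1, 5),
                 cell = cc, kind = kind)
}

test_that("plain-text dialect round-trips values, sigmas, indices and kind exactly", {
  s <- make_toy_set()
  s$sigma[5] <- NA
  path <- tempfile(fileext = ".txt")
  write_reflections(s, path)
  r <- read_reflections(path)
  expect_identical(r$hkl, s$hkl)
  expect_equal(r$value, s$value)
  expect_equal(r$sigma, s$sigma)
  expect_identical(r$kind, s$kind)
  expect_equal(unlist(r$cell), unlist(s$cell))
})

test_that("MTZ writer output is read back (float32 storage precision)", {
  for (kind in c("intensity", "amplitude")) {
    s <- make_toy_set(kind)
    path <- tempfile(fileext = ".mtz")
    write_mtz(s, path)
    r <- read_reflections(path)
    expect_identical(r$kind, kind)
    expect_identical(r$hkl, s$hkl)
    expect_equal(r$value, s$value, tolerance = 1e-6)
    expect_equal(r$sigma, s$sigma, tolerance = 1e-6)
    expect_equal(r$d, s$d, tolerance = 1e-6)
  }
})

test_that("column selection prefers observed intensities over amplitudes", {
  set.seed(9)
  cc <- unit_cell(20, 20, 25)
  n <- 50
  hkl <- cbind(sample(1:5, n, TRUE), sample(-5:5, n, TRUE), sample(-5:5, n, TRUE))
  I <- rexp(n, 1 / 30)
  path <- tempfile(fileext = ".mtz")
  # file order puts the amplitude columns first: the type rule must still win
  icering:::mtz_write_table(
    path, cc,
    cbind(hkl, sqrt(I), sqrt(I) / 10, I, I / 10),
    labels = c("H", "K", "L", "FOBS", "SIGF", "IOBS", "SIGI"),
    types = c("H", "H", "H", "F", "Q", "J", "Q"))
  r <- read_reflections(path)
  expect_identical(r$kind, "intensity")
  expect_equal(r$value, I, tolerance = 1e-6)

  # amplitude-only file falls back to F
  path2 <- tempfile(fileext = ".mtz")
  icering:::mtz_write_table(
    path2, cc, cbind(hkl, sqrt(I), sqrt(I) / 10),
    labels = c("H", "K", "L", "FP", "SIGFP"),
    types = c("H", "H", "H", "F", "Q"))
  r2 <- read_reflections(path2)
  expect_identical(r2$kind, "amplitude")

  # with several observables of one type, the first listed (first dataset) wins
  path3 <- tempfile(fileext = ".mtz")
  icering:::mtz_write_table(
    path3, cc, cbind(hkl, I, I / 10, 2 * I, I / 5),
    labels = c("H", "K", "L", "IOBS_W1", "SIGI_W1", "IOBS_W2", "SIGI_W2"),
    types = c("H", "H", "H", "J", "Q", "J", "Q"))
  r3 <- read_reflections(path3)
  expect_equal(r3$value, I, tolerance = 1e-6)
})

test_that("a file with no observable column raises a no-observable error", {
  set.seed(10)
  cc <- unit_cell(20, 20, 25)
  n <- 20
  hkl <- cbind(sample(1:5, n, TRUE), sample(-5:5, n, TRUE), sample(-5:5, n, TRUE))
  path <- tempfile(fileext = ".mtz")
  icering:::mtz_write_table(
    path, cc, cbind(hkl, runif(n, -180, 180), sample(0:19, n, TRUE)),
    labels = c("H", "K", "L", "PHIB", "FREE"),
    types = c("H", "H", "H", "P", "I"))
  expect_error(read_reflections(path), "no observable")
  expect_error(read_reflections(tempfile()), "not found")
})

test_that("the MTZ codec interoperates with an external reference reader", {
  s <- make_toy_set(n = 80, seed = 21)
  path <- tempfile(fileext = ".mtz")
  write_mtz(s, path)
  out_csv <- tempfile(fileext = ".csv")
  script <- sprintf(paste0(
    "import gemmi, numpy as np, csv\n",
    "m = gemmi.read_mtz_file('%s')\n",
    "cols = [c.label for c in m.columns]\n",
    "arr = np.array(m, copy=False)\n",
    "with open('%s','w',newline='') as f:\n",
    "    w = csv.writer(f); w.writerow(cols)\n",
    "    for row in arr: w.writerow([repr(float(v)) for v in row])\n"),
    path, out_csv)
  status <- system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out_csv) && file.info(out_csv)$size > 0)
  ext <- utils::read.csv(out_csv, check.names = FALSE)
  expect_identical(names(ext), c("H", "K", "L", "IOBS", "SIGI"))
  o <- order(ext$H, ext$K, ext$L)
  oo <- order(s$hkl[, 1], s$hkl[, 2], s$hkl[, 3])
  expect_equal(ext$IOBS[o], s$value[oo], tolerance = 1e-6)
})
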