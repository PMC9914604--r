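test_that("pixel positions are drawn once and shared across frames", {
  b <- make_pulse_bundle(duration = 0.2, frame_size = 64)
  pre <- preprocess_sequence(read_frames(b),
                             preprocess_config(target_size = 64))
  s1 <- sample_pixels(pre, max_pixels = 2048, seed = 7)
  expect_length(s1, pre$n_frames)
  expect_equal(nrow(s1[[1]]$positions), 2048)
  for (s in s1) expect_identical(s$positions, s1[[1]]$positions)
  s2 <- sample_pixels(pre, max_pixels = 2048, seed = 7)
  expect_identical(s1[[1]]$positions, s2[[1]]$positions)
  # small frames: full row-major enumeration
  small <- preprocess_sequence(read_frames(b),
                               preprocess_config(target_size = 32))
  sf <- sample_pixels(small, max_pixels = 2048, seed = 1)
  expect_equal(nrow(sf[[1]]$positions), 32 * 32)
  expect_equal(sf[[1]]$positions[1:3, "col"], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(sf[[1]]$positions[1:3, "row"], c(1, 1, 1), ignore_attr = TRUE)
})

test_that("jonckheere statistic matches enumeration on worked examples", {
  expect_equal(jonckheere_stat(list(c(1, 2), c(3, 4))), 4)
  expect_equal(jonckheere_stat(list(c(1, 1), c(1, 1))), 2)
  expect_equal(jonckheere_stat(list(1, 2, 3)), 3)
  expect_error(jonckheere_stat(list(numeric(0), 1)), class = "pulsebeat_input_error")
  expect_error(jonckheere_stat(list(1)), class = "pulsebeat_input_error")
})

test_that("jonckheere statistic equals brute-force enumeration on random instances", {
  set.seed(20240917)
  for (trial in 1:100) {
    k <- sample(2:4, 1)
    sizes <- sample(1:10, k, replace = TRUE)
    while (sum(sizes) > 30) sizes <- sample(1:10, k, replace = TRUE)
    groups <- lapply(sizes, function(n) sample(0:8, n, replace = TRUE))
    expect_equal(jonckheere_stat(groups), jonckheere_brute(groups))
  }
})

test_that("reversing group order reflects J when no ties exist", {
  set.seed(99)
  for (trial in 1:25) {
    k <- sample(2:4, 1)
    vals <- sample(1:500, sample(6:20, 1))  # distinct values, no ties
    groups <- split(vals, sort(rep_len(seq_len(k), length(vals))))
    n_pairs <- sum(utils::combn(lengths(groups), 2, prod))
    expect_equal(jonckheere_stat(rev(groups)),
                 n_pairs - jonckheere_stat(groups))
  }
})

test_that("Mann-Whitney U statistics of swapped samples sum to n1 * n2", {
  set.seed(5)
  for (trial in 1:25) {
    x <- sample(0:20, sample(3:15, 1), replace = TRUE)
    y <- sample(0:20, sample(3:15, 1), replace = TRUE)
    expect_equal(pulsebeat:::mann_whitney_u(x, y) +
                   pulsebeat:::mann_whitney_u(y, x),
                 length(x) * length(y))
  }
})

test_that("all 14 statistics match independent references on seeded windows", {
  set.seed(31415)
  for (trial in 1:50) {
    n <- sample(c(40, 80, 160), 1)
    # quantized intensities with ties, plus occasional exact repeats
    x0 <- round(runif(n, 0, 255))
    x1 <- pmin(pmax(x0 + round(rnorm(n, 1, 6)), 0), 255)
    x2 <- pmin(pmax(x1 + round(rnorm(n, -1, 6)), 0), 255)
    fm <- compute_feature_matrix(
      list(list(values = x0), list(values = x1), list(values = x2)),
      frame_times = c(0, 1, 2) / 30)
    expect_equal(nrow(fm), 1)
    tol <- 1e-8
    expect_equal(fm$mean, mean(x2), tolerance = tol)
    expect_equal(fm$median, median(x2), tolerance = tol)
    expect_equal(fm$variance, var(x2), tolerance = tol)
    expect_equal(fm$std, sd(x2), tolerance = tol)
    expect_equal(fm$correlation, cor(x2, x1), tolerance = tol)
    expect_equal(fm$rmse, sqrt(mean((x2 - x1)^2)), tolerance = tol)
    expect_equal(fm$regression_slope,
                 unname(coef(lm(x2 ~ x1))[2]), tolerance = tol)
    expect_equal(fm$wilcoxon,
                 unname(suppressWarnings(
                   wilcox.test(x2, x1, paired = TRUE))$statistic),
                 tolerance = tol)
    expect_equal(fm$mann_whitney,
                 unname(suppressWarnings(wilcox.test(x2, x1))$statistic),
                 tolerance = tol)
    expect_equal(fm$ks,
                 unname(suppressWarnings(ks.test(x2, x1))$statistic),
                 tolerance = tol)
    expect_equal(fm$kruskal_wallis,
                 unname(kruskal.test(list(x0, x1, x2))$statistic),
                 tolerance = tol)
    expect_equal(fm$friedman,
                 unname(friedman.test(cbind(x0, x1, x2))$statistic),
                 tolerance = tol)
    expect_equal(fm$jonckheere, jonckheere_brute(list(x0, x1, x2)),
                 tolerance = tol)
    # chi-square against a direct histogram computation
    br <- seq(0, 256, by = 16)
    o1 <- hist(x2, breaks = br, plot = FALSE, right = FALSE)$counts
    o2 <- hist(x1, breaks = br, plot = FALSE, right = FALSE)$counts
    e <- (o1 + o2) / 2; keep <- e > 0
    expect_equal(fm$chi_square,
                 sum((o1[keep] - e[keep])^2 / e[keep] +
                       (o2[keep] - e[keep])^2 / e[keep]),
                 tolerance = tol)
    expect_true(all(is.finite(as.matrix(fm[, FEATURE_NAMES]))))
    expect_equal(fm$variance, fm$std^2, tolerance = 1e-9)
  }
})

test_that("degenerate and exact-relation windows follow the documented conventions", {
  x <- rep(100, 50)
  suppressMessages({
    fm <- compute_feature_matrix(
      list(list(values = x), list(values = x), list(values = x)),
      frame_times = (0:2) / 30)
  })
  expect_equal(fm$ks, 0); expect_equal(fm$rmse, 0)
  expect_equal(fm$chi_square, 0); expect_equal(fm$kruskal_wallis, 0)
  expect_equal(fm$friedman, 0); expect_equal(fm$correlation, 0)
  expect_equal(fm$wilcoxon, 0); expect_equal(fm$regression_slope, 0)

  fm2 <- compute_feature_matrix(
    list(list(values = c(9, 9, 9, 9)), list(values = c(1, 2, 3, 4)),
         list(values = c(2, 4, 6, 8))),
    frame_times = (0:2) / 30)
  expect_equal(fm2$regression_slope, 2)
  expect_equal(fm2$correlation, 1)

  expect_equal(pulsebeat:::ks_stat(c(1, 1), c(0, 0)), 1)  # disjoint CDFs

  expect_error(compute_feature_matrix(list(list(values = x)), 0),
               class = "pulsebeat_input_error")
})

test_that("feature matrix is deterministic, warm-up rows are skipped, CSV round-trips", {
  b <- make_pulse_bundle(duration = 1, noise_sigma = 2, frame_size = 48)
  pre <- preprocess_sequence(read_frames(b), preprocess_config(target_size = 48))
  sm <- sample_pixels(pre, max_pixels = 512, seed = 3)
  f1 <- compute_feature_matrix(sm, pre$timestamps)
  f2 <- compute_feature_matrix(sm, pre$timestamps)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), pre$n_frames - 2)
  expect_equal(f1$frame_index[1], 3)
  expect_equal(f1$time_s[1], pre$timestamps[3])
  csv <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(f1, csv)
  back <- read.csv(csv)
  expect_equal(back$jonckheere, f1$jonckheere)
  expect_equal(names(back), c("frame_index", "time_s", FEATURE_NAMES))
})
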