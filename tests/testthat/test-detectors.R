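test_that("a buffered diagonal track searches all four sub-cells of one cell", {
  tracks <- data.frame(track_id = 1, x = c(5, 95), y = c(5, 95))
  det <- buildDetectors(tracks, square_poly(200, -50, -50))
  expect_equal(nrow(det), 1L)
  expect_equal(det$K, 4L)
  expect_equal(sort(attr(det, "sub_cells")[[1]]), 1:4)
})

test_that("unsearched cells are absent and searched area matches geometry", {
  # wall-to-wall track through cell [0,100]^2: 3 m buffer -> 6 x 100 m2 band
  tracks <- data.frame(track_id = 1, x = c(0, 100), y = c(50, 50))
  det <- buildDetectors(tracks, square_poly(400, -150, -150))
  mid <- which(det$x == 50 & det$y == 50)
  expect_length(mid, 1L)
  expect_equal(det$effort_raw[mid], 600, tolerance = 0.02)
  # cells away from the track are not in the grid
  expect_true(all(abs(det$y - 50) <= 100))
  expect_lte(nrow(det), 3L)
})

test_that("degenerate and out-of-area tracks are handled", {
  expect_error(buildDetectors(data.frame(track_id = 1, x = 5, y = 5),
                              square_poly(100)), "single-point")
  expect_warning(
    det <- buildDetectors(data.frame(track_id = 1, x = c(1000, 1100),
                                     y = c(1000, 1000)),
                          square_poly(100)),
    "outside|no searched")
  expect_equal(nrow(det), 0L)
})

test_that("encounters are de-duplicated per searched sub-cell", {
  det <- detectorGrid(x = 50, y = 50, K = 4, effort_raw = 600)
  samples <- data.frame(
    individual_id = "a", sex = "F",
    x = c(10, 20, 5), y = c(10, 15, 30))     # all in the SW sub-cell
  enc <- assignDetections(samples, det)
  expect_equal(unname(enc$y[1, 1]), 1L)

  samples2 <- rbind(samples,
                    data.frame(individual_id = "a", sex = "F", x = 70, y = 10))
  enc2 <- assignDetections(samples2, det)
  expect_equal(unname(enc2$y[1, 1]), 2L)
  expect_equal(enc2$sex, c(a = 0))
})

test_that("samples in unsearched cells or sub-cells are dropped with reasons", {
  det <- detectorGrid(x = 50, y = 50, K = 2, effort_raw = 600,
                      sub_cells = list(c(1L, 2L)))   # southern half searched
  samples <- data.frame(individual_id = c("a", "a", "b"), sex = "F",
                        x = c(10, 10, 500), y = c(10, 80, 10))
  enc <- assignDetections(samples, det)
  expect_equal(nrow(enc$y), 1L)
  expect_equal(sort(enc$dropped$reason),
               sort(c("unsearched sub-cell", "unsearched detector cell")))
})

test_that("encounter counts never exceed the trial counts on random surveys", {
  set.seed(11)
  for (rep in 1:10) {
    n_det <- 20
    det <- detectorGrid(x = (sample(20, n_det) - 0.5) * 100,
                        y = (sample(20, n_det) - 0.5) * 100,
                        K = sample(1:4, n_det, replace = TRUE),
                        effort_raw = runif(n_det, 100, 9000))
    ids <- sample(letters[1:6], 100, replace = TRUE)
    sex_of <- setNames(sample(c("F", "M"), 6, replace = TRUE), letters[1:6])
    samples <- data.frame(
      individual_id = ids, sex = unname(sex_of[ids]),
      x = runif(100, 0, 2000), y = runif(100, 0, 2000))
    # sub_cells defaults to 1:K, so route samples through assignment and
    # check the binomial bound
    enc <- assignDetections(samples, det)
    if (nrow(enc$y))
      expect_true(all(sweep(enc$y, 2, det$K, "<=") == 1))
  }
})

test_that("long-recapture filter removes the farthest detection until capped", {
  det3 <- data.frame(individual_id = "a", detector_id = c(1L, 2L, 3L),
                     sub_cell = 1L, x = c(0, 100, 5000), y = 0)
  enc <- enc_from_detections(det3)
  out <- filterLongRecaptures(enc, cap = 1500)
  expect_equal(nrow(out$detections), 2L)
  expect_equal(out$removed$x, 5000)
  expect_equal(sort(out$detections$x), c(0, 100))
  expect_equal(out$applied_cap, 1500)
  # y rebuilt
  expect_equal(sum(out$y), 2)
})

test_that("the cap is the linear-interpolation percentile of the pooled distances", {
  # 101 two-detection individuals: pooled distances d_1..d_101 with the
  # 100th order statistic exactly 1500 -> 99th percentile = 1500 (type 7)
  dists <- c(seq(10, 990, length.out = 99), 1500, 5000)
  det <- do.call(rbind, lapply(seq_along(dists), function(i)
    data.frame(individual_id = sprintf("i%03d", i), detector_id = c(1L, 2L),
               sub_cell = 1L, x = c(0, dists[i]), y = i * 10000)))
  enc <- enc_from_detections(det)
  out <- filterLongRecaptures(enc, percentile = 99)
  expect_equal(out$applied_cap, 1500)
  # only the 5000 m recapture is broken up
  expect_equal(nrow(out$removed), 1L)
  expect_equal(out$removed$individual_id, "i101")
})

test_that("filtering is idempotent at a fixed cap and enforces the bound", {
  set.seed(12)
  det <- data.frame(individual_id = rep(sprintf("i%d", 1:8), each = 4),
                    detector_id = rep(1:4, 8), sub_cell = 1L,
                    x = rnorm(32, sd = 800), y = rnorm(32, sd = 800))
  enc <- enc_from_detections(det)
  f1 <- filterLongRecaptures(enc, cap = 1500)
  f2 <- filterLongRecaptures(f1, cap = 1500)
  expect_equal(f1$detections, f2$detections)
  for (id in unique(f1$detections$individual_id)) {
    p <- f1$detections[f1$detections$individual_id == id, c("x", "y")]
    if (nrow(p) > 1) expect_lte(max(dist(p)), 1500)
  }
})

test_that("no-recapture input is returned unchanged with a notice", {
  det <- data.frame(individual_id = c("a", "b"), detector_id = 1L,
                    sub_cell = 1L, x = c(0, 10), y = 0)
  enc <- enc_from_detections(det)
  expect_message(out <- filterLongRecaptures(enc), "no spatial recaptures")
  expect_identical(out$y, enc$y)
})
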