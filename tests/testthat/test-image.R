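test_that("pixel-to-voltage map is the stated affine transform", {
  expect_equal(pixel_to_voltage(0, 60, 100), 60)    # black pixel
  expect_equal(pixel_to_voltage(1, 60, 100), 160)   # white = V_black + V_white
  expect_equal(pixel_to_voltage(0.5, 60, 100), 110)
  expect_error(pixel_to_voltage(-0.1), "\\[0, 1\\]")
  expect_error(pixel_to_voltage(1.1), "\\[0, 1\\]")
})

test_that("average spike rate reproduces the worked example", {
  expect_equal(average_spike_rate(6, 120), 50)      # 6 spikes in 120 ns
  expect_equal(average_spike_rate(0, 100), 0)
  expect_equal(average_spike_rate(12, 240), average_spike_rate(6, 120))
})

test_that("synthetic test images have the advertised structure", {
  ramp <- generate_test_image("ramp", 256, 4)
  expect_equal(dim(ramp), c(4, 256))
  expect_equal(ramp[1, ], 0:255)                    # column k has level k
  expect_equal(ramp[3, 100], ramp[1, 100])

  cb <- generate_test_image("checkerboard", 8, 8)
  expect_setequal(unique(as.vector(cb)), c(0L, 255L))
  expect_equal(cb[1, 1], 0L)
  expect_equal(cb[1, 2], 255L)
  cb4 <- generate_test_image("checkerboard", 8, 8, cell = 4)
  expect_equal(cb4[1:4, 1:4], matrix(0L, 4, 4))

  blob <- generate_test_image("blob", 33, 33)
  expect_equal(which(blob == max(blob))[1], (17 - 1) * 33 + 17)
  expect_equal(blob[1, 1], 128L)                    # mid-grey background
})

test_that("grey images validate their range", {
  expect_error(grey_image(matrix(c(0, 300), 1)), "\\[0, 255\\]")
  expect_error(grey_image(matrix(c(-1, 4), 1)), "\\[0, 255\\]")
  expect_s3_class(grey_image(matrix(0:255, 16)), "grey_image")
})

test_that("PGM images round-trip in both plain and binary form", {
  img <- generate_test_image("ramp", 32, 5)
  p2 <- tempfile(fileext = ".pgm")
  p5 <- tempfile(fileext = ".pgm")
  write_pgm(img, p2)
  write_pgm(img, p5, binary = TRUE)
  expect_equal(unclass(read_pgm(p2)), unclass(img))
  expect_equal(unclass(read_pgm(p5)), unclass(img))
  expect_match(readLines(p2, n = 1), "^P2$")
  # header comments are tolerated
  lines <- readLines(p2)
  writeLines(c(lines[1], "# a comment", lines[-1]), p2)
  expect_equal(unclass(read_pgm(p2)), unclass(img))
  unlink(c(p2, p5))
})

test_that("PNG images round-trip", {
  img <- generate_test_image("blob", 17, 9)
  path <- tempfile(fileext = ".png")
  write_grey_png(img, path)
  expect_equal(unclass(read_grey_png(path)), unclass(img))
  unlink(path)
})

test_that("rank coding saturates at black and white extremes", {
  ens <- homog_ensemble(16)
  ccfg <- coding_config("rank")
  scfg <- sim_config(duration = 1)
  # sub-threshold black pixel: V = 60 mV < V_th for everyone
  expect_equal(rank_code_pixel(0, ens, ccfg, scfg, seed = 1), 0L)
  # white pixel: V = 160 mV, all members spike within 30 ns
  expect_equal(rank_code_pixel(1, ens, ccfg, scfg, seed = 2), 255L)
  # long windows leave the no-spike/one-spike regime
  expect_warning(
    rank_code_pixel(1, ens, coding_config("rank", tau_pixel = 200), scfg,
                    seed = 3),
    "no-spike/one-spike")
})

test_that("rank coding is monotone in the input grey level (in expectation)", {
  ens <- heterog_ensemble(16, seed = 4)
  ccfg <- coding_config("rank")
  scfg <- sim_config(duration = 1)
  g <- seq(0, 1, length.out = 16)
  means <- vapply(seq_along(g), function(i) {
    mean(vapply(1:20, function(r) {
      rank_code_pixel(g[i], ens, ccfg, scfg, seed = 1000 * i + r)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= -8))   # non-decreasing up to replicate noise
  expect_gt(means[16], means[1])
})

test_that("rate coding anchors its grey scale to the black/white rates", {
  ens <- heterog_ensemble(32, seed = 5)
  ccfg <- coding_config("rate", tau_pixel = 120)
  scfg <- sim_config(duration = 1)
  anchors <- calibrate_rate_anchors(ens, ccfg, scfg, seed = 9)
  expect_gt(anchors$f_max, anchors$f_min)
  lo <- rate_code_pixel(0, ens, ccfg, scfg, seed = 11, anchors = anchors)
  hi <- rate_code_pixel(1, ens, ccfg, scfg, seed = 12, anchors = anchors)
  mid <- rate_code_pixel(0.5, ens, ccfg, scfg, seed = 13, anchors = anchors)
  expect_lt(lo, 40)
  expect_gt(hi, 215)
  expect_true(mid > lo && mid < hi)
})

test_that("rate coding quantizes to N_grey levels", {
  ens <- heterog_ensemble(16, seed = 6)
  ccfg <- coding_config("rate", tau_pixel = 120, N_grey = 16)
  scfg <- sim_config(duration = 1)
  anchors <- calibrate_rate_anchors(ens, ccfg, scfg, seed = 2)
  lv <- vapply(c(0, 0.3, 0.6, 1), function(g) {
    rate_code_pixel(g, ens, ccfg, scfg, seed = 50 + round(100 * g),
                    anchors = anchors)
  }, integer(1))
  lattice <- as.integer(round(round((0:15) * 17) ))
  expect_true(all(lv %in% lattice))
})

test_that("a homogeneous ensemble still responds at the shifted black level", {
  # rate coding with V_black = 75 mV: the response region starts just below
  # the 80 mV threshold, so a black pixel elicits a small but nonzero rate
  ens <- homog_ensemble(64, seed = 2)
  total <- sum(vapply(1:5, function(r) {
    nrow(run_rset(ens, 75, sim_config(duration = 330, seed = 300 + r))$events)
  }, numeric(1)))
  expect_gt(total, 0)
})

test_that("image processing preserves dimensions and is reproducible", {
  ens <- heterog_ensemble(16, seed = 7)
  ccfg <- coding_config("rank")
  scfg <- sim_config(duration = 1)
  img <- generate_test_image("ramp", 8, 3)
  out1 <- process_image(img, ens, ccfg, scfg, seed = 42)
  out2 <- process_image(img, ens, ccfg, scfg, seed = 42)
  expect_equal(dim(out1), dim(img))
  expect_identical(out1, out2)
  # a 1x1 image reduces to the single-pixel operation with child seed + 0
  one <- process_image(grey_image(matrix(255L)), ens, ccfg, scfg, seed = 17)
  expect_equal(one[1, 1],
               rank_code_pixel(1, ens, ccfg, scfg, seed = 17))
  # an all-black sub-threshold image comes out all black
  black <- process_image(grey_image(matrix(0L, 2, 3)), ens, ccfg, scfg,
                         seed = 5)
  expect_true(all(black == 0))
})

test_that("heterogeneity widens the rank-coded grey palette on a ramp", {
  img <- generate_test_image("ramp", 64, 1)
  ccfg <- coding_config("rank")
  scfg <- sim_config(duration = 1)
  out0 <- process_image(img, homog_ensemble(32, seed = 8), ccfg, scfg,
                        seed = 100)
  out25 <- process_image(img, heterog_ensemble(32, seed = 8), ccfg, scfg,
                         seed = 100)
  expect_gt(length(unique(as.vector(out25))), length(unique(as.vector(out0))))
})
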