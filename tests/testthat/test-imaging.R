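test_that("granularity matches closed forms and the pixel-loop oracle", {
  img <- matrix(c(10, 10, 20, 20), 2, 2)
  mask <- matrix(1L, 2, 2)
  g <- granularity(img, mask)
  expect_equal(g$mean_intensity, 15)
  expect_equal(g$intensity_sd, 5)  # population s.d., divisor n
  # arbitrary image against the brute-force loop
  set.seed(7)
  img2 <- matrix(runif(400, 0, 4096), 20, 20)
  mask2 <- matrix(0L, 20, 20)
  mask2[3:9, 4:12] <- 1L
  mask2[12:18, 10:17] <- 2L
  o <- oracle_granularity(img2, mask2)
  g2 <- granularity(img2, mask2)
  expect_equal(g2$mean_intensity, o$mean_intensity, tolerance = 1e-12)
  expect_equal(g2$intensity_sd, o$intensity_sd, tolerance = 1e-9)
})

test_that("nucleus segmentation recovers generator masks", {
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64))$table), 0)
  g <- gen_nuclei_field(n_nuclei = 3, cluster_contrast = 0.5,
                        noise_sd = 40, seed = 11)
  seg <- segment_nuclei(g$image)
  expect_equal(nrow(seg$table), 3)
  for (i in 1:3) {
    tm <- g$labels == i
    overlap <- max(vapply(seq_len(nrow(seg$table)), function(j)
      sum(tm & seg$labels == j) / sum(tm), numeric(1)))
    expect_gte(overlap, 0.95)
  }
  # touching nuclei merge into a single label (no watershed)
  img <- matrix(100, 96, 96)
  xg <- matrix(rep(0:95, each = 96), 96, 96)
  yg <- matrix(rep(0:95, 96), 96, 96)
  img[(xg - 40)^2 + (yg - 48)^2 <= 14^2] <- 3000
  img[(xg - 60)^2 + (yg - 48)^2 <= 14^2] <- 3000
  seg2 <- segment_nuclei(image_stack(img, 100), median_radius = 1)
  expect_equal(nrow(seg2$table), 1)
})

test_that("condensate detection counts and areas track ground truth", {
  g <- gen_condensate_timelapse(rate_nucleation = 1.5, growth_rate = 4,
                                timepoints = 6, seed = 21)
  cs <- detect_condensates(g$stack, g$nuclear_roi, threshold = 1000)
  expect_equal(cs$summary$count, g$truth$params$count)
  # per-frame areas agree with rasterized truth (allowing merged overlaps)
  t_last <- 6
  if (cs$summary$count[t_last] > 0) {
    expect_equal(sum(cs$objects$area_px2[cs$objects$timepoint == t_last - 1]),
                 sum(g$truth$params$areas[[t_last]]), tolerance = 0.05)
  }
  # count invariance to whole-pixel translation
  shifted <- g$stack
  shifted$pixels[, , , , 1] <- shifted$pixels[, , c(3:192, 1, 2), , 1]
  roi_shift <- g$nuclear_roi
  roi_shift$y <- roi_shift$y - 2
  cs2 <- detect_condensates(shifted, roi_shift, threshold = 1000)
  expect_equal(cs2$summary$count, cs$summary$count)
  # intensity rescaling above threshold leaves areas unchanged
  scaled <- g$stack
  scaled$pixels <- scaled$pixels * 3
  cs3 <- detect_condensates(scaled, g$nuclear_roi, threshold = 3000)
  expect_equal(cs3$objects$area_px2, cs$objects$area_px2)
  # condensate inside the nuclear ROI is excluded
  st <- g$stack$pixels[1, , , , , drop = FALSE]
  st[1, 1, 93:99, 93:99, 1] <- 60000  # center of the nuclear ellipse
  one <- image_stack(st, pixel_size = 200)
  cs4 <- detect_condensates(one, g$nuclear_roi, threshold = 1000)
  expect_equal(cs4$summary$count[1], g$truth$params$count[1])
  # ROI outside the frame is rejected
  bad_roi <- data.frame(x = c(-5, 10, 10), y = c(0, 0, 10))
  expect_error(detect_condensates(g$stack, bad_roi), "outside")
})

test_that("relative nuclear localization is bounded and monotone", {
  arr <- array(0, c(3, 2, 48, 48, 1))
  arr[, , 10:20, 10:20, 1] <- 500   # nuclear box
  arr[, , 30:40, 30:40, 1] <- 500   # cytosolic box
  st <- image_stack(arr, pixel_size = 100)
  nuc <- data.frame(x = c(9, 20, 20, 9), y = c(9, 9, 20, 20))
  cyt <- data.frame(x = c(29, 40, 40, 29), y = c(29, 29, 40, 40))
  tr <- translocation_trace(st, nuc, cyt, register = FALSE)
  expect_true(all(tr$relative_nuclear_localization >= 0 &
                  tr$relative_nuclear_localization <= 1))
  expect_equal(tr$relative_nuclear_localization, rep(0.5, 3))
  # move intensity from cytosol to nucleus -> ratio strictly increases
  arr2 <- arr
  arr2[2, , 10:20, 10:20, 1] <- 700
  arr2[2, , 30:40, 30:40, 1] <- 300
  arr2[3, , 10:20, 10:20, 1] <- 900
  arr2[3, , 30:40, 30:40, 1] <- 100
  tr2 <- translocation_trace(image_stack(arr2, 100), nuc, cyt,
                             register = FALSE)
  expect_true(all(diff(tr2$relative_nuclear_localization) > 0))
  # all signal nuclear -> 1
  arr3 <- array(0, c(1, 1, 48, 48, 1))
  arr3[1, 1, 10:20, 10:20, 1] <- 800
  tr3 <- translocation_trace(image_stack(arr3, 100), nuc, cyt,
                             register = FALSE)
  expect_equal(tr3$relative_nuclear_localization, 1)
})

test_that("registration undoes an integer-pixel drift", {
  set.seed(3)
  base <- matrix(100, 64, 64)
  base[20:30, 20:30] <- 2000
  arr <- array(0, c(3, 1, 64, 64, 1))
  arr[1, 1, , , 1] <- base
  arr[2, 1, , , 1] <- rbind(base[-(1:3), ], matrix(100, 3, 64))  # drift
  arr[3, 1, , , 1] <- cbind(base[, -(1:2)], matrix(100, 64, 2))
  st <- image_stack(arr, 100)
  nuc <- data.frame(x = c(19, 30, 30, 19), y = c(19, 19, 30, 30))
  cyt <- data.frame(x = c(40, 60, 60, 40), y = c(40, 40, 60, 60))
  reg <- translocation_trace(st, nuc, cyt, register = TRUE)
  unreg <- translocation_trace(st, nuc, cyt, register = FALSE)
  expect_equal(reg$I_nuc, rep(reg$I_nuc[1], 3), tolerance = 0.02)
  expect_gt(abs(unreg$I_nuc[2] - unreg$I_nuc[1]), 100)
})

test_that("rolling-ball cluster detection beats a naive global threshold", {
  ny <- 128; nx <- 128
  xg <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  yg <- matrix(rep(0:(ny - 1), nx), ny, nx)
  dna <- matrix(0, ny, nx)
  dna[(xg - 64)^2 + (yg - 64)^2 <= 52^2] <- 3000
  grad <- 500 + 10 * xg  # strong linear gradient background
  sig <- grad
  spots <- data.frame(x = c(40, 64, 90, 55, 75, 30, 88),
                      y = c(50, 40, 70, 80, 60, 70, 45))
  for (i in seq_len(nrow(spots)))
    sig <- sig + 4000 * exp(-((xg - spots$x[i])^2 +
                              (yg - spots$y[i])^2) / (2 * 2^2))
  st <- image_stack(array(c(round(sig), dna), c(1, 1, ny, nx, 2)),
                    pixel_size = 48)
  cl <- detect_nuclear_clusters(st, 1, 2, resolution_limit = 48,
                                ball_multiple = 8)
  # one detection per true spot: full recall, no false positives
  expect_equal(nrow(cl), nrow(spots))
  expect_true(all(cl$mean_intensity > 500 + 10 * 128 / 2 - 500))
  # naive global Otsu without background subtraction fails on the gradient
  th <- EBImage::otsu(EBImage::Image(sig / max(sig)), range = c(0, 1))
  naive <- matrix(as.integer(EBImage::bwlabel(
    EBImage::Image((sig / max(sig) > th) * 1))), ny, nx)
  expect_false(max(naive) == nrow(spots))
  # spot outside the DNA mask is not reported
  sig2 <- grad
  sig2 <- sig2 + 4000 * exp(-((xg - 5)^2 + (yg - 5)^2) / (2 * 2^2))
  st2 <- image_stack(array(c(round(sig2), dna), c(1, 1, ny, nx, 2)),
                     pixel_size = 48)
  cl2 <- detect_nuclear_clusters(st2, 1, 2, resolution_limit = 48)
  expect_equal(nrow(cl2), 0)
  # resolution limit below pixel size is rejected
  expect_error(detect_nuclear_clusters(st, resolution_limit = 10),
               "below pixel size")
})

test_that("flat nucleus yields no clusters", {
  ny <- 96; nx <- 96
  xg <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  yg <- matrix(rep(0:(ny - 1), nx), ny, nx)
  dna <- matrix(0, ny, nx)
  dna[(xg - 48)^2 + (yg - 48)^2 <= 36^2] <- 3000
  sig <- matrix(800, ny, nx)
  st <- image_stack(array(c(sig, dna), c(1, 1, ny, nx, 2)), pixel_size = 48)
  cl <- detect_nuclear_clusters(st, 1, 2, resolution_limit = 48)
  expect_equal(nrow(cl), 0)
})

test_that("droplet partitioning filters by diameter and measures ratios", {
  ny <- 96; nx <- 96
  xg <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  yg <- matrix(rep(0:(ny - 1), nx), ny, nx)
  # pixel size 30 nm: a single pixel is below the 0.1 um diameter cut
  ch_marker <- matrix(0, ny, nx)
  ch_probe <- matrix(50, ny, nx)
  disk <- (xg - 48)^2 + (yg - 48)^2 <= 12^2
  ch_marker[disk] <- 4000
  ch_probe[disk] <- 50 * 20  # partition ratio 20
  ch_marker[10, 10] <- 4000  # sub-diffraction speck
  st <- image_stack(array(c(ch_probe, ch_marker), c(1, 1, ny, nx, 2)),
                    pixel_size = 30)
  dp <- quantify_droplet_partitioning(st, channel_of_interest = 1)
  expect_equal(nrow(dp$droplets), 1)  # speck filtered out
  expect_equal(dp$droplets$mean_intensity, 1000)
  outside <- mean(ch_probe[!disk])
  expect_equal(dp$droplets$mean_intensity / outside, 20, tolerance = 0.05)
  expect_false(is.null(dp$profile))
  expect_true(all(dp$profile$intensity_norm >= 0 &
                  dp$profile$intensity_norm <= 1))
  # uniform droplet reports its plateau intensity
  expect_equal(dp$droplets$mean_intensity, 1000)
  expect_error(quantify_droplet_partitioning(
    image_stack(matrix(1, 8, 8), 100)), "2 registered channels")
})
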