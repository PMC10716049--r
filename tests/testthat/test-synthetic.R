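test_that("generators are deterministic functions of their seed", {
  a <- gen_nuclei_field(n_nuclei = 2, noise_sd = 30, seed = 42)
  b <- gen_nuclei_field(n_nuclei = 2, noise_sd = 30, seed = 42)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$labels, b$labels)
  c1 <- gen_contact_trajectory(500, 4, seed = 9)
  c2 <- gen_contact_trajectory(500, 4, seed = 9)
  expect_identical(c1$cm$contacts, c2$cm$contacts)
  t1 <- gen_turbidity_curve(noise_sd = 0.05, seed = 3)
  t2 <- gen_turbidity_curve(noise_sd = 0.05, seed = 3)
  expect_identical(t1$curve, t2$curve)
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_frap_trace(seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("nuclei field: spot contrast adds variance, none means constant", {
  flat <- gen_nuclei_field(n_nuclei = 3, cluster_contrast = 0, noise_sd = 0,
                           seed = 5)
  g <- granularity(flat$image, flat$labels)
  expect_equal(g$intensity_sd, rep(0, 3))
  spotted <- gen_nuclei_field(n_nuclei = 3, cluster_contrast = 1,
                              noise_sd = 0, seed = 5)
  gs <- granularity(spotted$image, spotted$labels)
  expect_true(all(gs$intensity_sd > 0))
  expect_true(all(gs$intensity_sd > g$intensity_sd))
})

test_that("nuclei field fails explicitly when placement is impossible", {
  expect_error(gen_nuclei_field(n_nuclei = 50, dim = c(64L, 64L), seed = 1),
               "field too small")
})

test_that("condensate timelapse ground truth matches construction", {
  none <- gen_condensate_timelapse(rate_nucleation = 0, timepoints = 5,
                                   seed = 1)
  expect_equal(none$truth$params$count, rep(0L, 5))
  gr <- gen_condensate_timelapse(rate_nucleation = 2, growth_rate = 3,
                                 timepoints = 8, seed = 4)
  mean_area <- vapply(gr$truth$params$areas, function(a)
    if (length(a)) mean(a) else 0, numeric(1))
  grew <- mean_area[gr$truth$params$count > 0]
  expect_true(all(diff(grew) > -1e-9 | diff(gr$truth$params$count[
    gr$truth$params$count > 0]) > 0))
  # rasterized disk of radius 5 has area ~ pi * 25
  one <- gen_condensate_timelapse(rate_nucleation = 5, growth_rate = 0,
                                  timepoints = 1, r0 = 5, seed = 2)
  k <- one$truth$params$count[1]
  expect_gt(k, 0)
  expect_equal(sum(one$truth$params$areas[[1]]), k * pi * 25,
               tolerance = 0.08)
})

test_that("frap generator hits its closed-form anchor points", {
  g <- gen_frap_trace(mobile_fraction = 0.5, t_half = 2, bleach_depth = 0.9,
                      noise_sd = 0, acq_bleach_rate = 0, seed = 1,
                      signal = 1000, background = 0)
  tr <- g$trace
  post <- tr[tr$t >= 0, ]
  I0 <- 1000 * 0.1
  Finf <- I0 + 0.5 * (1000 - I0)
  expect_equal(post$bleach[1], I0)
  # value at t = t_half is exactly midway between I0 and Finf
  at_half <- post$bleach[which.min(abs(post$t - 2))]
  i <- which.min(abs(post$t - 2))
  expect_equal(post$t[i], 1.98, tolerance = 0.2)  # nearest frame to t_half
  expect_equal(post$bleach[i],
               I0 + (Finf - I0) * (1 - 2^(-post$t[i] / 2)))
  # immobile: flat post-bleach
  g0 <- gen_frap_trace(mobile_fraction = 0, t_half = 2, bleach_depth = 0.7,
                       noise_sd = 0, seed = 1)
  expect_equal(diff(range(g0$trace$bleach[g0$trace$t >= 0])), 0)
})

test_that("turbidity generator: derivative max at the true cloud point", {
  g <- gen_turbidity_curve(true_Tc = 34, width = 1, noise_sd = 0, seed = 1,
                           T_grid = seq(25, 45, by = 0.2))
  d <- diff(g$curve$A340) / diff(g$curve$T)
  Tm <- g$curve$T[which.max(d)]
  expect_lt(abs(Tm - 34), 0.21)
  flat <- gen_turbidity_curve(amplitude = 0, noise_sd = 0, seed = 1)
  expect_equal(diff(range(flat$curve$A340)), 0)
  out <- gen_turbidity_curve(true_Tc = 90, T_grid = seq(25, 45, 0.2),
                             seed = 1)
  expect_false(out$truth$params$tc_in_grid)
})

test_that("contact trajectory chain has the stated stationary behavior", {
  stuck <- gen_contact_trajectory(100, 3, p_stay_bound = 1,
                                  p_stay_unbound = 0, init = "bound",
                                  seed = 1)
  expect_true(all(stuck$states))
  # symmetric chain: fB* = 0.5, empirical fB near it at large n
  g <- gen_contact_trajectory(1e5, 2, 0.5, 0.5, seed = 1)
  expect_equal(g$truth$params$fB_star, 0.5)
  # empirical bound fraction of the latent chain near its stationary value
  expect_lt(abs(mean(g$states) - 0.5), 6 * sqrt(0.25 / 1e5))
  # deterministic residue profile
  p <- gen_contact_trajectory(2000, 3, 0.8, 0.8,
                              residue_profile = c(1, 0, 0.5), seed = 2)
  bound <- p$states
  expect_true(all(p$cm$contacts[bound, 1]))
  expect_false(any(p$cm$contacts[, 2]))
  expect_false(any(p$cm$contacts[!bound, ]))
})

test_that("generated noise magnitude matches the requested noise_sd", {
  g <- gen_turbidity_curve(noise_sd = 0.1, seed = 8,
                           T_grid = seq(0, 1000, length.out = 2e4))
  resid <- g$curve$A340 - (0.05 + 1 * plogis((g$curve$T - 34) / 1))
  expect_equal(sd(resid), 0.1, tolerance = 0.1)
})

test_that("coordinate-frame fixture writes readable topology and frames", {
  prot <- data.frame(resid = c(1, 1, 2), element = c("C", "N", "C"),
                     x = c(0, 1, 8), y = 0, z = 0)
  lig <- data.frame(element = c("C", "O"), x = c(0, 1), y = 0, z = 0)
  g <- gen_coordinate_frames(4, prot, lig, bound_offset = c(0, 5, 0),
                             unbound_offset = c(0, 50, 0),
                             dir = withr::local_tempdir(), seed = 1)
  expect_true(file.exists(g$topology))
  top <- read_topology(g$topology)
  expect_equal(nrow(top), 5)
  expect_equal(sum(top$resname == "LIG"), 2)
  cm <- contact_matrix(g$topology, g$frames, "LIG")
  expect_equal(dim(cm$contacts), c(4L, 2L))
  # bound frames contact residue 1 (5 A), unbound frames contact nothing
  expect_equal(unname(cm$contacts[, 1]), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(
    gen_coordinate_frames(2, transform(prot, element = "Xx"), lig,
                          dir = withr::local_tempdir(), seed = 1),
    "unknown element")
})

test_that("dose-response generator: dose at e gives d/2 before noise", {
  g <- gen_dose_response(true_IC50 = 2, hill_b = 1.5, upper_d = 80,
                         doses = c(0.5, 1, 2, 4, 8, 16), replicates = 1,
                         noise_sd = 0, seed = 1)
  at_e <- g$data$response[g$data$dose == 2]
  expect_equal(at_e, 40)
  # steep slope approaches a step function
  steep <- gen_dose_response(true_IC50 = 2, hill_b = 50, upper_d = 80,
                             doses = c(0.5, 1, 1.9, 2.1, 4, 8),
                             replicates = 1, noise_sd = 0, seed = 1)
  expect_equal(steep$data$response[steep$data$dose < 1.9 + 1e-9][1:2],
               c(80, 80), tolerance = 1e-3)
  expect_lt(steep$data$response[steep$data$dose == 8], 1e-10)
})
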