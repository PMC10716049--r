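test_that("contact matrix equals the brute-force distance loop", {
  for (s in 1:20) {
    box <- if (s %% 3 == 0) rep(18, 3) else NULL
    sys <- random_toy_system(seed = s, n_frames = 5, box = box)
    cm <- contact_matrix(sys$top, sys$coords, ligand = "LIG", cutoff = 6,
                         box = box)
    oracle <- oracle_contacts(sys$top, sys$coords, "LIG", 6, box = box)
    expect_identical(unname(cm$contacts), oracle)
  }
})

test_that("contact cutoff is inclusive and hydrogens are excluded", {
  prot <- data.frame(resno = 1, resname = "ALA", name = "CA",
                     element = "C", stringsAsFactors = FALSE)
  lig <- data.frame(resno = 2, resname = "LIG", name = "C1", element = "C",
                    stringsAsFactors = FALSE)
  top <- rbind(prot, lig)
  place <- function(d) array(c(0, d, 0, 0, 0, 0), c(1, 2, 3))
  expect_true(contact_matrix(top, place(5.99), "LIG")$contacts[1, 1])
  expect_true(contact_matrix(top, place(6.00), "LIG")$contacts[1, 1])
  expect_false(contact_matrix(top, place(6.01), "LIG")$contacts[1, 1])
  # ligand hydrogen at 1 A does not count; nearest heavy atom is far
  top_h <- rbind(prot,
                 data.frame(resno = 2, resname = "LIG", name = "H1",
                            element = "H"),
                 data.frame(resno = 2, resname = "LIG", name = "C1",
                            element = "C"))
  coords <- array(c(0, 1, 20, rep(0, 6)), c(1, 3, 3))
  expect_false(contact_matrix(top_h, coords, "LIG")$contacts[1, 1])
  # hydrogen-only ligand selection is an error
  top_only_h <- rbind(prot, data.frame(resno = 2, resname = "LIG",
                                       name = "H1", element = "H"))
  expect_error(contact_matrix(top_only_h, array(0, c(1, 2, 3)), "LIG"),
               "empty ligand selection")
  # atom-count mismatch is an error
  expect_error(contact_matrix(top, array(0, c(1, 3, 3)), "LIG"),
               "mismatch")
})

test_that("minimum-image convention wraps distances across the box", {
  prot <- data.frame(resno = 1, resname = "ALA", name = "CA", element = "C")
  lig <- data.frame(resno = 2, resname = "LIG", name = "C1", element = "C")
  top <- rbind(prot, lig)
  # 1 A and 19 A apart across a 20 A box are the same separation
  coords <- array(c(0.5, 19.5, 0, 0, 0, 0), c(1, 2, 3))
  expect_true(contact_matrix(top, coords, "LIG", box = rep(20, 3))$
                contacts[1, 1])
  expect_false(contact_matrix(top, coords, "LIG")$contacts[1, 1])
})

test_that("blocking analysis matches i.i.d. and duplicated-series limits", {
  set.seed(11)
  x <- rbinom(1e4, 1, 0.3)
  b <- blocking_se(x)
  expect_equal(b$se, sqrt(0.3 * 0.7 / 1e4), tolerance = 0.2)
  # duplicating every value halves the effective sample size
  y <- rep(x[1:5000], each = 2)
  bdup <- blocking_se(y)
  iid_dedup <- sd(x[1:5000]) / sqrt(5000)
  expect_equal(bdup$se, sqrt(2) * sd(y) / sqrt(length(y)), tolerance = 0.15)
  expect_equal(bdup$se, iid_dedup, tolerance = 0.15)
  # constant series: zero error at every level
  bc <- blocking_se(rep(2.5, 64))
  expect_equal(bc$se, 0)
  expect_true(all(bc$curve$se == 0))
  expect_error(blocking_se(1:10), "at least 16")
})

test_that("blocking plateau tracks the autocorrelation-corrected s.e.", {
  # two-state chains with known integrated autocorrelation time
  for (p_stay in c(0.8, 0.95)) {
    g <- gen_contact_trajectory(1e5, 1, p_stay, p_stay,
                                residue_profile = 1, seed = 31)
    x <- as.numeric(g$states)
    tau <- g$truth$params$tau_int
    p <- mean(x)
    se_true <- sqrt(p * (1 - p) * (1 + 2 * tau) / length(x))
    expect_equal(blocking_se(x)$se, se_true, tolerance = 0.15)
  }
})

test_that("contact summary: probabilities, bound fraction and ordering", {
  cm0 <- contact_matrix_obj(matrix(FALSE, 32, 3), 1:3)
  s0 <- contact_summary(cm0)
  expect_equal(s0$fB, 0)
  expect_equal(s0$per_residue$p, rep(0, 3))
  # fB >= p_i always (a bound frame is any frame with >= 1 contact)
  g <- gen_contact_trajectory(2000, 6, 0.85, 0.85, seed = 13)
  s <- contact_summary(g$cm)
  expect_true(all(s$fB >= s$per_residue$p - 1e-12))
  # single residue always in contact when bound: p = fB
  g1 <- gen_contact_trajectory(5000, 1, 0.9, 0.9, residue_profile = 1,
                               seed = 3)
  s1 <- contact_summary(g1$cm)
  expect_equal(s1$per_residue$p, s1$fB)
  # stationary recovery within 3 blocking s.e. at n = 1e5
  gs <- gen_contact_trajectory(1e5, 3, 0.9, 0.9, seed = 1)
  ss <- contact_summary(gs$cm)
  expect_lt(abs(ss$fB - gs$truth$params$fB_star), 3 * ss$fB_se)
  expect_error(contact_summary(contact_matrix_obj(matrix(TRUE, 8, 1), 1)),
               "16 frames")
})

test_that("simulated K_D reproduces the closed-box closed forms", {
  kd <- simulated_kd(0.5, box_length = 7.5)
  expect_equal(1e3 * kd$C0, 3.936, tolerance = 1e-3)
  expect_equal(1e3 * kd$Kd, 1.968, tolerance = 1e-3)
  expect_equal(kd$Kd, kd$C0 * (1 - 0.5)^2 / 0.5)
  # strictly decreasing in fB; limits
  fbs <- seq(0.05, 0.95, by = 0.05)
  kds <- vapply(fbs, function(f) simulated_kd(f)$Kd, numeric(1))
  expect_true(all(diff(kds) < 0))
  expect_lt(simulated_kd(0.999)$Kd, simulated_kd(0.9)$Kd)
  expect_error(simulated_kd(0), "strictly between")
  expect_error(simulated_kd(1), "strictly between")
  # dimensional check: Kd * NA * L^3 is the unitless (1-fB)^2/fB
  f <- 0.3
  kd3 <- simulated_kd(f, box_length = 10)
  expect_equal(kd3$Kd * 6.02214076e23 * (10 * 1e-8)^3, (1 - f)^2 / f)
  # delta-method s.e.
  kse <- simulated_kd(0.5, se = 0.01, box_length = 7.5)
  expect_equal(kse$Kd_se, kse$C0 * (1 - 0.5) * (1 + 0.5) / 0.25 * 0.01)
})

test_that("pdb + frames-table pathway matches the in-memory pathway", {
  prot <- data.frame(resid = c(1, 1, 2, 2), element = c("C", "N", "C", "O"),
                     x = c(0, 1.2, 6, 7), y = 0, z = 0)
  lig <- data.frame(element = c("C", "Cl"), x = c(0, 1.5), y = 0, z = 0)
  g <- gen_coordinate_frames(8, prot, lig, bound_offset = c(0, 4, 0),
                             unbound_offset = c(0, 40, 0),
                             dir = withr::local_tempdir(), seed = 1)
  cm_file <- suppressWarnings(contact_matrix(g$topology, g$frames, "LIG"))
  expect_equal(unname(cm_file$contacts[, 1]),
               g$truth$params$bound_frames)
  expect_false(any(cm_file$contacts[!g$truth$params$bound_frames, ]))
})
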