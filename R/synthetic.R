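#' Synthetic field of fluorescent nuclei with intensity clustering
#'
#' Renders non-overlapping elliptical nuclei of uniform body intensity, each
#' carrying a controllable number of Gaussian bright spots ("clusters") that
#' raise the within-nucleus intensity standard deviation (the granularity
#' statistic), plus additive Gaussian noise. The point-spread function is
#' applied to the spot layer (spot width and PSF width add in quadrature);
#' the nucleus body stays uniform so that with `cluster_contrast = 0` and
#' `noise_sd = 0` the within-mask s.d. is exactly zero.
#'
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param mean_intensity body intensity of each nucleus, AU.
#' @param cluster_count Gaussian spots per nucleus.
#' @param cluster_contrast spot peak amplitude as a multiple of
#'   `mean_intensity` (>= 0).
#' @param psf_sigma point-spread-function s.d. in pixels.
#' @param noise_sd additive Gaussian noise s.d., AU.
#' @param pixel_size pixel size in nm.
#' @param dim image dimension `c(ny, nx)`.
#' @param radius_range range of nucleus semi-axes in pixels.
#' @param spot_sigma intrinsic spot s.d. in pixels before PSF blurring.
#' @param background camera offset, AU.
#' @param seed integer seed.
#' @return list with elements `image` ([image_stack]), `labels`
#'   (ground-truth integer label mask), `spots` (data frame of spot centers)
#'   and `truth` ([ground_truth] including the expected within-mask s.d. per
#'   nucleus).
#' @export
gen_nuclei_field <- function(n_nuclei = 5, mean_intensity = 2000,
                             cluster_count = 10, cluster_contrast = 1,
                             psf_sigma = 1, noise_sd = 50,
                             pixel_size = 100, dim = c(256L, 256L),
                             radius_range = c(16, 24), spot_sigma = 2,
                             background = 100, seed = 1) {
  stopifnot(n_nuclei >= 0, cluster_contrast >= 0, noise_sd >= 0)
  ny <- dim[1L]; nx <- dim[2L]
  with_seed(seed, {
    labels <- matrix(0L, ny, nx)
    noiseless <- matrix(background, ny, nx)
    spots <- data.frame(nucleus = integer(), x = numeric(), y = numeric())
    centers <- matrix(numeric(0), 0, 2)
    axes <- matrix(numeric(0), 0, 2)
    rmax <- max(radius_range)
    if (n_nuclei > 0) {
      tries <- 0L
      while (nrow(centers) < n_nuclei) {
        tries <- tries + 1L
        if (tries > 5000L)
          stop("field too small to place ", n_nuclei,
               " non-overlapping nuclei", call. = FALSE)
        a <- stats::runif(1, radius_range[1], radius_range[2])
        b <- stats::runif(1, radius_range[1], radius_range[2])
        cx <- stats::runif(1, rmax + 2, nx - rmax - 3)
        cy <- stats::runif(1, rmax + 2, ny - rmax - 3)
        if (nrow(centers) > 0) {
          dists <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
          if (any(dists < max(a, b) + apply(axes, 1, max) + 3)) next
        }
        centers <- rbind(centers, c(cx, cy))
        axes <- rbind(axes, c(a, b))
      }
      xg <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)
      yg <- matrix(rep(seq_len(ny) - 1, times = nx), ny, nx)
      sig_eff <- sqrt(spot_sigma^2 + psf_sigma^2)
      for (i in seq_len(n_nuclei)) {
        inside <- ((xg - centers[i, 1]) / axes[i, 1])^2 +
          ((yg - centers[i, 2]) / axes[i, 2])^2 <= 1
        labels[inside] <- i
        noiseless[inside] <- noiseless[inside] + mean_intensity
        if (cluster_count > 0 && cluster_contrast > 0) {
          placed <- 0L
          while (placed < cluster_count) {
            sx <- stats::runif(1, centers[i, 1] - axes[i, 1],
                               centers[i, 1] + axes[i, 1])
            sy <- stats::runif(1, centers[i, 2] - axes[i, 2],
                               centers[i, 2] + axes[i, 2])
            if (((sx - centers[i, 1]) / (axes[i, 1] * 0.8))^2 +
                ((sy - centers[i, 2]) / (axes[i, 2] * 0.8))^2 > 1) next
            placed <- placed + 1L
            spots <- rbind(spots, data.frame(nucleus = i, x = sx, y = sy))
            amp <- cluster_contrast * mean_intensity
            noiseless <- noiseless + amp *
              exp(-((xg - sx)^2 + (yg - sy)^2) / (2 * sig_eff^2))
          }
        }
      }
    }
    sd_expected <- vapply(seq_len(max(0L, n_nuclei)), function(i) {
      v <- noiseless[labels == i]
      sqrt(pop_sd(v)^2 + noise_sd^2)
    }, numeric(1))
    img <- noiseless
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
    img <- round(pmin(pmax(img, 0), 65535))
    list(
      image = image_stack(img, pixel_size = pixel_size, bit_depth = 16L),
      labels = labels,
      spots = spots,
      truth = ground_truth(list(
        n_nuclei = n_nuclei, mean_intensity = mean_intensity,
        cluster_count = cluster_count, cluster_contrast = cluster_contrast,
        noise_sd = noise_sd, background = background,
        sd_expected = sd_expected, centers = centers, axes = axes), seed)
    )
  })
}

#' Synthetic time-lapse of cytosolic condensates nucleating and growing
#'
#' Emulates a cell whose cytosol accumulates bright circular condensates:
#' new condensates appear at a Poisson rate and each grows linearly in area.
#' A central elliptical nuclear region stays condensate-free. The per-frame
#' true counts and rasterized areas are recorded in the ground truth.
#'
#' @param rate_nucleation expected new condensates per minute.
#' @param growth_rate area growth per condensate, px^2 per minute.
#' @param timepoints number of frames (>= 1).
#' @param dt_min frame interval in minutes.
#' @param dim image dimension `c(ny, nx)`.
#' @param r0 initial condensate radius, px.
#' @param intensity condensate intensity above background, AU.
#' @param background background intensity, AU.
#' @param noise_sd additive Gaussian noise s.d., AU.
#' @param pixel_size pixel size in nm.
#' @param seed integer seed.
#' @return list with `stack` ([image_stack] with `timepoints` frames),
#'   `nuclear_roi` (polygon data frame), and `truth` (per-frame counts and
#'   rasterized areas).
#' @export
gen_condensate_timelapse <- function(rate_nucleation = 1, growth_rate = 2,
                                     timepoints = 10, dt_min = 1,
                                     dim = c(192L, 192L), r0 = 2,
                                     intensity = 5000, background = 100,
                                     noise_sd = 0, pixel_size = 200,
                                     seed = 1) {
  stopifnot(timepoints >= 1, rate_nucleation >= 0, growth_rate >= 0)
  ny <- dim[1L]; nx <- dim[2L]
  # central elliptical nucleus, kept condensate-free
  ncx <- (nx - 1) / 2; ncy <- (ny - 1) / 2
  na <- nx / 6; nb <- ny / 6
  theta <- seq(0, 2 * pi, length.out = 33L)[-33L]
  nuclear_roi <- data.frame(x = ncx + na * cos(theta),
                            y = ncy + nb * sin(theta))
  with_seed(seed, {
    xg <- matrix(rep(seq_len(nx) - 1, each = ny), ny, nx)
    yg <- matrix(rep(seq_len(ny) - 1, times = nx), ny, nx)
    in_nucleus <- ((xg - ncx) / na)^2 + ((yg - ncy) / nb)^2 <= 1
    births <- data.frame(x = numeric(), y = numeric(), t = numeric())
    pixels <- array(0, c(timepoints, 1L, ny, nx, 1L))
    counts <- integer(timepoints)
    areas <- vector("list", timepoints)
    margin <- 6
    for (ti in seq_len(timepoints)) {
      n_new <- stats::rpois(1, rate_nucleation * dt_min)
      k <- 0L
      while (k < n_new) {
        bx <- stats::runif(1, margin, nx - 1 - margin)
        by <- stats::runif(1, margin, ny - 1 - margin)
        if (((bx - ncx) / (na + r0 + 2))^2 +
            ((by - ncy) / (nb + r0 + 2))^2 <= 1) next
        k <- k + 1L
        births <- rbind(births, data.frame(x = bx, y = by,
                                           t = (ti - 1) * dt_min))
      }
      frame <- matrix(background, ny, nx)
      a_list <- numeric(0)
      if (nrow(births) > 0) {
        for (bi in seq_len(nrow(births))) {
          age <- (ti - 1) * dt_min - births$t[bi]
          area_t <- pi * r0^2 + growth_rate * age
          rad <- sqrt(area_t / pi)
          disk <- (xg - births$x[bi])^2 + (yg - births$y[bi])^2 <= rad^2
          a_list <- c(a_list, sum(disk))
          frame[disk] <- background + intensity
        }
      }
      counts[ti] <- nrow(births)
      areas[[ti]] <- a_list
      if (noise_sd > 0)
        frame <- frame + matrix(stats::rnorm(ny * nx, 0, noise_sd), ny, nx)
      pixels[ti, 1, , , 1] <- round(pmin(pmax(frame, 0), 65535))
    }
    list(
      stack = image_stack(pixels, pixel_size = pixel_size, bit_depth = 16L),
      nuclear_roi = nuclear_roi,
      truth = ground_truth(list(
        rate_nucleation = rate_nucleation, growth_rate = growth_rate,
        timepoints = timepoints, count = counts, areas = areas,
        births = births, intensity = intensity,
        background = background), seed)
    )
  })
}

#' Synthetic FRAP trace triple with acquisition bleaching
#'
#' Generates the three regions of interest a FRAP experiment records --
#' bleach ROI, whole cell, and background -- following a single-exponential
#' recovery \eqn{I(t) = I_0 + (F_\infty - I_0)(1 - e^{-kt})} with
#' \eqn{k = \ln 2 / t_{1/2}}, multiplied by whole-cell acquisition bleaching
#' \eqn{e^{-\lambda t}} applied to both cellular ROIs, plus a constant
#' background. Defaults mirror a typical live-cell protocol: 20 pre-bleach
#' and 200 post-bleach frames at 180 ms intervals.
#'
#' @param mobile_fraction fraction of bleached signal that recovers, 0-1.
#' @param t_half recovery half-time, s (> 0).
#' @param bleach_depth fraction of signal removed by the bleach pulse, 0-1.
#' @param acq_bleach_rate acquisition photobleaching rate, s^-1.
#' @param noise_sd additive Gaussian noise s.d. (AU).
#' @param n_pre,n_post number of pre- and post-bleach frames.
#' @param dt frame interval, s.
#' @param signal pre-bleach ROI intensity, AU.
#' @param background constant background intensity, AU.
#' @param seed integer seed.
#' @return list with `trace` (a [frap_trace]) and `truth`.
#' @export
gen_frap_trace <- function(mobile_fraction = 0.94, t_half = 2.29,
                           bleach_depth = 0.9, acq_bleach_rate = 0,
                           noise_sd = 0, n_pre = 20L, n_post = 200L,
                           dt = 0.18, signal = 1000, background = 100,
                           seed = 1) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, t_half > 0,
            bleach_depth >= 0, bleach_depth <= 1, n_pre >= 2, n_post >= 1)
  k <- log(2) / t_half
  t_pre <- -rev(seq_len(n_pre)) * dt
  t_post <- (seq_len(n_post) - 1) * dt
  t <- c(t_pre, t_post)
  I0 <- signal * (1 - bleach_depth)
  Finf <- I0 + mobile_fraction * (signal - I0)
  bleach <- c(rep(signal, n_pre), I0 + (Finf - I0) * (1 - exp(-k * t_post)))
  whole <- rep(signal, n_pre + n_post)
  # acquisition bleaching attenuates the fluorescent signal in every
  # acquired frame; the background offset does not bleach, so the measured
  # cellular ROIs are background + attenuated signal
  acq <- exp(-acq_bleach_rate * (t - t[1L]))
  bleach <- background + bleach * acq
  whole <- background + whole * acq
  bg <- rep(background, n_pre + n_post)
  with_seed(seed, {
    if (noise_sd > 0) {
      bleach <- bleach + stats::rnorm(length(t), 0, noise_sd)
      whole <- whole + stats::rnorm(length(t), 0, noise_sd)
      bg <- bg + stats::rnorm(length(t), 0, noise_sd)
    }
    list(
      trace = frap_trace(t = t, bleach = bleach, whole = whole,
                         background = bg),
      truth = ground_truth(list(
        mobile_fraction = mobile_fraction, t_half = t_half, k = k,
        bleach_depth = bleach_depth, acq_bleach_rate = acq_bleach_rate,
        noise_sd = noise_sd, signal = signal, background = background,
        dt = dt), seed)
    )
  })
}

#' Synthetic turbidity (A340 vs temperature) curve
#'
#' Sigmoidal absorbance ramp
#' \eqn{y(T) = baseline + amplitude \cdot logistic((T - T_c)/width)} plus
#' additive noise; the midpoint, inflection and first-derivative maximum all
#' coincide at the true cloud point.
#'
#' @param true_Tc cloud-point temperature, deg C.
#' @param width transition width, deg C.
#' @param baseline pre-transition absorbance (A340).
#' @param amplitude transition amplitude (A340).
#' @param T_grid strictly increasing temperature grid, deg C.
#' @param noise_sd additive noise s.d. (A340).
#' @param seed integer seed.
#' @return list with `curve` (data frame `T`, `A340`) and `truth`
#'   (including `tc_in_grid`, FALSE when the cloud point lies outside the
#'   sampled ramp and only a monotone tail is visible).
#' @export
gen_turbidity_curve <- function(true_Tc = 34, width = 1, baseline = 0.05,
                                amplitude = 1,
                                T_grid = seq(25, 45, by = 0.2),
                                noise_sd = 0, seed = 1) {
  if (any(diff(T_grid) <= 0)) stop("'T_grid' must be strictly increasing")
  y0 <- baseline + amplitude * stats::plogis((T_grid - true_Tc) / width)
  with_seed(seed, {
    y <- y0
    if (noise_sd > 0) y <- y + stats::rnorm(length(T_grid), 0, noise_sd)
    list(
      curve = data.frame(T = T_grid, A340 = y),
      truth = ground_truth(list(
        true_Tc = true_Tc, width = width, baseline = baseline,
        amplitude = amplitude, noise_sd = noise_sd,
        tc_in_grid = true_Tc >= min(T_grid) && true_Tc <= max(T_grid)), seed)
    )
  })
}

#' Synthetic two-state ligand-binding contact trajectory
#'
#' Simulates a latent bound/unbound Markov chain (transition retention
#' probabilities `p_stay_bound`, `p_stay_unbound`); in bound frames each
#' residue registers a contact independently with its profile probability,
#' in unbound frames no residue does. The stationary bound fraction
#' \eqn{f_B^* = (1 - p_{uu}) / ((1 - p_{bb}) + (1 - p_{uu}))} and the
#' chain's integrated autocorrelation time are stored in the ground truth.
#'
#' @param n_frames number of frames.
#' @param n_residues number of protein residues.
#' @param p_stay_bound,p_stay_unbound state retention probabilities, 0-1.
#' @param residue_profile per-residue contact probability given bound. The
#'   default anchors residue 1 at probability 1 (a bound pose always touches
#'   its primary binding residue) with 0.5 elsewhere, so every bound frame
#'   registers at least one contact and the observable bound fraction equals
#'   the chain's stationary value.
#' @param residue_ids residue identifiers (defaults to `1:n_residues`).
#' @param stride_ps frame stride in picoseconds (metadata).
#' @param init optional initial state, `"bound"` or `"unbound"`; by default
#'   drawn from the stationary distribution.
#' @param seed integer seed.
#' @return list with `cm` (a [contact_matrix_obj]), `states` (logical
#'   bound indicator per frame) and `truth` (including `fB_star` and
#'   `tau_int`, the integrated autocorrelation time in frames).
#' @export
gen_contact_trajectory <- function(n_frames, n_residues = 10,
                                   p_stay_bound = 0.9,
                                   p_stay_unbound = 0.9,
                                   residue_profile = NULL,
                                   residue_ids = NULL,
                                   stride_ps = 100, init = NULL, seed = 1) {
  stopifnot(p_stay_bound >= 0, p_stay_bound <= 1,
            p_stay_unbound >= 0, p_stay_unbound <= 1, n_frames >= 1)
  if (is.null(residue_profile))
    residue_profile <- c(1, rep(0.5, n_residues - 1L))
  stopifnot(length(residue_profile) == n_residues,
            all(residue_profile >= 0 & residue_profile <= 1))
  if (is.null(residue_ids)) residue_ids <- seq_len(n_residues)
  denom <- (1 - p_stay_bound) + (1 - p_stay_unbound)
  fB_star <- if (denom > 0) (1 - p_stay_unbound) / denom else NA_real_
  lambda <- p_stay_bound + p_stay_unbound - 1
  tau_int <- if (abs(lambda) < 1) lambda / (1 - lambda) else Inf
  with_seed(seed, {
    states <- logical(n_frames)
    states[1L] <- if (!is.null(init)) identical(init, "bound")
      else stats::runif(1) < (if (is.na(fB_star)) 0.5 else fB_star)
    u <- stats::runif(n_frames)
    for (i in seq_len(n_frames - 1L)) {
      states[i + 1L] <- if (states[i]) u[i] < p_stay_bound
        else u[i] >= p_stay_unbound
    }
    contacts <- matrix(FALSE, n_frames, n_residues)
    nb <- sum(states)
    if (nb > 0) {
      contacts[states, ] <- matrix(
        stats::runif(nb * n_residues) <
          rep(residue_profile, each = nb), nb, n_residues)
    }
    list(
      cm = contact_matrix_obj(contacts, residue_ids = residue_ids,
                              cutoff = 6.0, stride_ps = stride_ps),
      states = states,
      truth = ground_truth(list(
        fB_star = fB_star,
        # bound fraction observable from contacts: a bound frame can emit
        # zero contacts with probability prod(1 - p_i)
        fB_obs_star = fB_star * (1 - prod(1 - residue_profile)),
        tau_int = tau_int,
        p_stay_bound = p_stay_bound, p_stay_unbound = p_stay_unbound,
        residue_profile = residue_profile), seed)
    )
  })
}

.elements_known <- c("H", "D", "C", "N", "O", "S", "P", "F", "CL", "BR", "I",
                     "NA", "K", "MG", "CA", "ZN", "FE")

#' Write a geometry-path trajectory fixture (PDB topology + frames table)
#'
#' Builds a toy protein/ligand system and writes a PDB topology plus a
#' plain-text coordinate table (`frame,atom,x,y,z`, in Angstroms) in which
#' the ligand alternates between a bound pose (translated by
#' `bound_offset` relative to its reference coordinates) and an unbound pose
#' (`unbound_offset`), according to `bound_frames`.
#'
#' @param n_frames number of frames to write.
#' @param protein_atoms data frame with columns `resid`, `element`, `x`,
#'   `y`, `z` and optionally `name` (atom name).
#' @param ligand_atoms data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `name`; written with residue name `LIG`.
#' @param bound_offset,unbound_offset length-3 xyz translations (Angstrom)
#'   applied to the ligand in bound / unbound frames.
#' @param bound_frames logical vector of length `n_frames`; by default
#'   frames alternate bound / unbound.
#' @param dir output directory (created if needed).
#' @param seed integer seed (recorded; the geometry itself is deterministic).
#' @return list with `topology` and `frames` file paths and `truth`.
#' @export
gen_coordinate_frames <- function(n_frames, protein_atoms, ligand_atoms,
                                  bound_offset = c(0, 0, 0),
                                  unbound_offset = c(50, 0, 0),
                                  bound_frames = NULL,
                                  dir = tempfile("traj"), seed = 1) {
  stopifnot(n_frames >= 1)
  protein_atoms <- as.data.frame(protein_atoms)
  ligand_atoms <- as.data.frame(ligand_atoms)
  els <- toupper(c(protein_atoms$element, ligand_atoms$element))
  bad <- setdiff(unique(els), .elements_known)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (is.null(bound_frames))
    bound_frames <- rep_len(c(TRUE, FALSE), n_frames)
  stopifnot(length(bound_frames) == n_frames)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  np <- nrow(protein_atoms); nl <- nrow(ligand_atoms)
  if (is.null(protein_atoms$name))
    protein_atoms$name <- paste0(toupper(protein_atoms$element),
                                 seq_len(np))
  if (is.null(ligand_atoms$name))
    ligand_atoms$name <- paste0(toupper(ligand_atoms$element), seq_len(nl))
  top_path <- file.path(dir, "topology.pdb")
  lines <- character(np + nl + 1L)
  fmt <- function(rec, serial, name, resname, resid, x, y, z, el) {
    sprintf("%-6s%5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            rec, serial, substr(name, 1, 4), resname, resid, x, y, z,
            toupper(el))
  }
  for (i in seq_len(np))
    lines[i] <- fmt("ATOM", i, protein_atoms$name[i], "ALA",
                    protein_atoms$resid[i], protein_atoms$x[i],
                    protein_atoms$y[i], protein_atoms$z[i],
                    protein_atoms$element[i])
  lig_resid <- max(protein_atoms$resid) + 1L
  for (j in seq_len(nl))
    lines[np + j] <- fmt("HETATM", np + j, ligand_atoms$name[j], "LIG",
                         lig_resid, ligand_atoms$x[j], ligand_atoms$y[j],
                         ligand_atoms$z[j], ligand_atoms$element[j])
  lines[np + nl + 1L] <- "END"
  writeLines(lines, top_path)
  frames_path <- file.path(dir, "frames.txt")
  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    off <- if (bound_frames[f]) bound_offset else unbound_offset
    coords <- rbind(
      cbind(protein_atoms$x, protein_atoms$y, protein_atoms$z),
      cbind(ligand_atoms$x + off[1], ligand_atoms$y + off[2],
            ligand_atoms$z + off[3]))
    rows[[f]] <- data.frame(frame = f, atom = seq_len(np + nl),
                            x = coords[, 1], y = coords[, 2],
                            z = coords[, 3])
  }
  utils::write.csv(do.call(rbind, rows), frames_path, row.names = FALSE)
  list(topology = top_path, frames = frames_path,
       truth = ground_truth(list(bound_frames = bound_frames,
                                 n_frames = n_frames), seed))
}

#' Synthetic dose-response data from a three-parameter log-logistic model
#'
#' Responses follow \eqn{f(x) = d / (1 + \exp(b(\ln x - \ln e)))} (lower
#' limit 0) with additive Gaussian noise; `e` is the true IC50.
#'
#' @param true_IC50 inflection dose `e` (same units as `doses`).
#' @param hill_b slope parameter `b` (> 0 for inhibition curves).
#' @param upper_d upper asymptote `d`.
#' @param doses vector of positive doses.
#' @param replicates replicate measurements per dose.
#' @param noise_sd additive noise s.d. (response units).
#' @param n_zero number of zero-dose control wells (responses at `d`).
#' @param seed integer seed.
#' @return list with `data` (data frame `dose`, `response`, `replicate`)
#'   and `truth`.
#' @export
gen_dose_response <- function(true_IC50 = 1.5, hill_b = 1, upper_d = 100,
                              doses = c(0.1, 0.3, 1, 3, 10, 30),
                              replicates = 3, noise_sd = 0, n_zero = 0,
                              seed = 1) {
  stopifnot(all(doses > 0), true_IC50 > 0, upper_d > 0)
  x <- rep(doses, each = replicates)
  mu <- upper_d / (1 + exp(hill_b * (log(x) - log(true_IC50))))
  if (n_zero > 0) {
    x <- c(rep(0, n_zero), x)
    mu <- c(rep(upper_d, n_zero), mu)
  }
  with_seed(seed, {
    y <- mu
    if (noise_sd > 0) y <- y + stats::rnorm(length(mu), 0, noise_sd)
    list(
      data = data.frame(dose = x, response = y,
                        replicate = rep_len(seq_len(replicates), length(x))),
      truth = ground_truth(list(b = hill_b, d = upper_d, e = true_IC50,
                                noise_sd = noise_sd), seed)
    )
  })
}
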