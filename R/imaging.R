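# integer-shift a matrix, padding with `fill`
shift_matrix <- function(m, dy, dx, fill) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- max(1, 1 - dy):min(ny, ny - dy)
  xs <- max(1, 1 - dx):min(nx, nx - dx)
  if (length(ys) && length(xs))
    out[ys + dy, xs + dx] <- m[ys, xs]
  out
}

# first frame of whatever image argument was passed
first_frame <- function(image, channel = 1L) {
  if (inherits(image, "image_stack")) stack_frame(image, channel = channel)
  else as.matrix(image)
}

#' Segment nuclei in a fluorescence image
#'
#' Median filtering, background subtraction and automatic thresholding
#' (Otsu or local adaptive), followed by connected-component labelling.
#' Dark interior holes (nucleoli) are kept excluded from the masks unless
#' their intensity reaches `hole_fill_frac` of the parent nucleus mean;
#' brighter holes are treated as threshold artefacts and filled. Touching
#' nuclei are not split (no watershed); over-merged objects can be removed
#' with the `max_area` ceiling. Labels are assigned in raster order of the
#' object centroid (top-to-bottom, then left-to-right) for determinism.
#'
#' @param image an [image_stack] or numeric matrix (single channel).
#' @param median_radius median filter radius in px (0 disables).
#' @param bg_radius Gaussian background estimation sigma in px.
#' @param method `"otsu"` (global) or `"local"` (adaptive mean).
#' @param min_area,max_area object area bounds in px^2.
#' @param hole_fill_frac holes with mean intensity at or above this
#'   fraction of the parent nucleus mean are filled; darker holes
#'   (nucleoli) stay excluded.
#' @param bit_depth used to scale intensities when `image` is a matrix.
#' @return an object of class `labeled_regions`: integer label matrix
#'   (`$labels`, background 0), a per-object table (`$table`) and
#'   `$flags` (e.g. `"saturated"`).
#' @export
segment_nuclei <- function(image, median_radius = 2, bg_radius = 48,
                           method = c("otsu", "local"), min_area = 64,
                           max_area = Inf, hole_fill_frac = 0.5,
                           bit_depth = 16L) {
  method <- match.arg(method)
  if (inherits(image, "image_stack")) bit_depth <- image$bit_depth
  img <- first_frame(image)
  maxval <- 2^bit_depth - 1
  flags <- character(0)
  if (any(img >= maxval)) {
    warning("saturated pixels present")
    flags <- c(flags, "saturated")
  }
  x <- img / maxval
  if (max(x) == min(x)) {
    return(structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                          table = data.frame(label = integer(),
                                             area_px = integer(),
                                             centroid_x = numeric(),
                                             centroid_y = numeric()),
                          flags = flags), class = "labeled_regions"))
  }
  if (median_radius > 0)
    x <- EBImage::medianFilter(x, as.integer(median_radius))
  # Gaussian kernel must fit inside the image
  sigma <- min(bg_radius, floor((min(dim(x)) - 1) / 6) - 1)
  bg <- EBImage::gblur(x, sigma = sigma)
  sub <- pmax(x - bg, 0)
  mask <- if (method == "otsu") {
    th <- EBImage::otsu(EBImage::Image(sub), range = c(0, 1))
    sub > th
  } else {
    EBImage::thresh(sub, w = bg_radius, h = bg_radius, offset = 0.005) > 0
  }
  mask <- matrix(as.logical(mask), nrow(img), ncol(img))
  # fill bright holes, keep dark ones (nucleoli) excluded
  filled <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0
  filled <- matrix(as.logical(filled), nrow(img), ncol(img))
  holes <- filled & !mask
  if (any(holes)) {
    labf <- EBImage::bwlabel(EBImage::Image(filled * 1))
    labh <- EBImage::bwlabel(EBImage::Image(holes * 1))
    labf <- matrix(as.integer(labf), nrow(img), ncol(img))
    labh <- matrix(as.integer(labh), nrow(img), ncol(img))
    for (h in seq_len(max(labh))) {
      hp <- labh == h
      parent <- labf[hp][1L]
      body <- labf == parent & mask
      if (any(body) &&
          mean(img[hp]) >= hole_fill_frac * mean(img[body]))
        mask[hp] <- TRUE
    }
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  tab <- region_table(lab)
  keep <- tab$area_px >= min_area & tab$area_px <= max_area
  tab <- tab[keep, , drop = FALSE]
  # relabel in raster order of centroid
  ord <- order(tab$centroid_y, tab$centroid_x)
  tab <- tab[ord, , drop = FALSE]
  new_lab <- matrix(0L, nrow(img), ncol(img))
  for (i in seq_len(nrow(tab)))
    new_lab[lab == tab$label[i]] <- i
  tab$label <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(list(labels = new_lab, table = tab, flags = flags),
            class = "labeled_regions")
}

# per-label pixel count and centroid (0-based pixel-center coordinates)
region_table <- function(lab) {
  labs <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!length(labs))
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_x = numeric(), centroid_y = numeric()))
  idx <- which(lab > 0)
  ll <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab)      # 0-based y
  cols <- (idx - 1L) %/% nrow(lab)     # 0-based x
  data.frame(label = labs,
             area_px = as.integer(tabulate(ll)[labs]),
             centroid_x = tapply(cols, ll, mean)[as.character(labs)],
             centroid_y = tapply(rows, ll, mean)[as.character(labs)])
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat("labeled_regions:", nrow(x$table), "object(s)\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-nucleus granularity (within-mask intensity s.d.)
#'
#' For every label in the mask, the mean and the population standard
#' deviation (divisor n) of the pixel intensities inside the label. The
#' s.d. is the granularity statistic: a proxy for sub-resolution
#' intensity clustering. Empty labels are excluded with a message.
#'
#' @param image an [image_stack] or numeric matrix.
#' @param mask integer label matrix (from [segment_nuclei()] or ground
#'   truth), same y/x dimension.
#' @param pixel_size optional pixel size in nm to report areas in um^2.
#' @return data frame with `label`, `n_pixels`, `mean_intensity`,
#'   `intensity_sd`, `area_px` and (if `pixel_size` known) `area_um2`.
#' @export
granularity <- function(image, mask, pixel_size = NULL) {
  if (inherits(image, "image_stack") && is.null(pixel_size))
    pixel_size <- image$pixel_size
  img <- first_frame(image)
  if (inherits(mask, "labeled_regions")) mask <- mask$labels
  stopifnot(all(dim(img) == dim(mask)))
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  empty <- labs[!labs %in% mask[mask > 0]]
  res <- lapply(labs, function(l) {
    v <- img[mask == l]
    if (!length(v)) {
      message("granularity: label ", l, " is empty; excluded")
      return(NULL)
    }
    data.frame(label = l, n_pixels = length(v), mean_intensity = mean(v),
               intensity_sd = pop_sd(v), area_px = length(v))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(label = integer(), n_pixels = integer(),
                      mean_intensity = numeric(), intensity_sd = numeric(),
                      area_px = integer())
  if (!is.null(pixel_size))
    out$area_um2 <- out$area_px * (pixel_size / 1000)^2
  rownames(out) <- NULL
  out
}

#' Count and size cytosolic condensates in a time-lapse
#'
#' Per timepoint: maximum-intensity z-projection, removal of the supplied
#' nuclear regions from the analysis area, thresholding, and
#' connected-component counting with a minimum-area filter. The nuclear
#' ROIs are explicit inputs (the original workflow drew them manually),
#' which keeps the pipeline deterministic.
#'
#' @param stack an [image_stack] time-lapse.
#' @param nuclear_rois a polygon vertex data frame, a list of them, or a
#'   logical mask marking nuclei; must lie inside the frame.
#' @param threshold `"otsu"` for automatic thresholding over the cytosol,
#'   or a numeric intensity in AU.
#' @param min_area minimum object area in px^2.
#' @param timepoint_minutes optional acquisition times (min since
#'   stimulation) for the summary table.
#' @return an object of class `condensate_set` with `$objects` (one row
#'   per condensate: `timepoint`, `label`, `area_px2`, `area_um2`) and
#'   `$summary` (`timepoint`, `count`, `cytosol_area_um2`,
#'   `count_density` in objects per um^2).
#' @export
detect_condensates <- function(stack, nuclear_rois, threshold = "otsu",
                               min_area = 4, timepoint_minutes = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  nt <- d[1L]; nz <- d[2L]; ny <- d[3L]; nx <- d[4L]
  if (is.data.frame(nuclear_rois) ||
      (is.matrix(nuclear_rois) && !is.logical(nuclear_rois)))
    nuclear_rois <- list(nuclear_rois)
  nuc_mask <- if (is.list(nuclear_rois)) {
    m <- matrix(FALSE, ny, nx)
    for (r in nuclear_rois) m <- m | as_roi_mask(r, c(ny, nx))
    m
  } else as_roi_mask(nuclear_rois, c(ny, nx))
  px_um2 <- (stack$pixel_size / 1000)^2
  if (is.null(timepoint_minutes)) timepoint_minutes <- seq_len(nt) - 1
  objects <- list(); summary <- list()
  for (ti in seq_len(nt)) {
    proj <- apply(stack$pixels[ti, , , , 1, drop = FALSE], c(3, 4), max)
    cyto <- !nuc_mask
    th <- if (identical(threshold, "otsu")) {
      v <- proj / (2^stack$bit_depth - 1)
      if (max(v[cyto]) == min(v[cyto])) Inf
      else EBImage::otsu(EBImage::Image(v), range = c(0, 1)) *
        (2^stack$bit_depth - 1)
    } else threshold
    mask <- proj > th & cyto
    lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                  ny, nx)
    tab <- region_table(lab)
    tab <- tab[tab$area_px >= min_area, , drop = FALSE]
    cyto_area_um2 <- sum(cyto) * px_um2
    objects[[ti]] <- if (nrow(tab)) data.frame(
      timepoint = timepoint_minutes[ti], label = seq_len(nrow(tab)),
      area_px2 = tab$area_px, area_um2 = tab$area_px * px_um2) else NULL
    summary[[ti]] <- data.frame(
      timepoint = timepoint_minutes[ti], count = nrow(tab),
      cytosol_area_um2 = cyto_area_um2,
      count_density = nrow(tab) / cyto_area_um2)
  }
  structure(list(objects = do.call(rbind, objects),
                 summary = do.call(rbind, summary)),
            class = "condensate_set")
}

#' @export
print.condensate_set <- function(x, ...) {
  cat("condensate_set over", nrow(x$summary), "timepoint(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Nuclear/cytosolic translocation trace from a time-lapse
#'
#' Per frame: sum z-projection, optional translation-only registration to
#' the first frame (integer-pixel search maximizing the Pearson
#' correlation of the overlap), mean gray value in the nuclear and
#' cytosolic ROIs, and the relative nuclear localization
#' \eqn{I_{nuc} / (I_{nuc} + I_{cyto})}, bounded in [0, 1].
#'
#' @param stack an [image_stack] time-lapse.
#' @param nuc_roi,cyto_roi polygon vertex tables or logical masks
#'   (non-empty, inside the frame).
#' @param register register frames to frame 1 (translation only).
#' @param max_shift registration search radius in px.
#' @param timepoint_minutes optional frame times.
#' @return data frame of class `translocation_trace` with `t`, `I_nuc`,
#'   `I_cyto` and `relative_nuclear_localization`.
#' @export
translocation_trace <- function(stack, nuc_roi, cyto_roi, register = TRUE,
                                max_shift = 8, timepoint_minutes = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  nt <- d[1L]; ny <- d[3L]; nx <- d[4L]
  nm <- as_roi_mask(nuc_roi, c(ny, nx))
  cm <- as_roi_mask(cyto_roi, c(ny, nx))
  if (!any(nm) || !any(cm)) stop("ROIs must be non-empty")
  if (is.null(timepoint_minutes)) timepoint_minutes <- seq_len(nt) - 1
  zsum <- function(ti) apply(stack$pixels[ti, , , , 1, drop = FALSE],
                             c(3, 4), sum)
  ref <- zsum(1L)
  out <- data.frame(t = timepoint_minutes, I_nuc = NA_real_,
                    I_cyto = NA_real_,
                    relative_nuclear_localization = NA_real_)
  for (ti in seq_len(nt)) {
    fr <- zsum(ti)
    if (register && ti > 1L) {
      best <- c(0L, 0L); best_r <- -Inf
      for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
        sh <- shift_matrix(fr, dy, dx, NA)
        ok <- !is.na(sh)
        if (sum(ok) < 16) next
        r <- suppressWarnings(stats::cor(sh[ok], ref[ok]))
        if (!is.na(r) && r > best_r) { best_r <- r; best <- c(dy, dx) }
      }
      if (is.infinite(best_r)) {
        warning("registration failed (no overlap); using unregistered frame")
      } else {
        fr <- shift_matrix(fr, best[1L], best[2L], 0)
      }
    }
    In <- mean(fr[nm]); Ic <- mean(fr[cm])
    out$I_nuc[ti] <- In; out$I_cyto[ti] <- Ic
    out$relative_nuclear_localization[ti] <-
      if (In + Ic > 0) In / (In + Ic) else NA_real_
  }
  structure(out, class = c("translocation_trace", "data.frame"))
}

#' Rolling-ball background subtraction
#'
#' Grayscale opening with a ball-shaped structuring element of the given
#' radius: the background is the upper envelope of a ball of radius
#' `radius` px rolled under the intensity surface (erosion followed by
#' dilation with the ball height profile); the corrected image is the
#' input minus that background. Bright features smaller than the ball are
#' removed from the background and survive subtraction; smooth
#' large-scale gradients are followed and removed.
#'
#' @param img numeric matrix.
#' @param radius ball radius in px (>= 1).
#' @param height_scale intensity units per px of ball height.
#' @return list with `background` and `corrected` matrices.
#' @export
rolling_ball <- function(img, radius, height_scale = 1) {
  stopifnot(is.matrix(img), radius >= 1)
  r <- ceiling(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  z <- height_scale * sqrt(pmax(radius^2 - offs$dy^2 - offs$dx^2, 0))
  er <- matrix(Inf, nrow(img), ncol(img))
  for (i in seq_len(nrow(offs)))
    er <- pmin(er, shift_matrix(img, offs$dy[i], offs$dx[i], Inf) - z[i])
  bg <- matrix(-Inf, nrow(img), ncol(img))
  for (i in seq_len(nrow(offs)))
    bg <- pmax(bg, shift_matrix(er, offs$dy[i], offs$dx[i], -Inf) + z[i])
  bg[!is.finite(bg)] <- min(img)
  list(background = bg, corrected = img - bg)
}

#' Detect sub-nuclear clusters with rolling-ball background subtraction
#'
#' Nuclei are segmented from the DNA counterstain channel by Otsu
#' thresholding; the signal channel is background-corrected with a
#' rolling ball whose radius is `ball_multiple` times the resolution
#' limit (converted to pixels), then thresholded and connected components
#' inside nuclei are reported with their mean intensity and size. The
#' default threshold is robust background statistics on the corrected
#' image within nuclei (median + `threshold_k` MAD): cluster pixels are a
#' tiny fraction of the nuclear area, so a bimodality-based threshold
#' such as Otsu degenerates to splitting the noise distribution.
#'
#' @param stack an [image_stack] with the signal and DNA channels, or a
#'   list with matrices `signal` and `dna` plus `pixel_size`.
#' @param signal_channel,dna_channel channel indices when `stack` is an
#'   [image_stack].
#' @param resolution_limit limit of detection in nm (must be >= the pixel
#'   size).
#' @param ball_multiple rolling-ball radius as a multiple of the
#'   resolution limit (default 8).
#' @param min_area minimum cluster area in px^2.
#' @param threshold method: `"robust"` (median + `threshold_k` x MAD of
#'   the corrected image inside nuclei) or `"otsu"`.
#' @param threshold_k MAD multiplier for the robust threshold.
#' @param pixel_size pixel size in nm (taken from the stack if absent).
#' @return data frame of class `cluster_set`: `cluster`, `nucleus`,
#'   `mean_intensity`, `area_px`, `size_nm2`.
#' @export
detect_nuclear_clusters <- function(stack, signal_channel = 1L,
                                    dna_channel = 2L,
                                    resolution_limit = 48,
                                    ball_multiple = 8, min_area = 2,
                                    threshold = c("robust", "otsu"),
                                    threshold_k = 5,
                                    pixel_size = NULL) {
  threshold <- match.arg(threshold)
  if (inherits(stack, "image_stack")) {
    pixel_size <- stack$pixel_size
    signal <- stack_frame(stack, channel = signal_channel)
    dna <- stack_frame(stack, channel = dna_channel)
    maxval <- 2^stack$bit_depth - 1
  } else {
    signal <- stack$signal; dna <- stack$dna
    if (is.null(pixel_size)) pixel_size <- stack$pixel_size
    maxval <- max(dna, signal, 1)
  }
  if (is.null(pixel_size)) stop("pixel size is required")
  if (resolution_limit < pixel_size)
    stop("resolution limit (", resolution_limit,
         " nm) below pixel size (", pixel_size, " nm)")
  th_dna <- EBImage::otsu(EBImage::Image(dna / maxval), range = c(0, 1))
  nmask <- EBImage::fillHull(EBImage::Image((dna / maxval > th_dna) * 1)) > 0
  nmask <- matrix(as.logical(nmask), nrow(dna), ncol(dna))
  nlab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(nmask * 1))),
                 nrow(dna), ncol(dna))
  radius_px <- ball_multiple * resolution_limit / pixel_size
  rb <- rolling_ball(signal, radius_px)
  sub <- rb$corrected
  inn <- sub[nmask]
  if (!length(inn) || max(inn) <= min(inn))
    return(structure(data.frame(cluster = integer(), nucleus = integer(),
                                mean_intensity = numeric(),
                                area_px = integer(), size_nm2 = numeric()),
                     class = c("cluster_set", "data.frame")))
  th <- if (threshold == "robust") {
    stats::median(inn) + threshold_k * stats::mad(inn)
  } else {
    rng <- range(inn)
    EBImage::otsu(EBImage::Image((sub - rng[1]) / diff(rng)),
                  range = c(0, 1)) * diff(rng) + rng[1]
  }
  cmask <- sub > th & nmask
  clab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(cmask * 1))),
                 nrow(dna), ncol(dna))
  tab <- region_table(clab)
  tab <- tab[tab$area_px >= min_area, , drop = FALSE]
  res <- lapply(seq_len(nrow(tab)), function(i) {
    px <- clab == tab$label[i]
    data.frame(cluster = i,
               nucleus = as.integer(stats::median(nlab[px])),
               mean_intensity = mean(signal[px]),
               area_px = tab$area_px[i],
               size_nm2 = tab$area_px[i] * pixel_size^2)
  })
  out <- if (length(res)) do.call(rbind, res)
    else data.frame(cluster = integer(), nucleus = integer(),
                    mean_intensity = numeric(), area_px = integer(),
                    size_nm2 = numeric())
  structure(out, class = c("cluster_set", "data.frame"))
}

#' Per-droplet intensity quantification in multichannel droplet images
#'
#' Droplets are identified on the channel-sum image with a fixed lower
#' threshold given on the 8-bit scale (default 3, i.e. the (3,255)
#' convention; rescaled proportionally for 16-bit input). Objects whose
#' equivalent diameter exceeds `min_diameter` are kept and the mean
#' intensity of the channel of interest is reported per droplet, along
#' with a normalized cross-section profile through the largest droplet.
#'
#' @param stack an [image_stack] with >= 2 channels.
#' @param channel_of_interest channel to quantify.
#' @param threshold lower intensity bound on the 8-bit scale.
#' @param min_diameter minimum equivalent diameter in um (objects must be
#'   strictly larger).
#' @return an object of class `droplet_partitioning` with `$droplets`
#'   (`label`, `area_px`, `equiv_diameter_um`, `mean_intensity`) and
#'   `$profile` (normalized per-channel cross-section of the largest
#'   droplet).
#' @export
quantify_droplet_partitioning <- function(stack, channel_of_interest = 1L,
                                          threshold = 3,
                                          min_diameter = 0.1) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  nch <- d[5L]
  if (nch < 2) stop("need at least 2 registered channels")
  ny <- d[3L]; nx <- d[4L]
  chsum <- matrix(0, ny, nx)
  for (ch in seq_len(nch)) chsum <- chsum + stack_frame(stack, channel = ch)
  thr_abs <- threshold / 255 * (2^stack$bit_depth - 1)
  mask <- chsum >= thr_abs
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(mask * 1))),
                ny, nx)
  tab <- region_table(lab)
  px_um <- stack$pixel_size / 1000
  tab$equiv_diameter_um <- 2 * sqrt(tab$area_px / pi) * px_um
  tab <- tab[tab$equiv_diameter_um > min_diameter, , drop = FALSE]
  coi <- stack_frame(stack, channel = channel_of_interest)
  droplets <- if (nrow(tab)) data.frame(
    label = seq_len(nrow(tab)), area_px = tab$area_px,
    equiv_diameter_um = tab$equiv_diameter_um,
    mean_intensity = vapply(tab$label, function(l) mean(coi[lab == l]),
                            numeric(1))) else
    data.frame(label = integer(), area_px = integer(),
               equiv_diameter_um = numeric(), mean_intensity = numeric())
  profile <- NULL
  if (nrow(tab)) {
    big <- tab[which.max(tab$area_px), ]
    row <- round(big$centroid_y) + 1L
    cols <- which(lab[row, ] == big$label)
    cols <- min(cols):max(cols)
    profile <- do.call(rbind, lapply(seq_len(nch), function(ch) {
      v <- stack_frame(stack, channel = ch)[row, cols]
      rng <- range(v)
      data.frame(channel = ch,
                 x_um = (cols - 1 - big$centroid_x) * px_um,
                 intensity_norm = if (diff(rng) > 0)
                   (v - rng[1]) / diff(rng) else rep(0, length(v)))
    }))
  }
  structure(list(droplets = droplets, profile = profile),
            class = "droplet_partitioning")
}

#' @export
print.droplet_partitioning <- function(x, ...) {
  cat("droplet_partitioning:", nrow(x$droplets), "droplet(s)\n")
  if (nrow(x$droplets))
    cat("  mean intensity:", format(mean(x$droplets$mean_intensity),
                                    digits = 4), "\n")
  invisible(x)
}
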