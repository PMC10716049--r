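#' Write an image stack to a multi-page TIFF with a metadata sidecar
#'
#' Pages are ordered t-major, then z, then channel. The axis layout,
#' bit depth and physical pixel size are written to a YAML sidecar
#' (`<path>.meta.yaml`) so [read_image_stack()] can reconstruct the five
#' axes and units. 8/16-bit integer data round-trips bit-exactly.
#'
#' @param stack an [image_stack].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$pixels)
  maxval <- 2^stack$bit_depth - 1
  pages <- list()
  for (ti in seq_len(d[1L])) for (zi in seq_len(d[2L]))
    for (ci in seq_len(d[5L]))
      pages[[length(pages) + 1L]] <- stack$pixels[ti, zi, , , ci] / maxval
  tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                  compression = "none", reduce = FALSE)
  yaml::write_yaml(list(axes = "tzyxc", t = d[1L], z = d[2L], c = d[5L],
                        bit_depth = stack$bit_depth,
                        pixel_size_nm = stack$pixel_size),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a TIFF into an image stack
#'
#' Axes are normalized to (t, z, y, x, channel) using the metadata
#' sidecar written by [write_image_stack()] when present; otherwise each
#' page becomes one timepoint. The pixel size comes from the sidecar or
#' the `pixel_size` override; without either, reading fails (physical
#' units are required downstream).
#'
#' @param path TIFF file path.
#' @param pixel_size override/fallback pixel size in nm.
#' @return an [image_stack].
#' @export
read_image_stack <- function(path, pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1L]])
  bit <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 16L
  nt <- length(pages); nz <- 1L; nc <- 1L
  px <- pixel_size
  meta_path <- paste0(path, ".meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    nt <- meta$t; nz <- meta$z; nc <- meta$c
    bit <- meta$bit_depth
    if (is.null(px)) px <- meta$pixel_size_nm
  }
  if (is.null(px))
    stop("pixel size not available (no metadata sidecar); pass 'pixel_size='")
  maxval <- 2^bit - 1
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  arr <- array(0, c(nt, nz, ny, nx, nc))
  p <- 1L
  for (ti in seq_len(nt)) for (zi in seq_len(nz)) for (ci in seq_len(nc)) {
    pg <- pages[[p]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1L]
    arr[ti, zi, , , ci] <- round(pg * maxval)
    p <- p + 1L
  }
  image_stack(arr, pixel_size = px, bit_depth = bit)
}

#' Write a ground-truth sidecar file
#'
#' Serializes the scalar and vector entries of a [ground_truth] to YAML
#' next to the data it describes, so round trips need no shared process
#' state.
#'
#' @param truth a [ground_truth].
#' @param path output path (conventionally `<data>.truth.yaml`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  keep <- truth$params[vapply(truth$params, function(p)
    is.atomic(p) && !is.matrix(p), logical(1))]
  yaml::write_yaml(list(seed = truth$seed, params = keep), path)
  invisible(path)
}

#' Read a ground-truth sidecar file
#'
#' @param path sidecar path written by [write_ground_truth()].
#' @return a [ground_truth].
#' @export
read_ground_truth <- function(path) {
  d <- yaml::read_yaml(path)
  ground_truth(d$params, d$seed)
}

.pipeline_stages <- c("frap", "turbidity", "dose_response", "contacts",
                      "granularity")

.config_keys <- c("stage", "out_dir", "seed", "params")

#' Run a simulate-analyze-recover pipeline stage
#'
#' Deterministically chains a synthetic-data generator with the matching
#' estimator and writes tidy CSV outputs, the resolved configuration and
#' a content-hash manifest to the output directory. Stages:
#' \describe{
#'   \item{frap}{[gen_frap_trace()] -> [normalize_double()] ->
#'     [fit_recovery()]}
#'   \item{turbidity}{[gen_turbidity_curve()] -> [cloud_point()]}
#'   \item{dose_response}{[gen_dose_response()] -> [fit_log_logistic()]}
#'   \item{contacts}{[gen_contact_trajectory()] -> [contact_summary()] ->
#'     [simulated_kd()]}
#'   \item{granularity}{[gen_nuclei_field()] -> [segment_nuclei()] ->
#'     [granularity()]}
#' }
#' All randomness flows from the config seed. Unknown configuration keys
#' are rejected before any computation. On stage failure a
#' `<stage>.failed` marker is written and the status is nonzero.
#'
#' @param config a named list (or path to a YAML file) with keys `stage`,
#'   `out_dir`, `seed` and optionally `params` (arguments passed to the
#'   stage generator).
#' @return invisibly, a list with `status` (0 = success) and `manifest`
#'   (data frame `file`, `md5`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$stage) || !config$stage %in% .pipeline_stages)
    stop("config$stage must be one of: ",
         paste(.pipeline_stages, collapse = ", "))
  if (is.null(config$out_dir) || is.null(config$seed))
    stop("config needs 'out_dir' and 'seed'")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  params <- if (is.null(config$params)) list() else config$params
  seed <- as.integer(config$seed)
  status <- 0L
  res <- tryCatch({
    switch(config$stage,
      frap = {
        g <- do.call(gen_frap_trace, c(params, list(seed = seed)))
        long <- data.frame(
          t = rep(g$trace$t, 3),
          roi = rep(c("bleach", "whole", "background"), each = nrow(g$trace)),
          value = c(g$trace$bleach, g$trace$whole, g$trace$background))
        utils::write.csv(long, file.path(out, "frap_trace.csv"),
                         row.names = FALSE)
        norm <- normalize_double(g$trace)
        fit <- fit_recovery(norm)
        utils::write.csv(as.data.frame(norm),
                         file.path(out, "frap_normalized.csv"),
                         row.names = FALSE)
        utils::write.csv(data.frame(t(coef(fit))),
                         file.path(out, "frap_fit.csv"), row.names = FALSE)
        write_ground_truth(g$truth, file.path(out, "frap_truth.yaml"))
      },
      turbidity = {
        g <- do.call(gen_turbidity_curve, c(params, list(seed = seed)))
        utils::write.csv(g$curve, file.path(out, "turbidity.csv"),
                         row.names = FALSE)
        cp <- cloud_point(g$curve)
        utils::write.csv(data.frame(Tc = cp$Tc,
                                    peak_height = cp$peak_height,
                                    flag = cp$flag),
                         file.path(out, "cloud_point.csv"),
                         row.names = FALSE)
        write_ground_truth(g$truth, file.path(out, "turbidity_truth.yaml"))
      },
      dose_response = {
        g <- do.call(gen_dose_response, c(params, list(seed = seed)))
        utils::write.csv(g$data, file.path(out, "dose_response.csv"),
                         row.names = FALSE)
        fit <- fit_log_logistic(g$data$dose, g$data$response)
        utils::write.csv(data.frame(b = fit$b, d = fit$d, e = fit$e,
                                    IC50 = fit$IC50, IC10 = fit$IC10),
                         file.path(out, "dose_response_fit.csv"),
                         row.names = FALSE)
        write_ground_truth(g$truth,
                           file.path(out, "dose_response_truth.yaml"))
      },
      contacts = {
        if (is.null(params$n_frames)) params$n_frames <- 1e4
        g <- do.call(gen_contact_trajectory, c(params, list(seed = seed)))
        cs <- contact_summary(g$cm)
        utils::write.csv(cs$per_residue,
                         file.path(out, "contact_probabilities.csv"),
                         row.names = FALSE)
        kd <- simulated_kd(cs$fB, cs$fB_se)
        utils::write.csv(data.frame(fB = cs$fB, fB_se = cs$fB_se,
                                    C0_M = kd$C0, Kd_M = kd$Kd,
                                    Kd_se_M = kd$Kd_se),
                         file.path(out, "kd_summary.csv"),
                         row.names = FALSE)
        write_ground_truth(g$truth, file.path(out, "contacts_truth.yaml"))
      },
      granularity = {
        g <- do.call(gen_nuclei_field, c(params, list(seed = seed)))
        write_image_stack(g$image, file.path(out, "nuclei.tiff"))
        seg <- segment_nuclei(g$image)
        gr <- granularity(g$image, seg)
        utils::write.csv(gr, file.path(out, "granularity.csv"),
                         row.names = FALSE)
        write_ground_truth(g$truth,
                           file.path(out, "granularity_truth.yaml"))
      })
    NULL
  }, error = function(e) e)
  if (inherits(res, "error")) {
    writeLines(conditionMessage(res),
               file.path(out, paste0(config$stage, ".failed")))
    status <- 1L
  }
  resolved <- list(stage = config$stage, out_dir = out, seed = seed,
                   params = params,
                   package_version = as.character(
                     utils::packageVersion("condensakit")))
  yaml::write_yaml(resolved, file.path(out, "config.resolved.yaml"))
  files <- setdiff(list.files(out, full.names = TRUE),
                   file.path(out, "config.resolved.yaml"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(status = status, manifest = manifest))
}
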