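#' FRAP trace triple
#'
#' Container for the three regions of interest recorded in a FRAP
#' experiment: the bleached region, a region spanning the whole cell, and a
#' background region outside the cells. Negative times are pre-bleach
#' frames; t = 0 is the first post-bleach frame.
#'
#' @param t time in seconds (negative = pre-bleach).
#' @param bleach,whole,background per-frame mean intensities, AU.
#' @return a data frame of class `frap_trace`.
#' @export
frap_trace <- function(t, bleach, whole, background) {
  stopifnot(length(t) == length(bleach), length(t) == length(whole),
            length(t) == length(background))
  if (sum(t < 0) < 2)
    stop("a FRAP trace needs at least 2 pre-bleach frames (t < 0)")
  if (mean(whole) < mean(background))
    stop("whole-cell intensity is below background on average")
  structure(data.frame(t = t, bleach = bleach, whole = whole,
                       background = background),
            class = c("frap_trace", "data.frame"))
}

#' Read a FRAP trace from a long-format CSV
#'
#' Expects columns `t,roi,value` with `roi` taking the values `bleach`,
#' `whole` and `background`.
#'
#' @param path CSV file path.
#' @return a [frap_trace].
#' @export
read_frap_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("t", "roi", "value") %in% names(d)))
  rois <- c("bleach", "whole", "background")
  if (!all(rois %in% d$roi))
    stop("CSV must contain bleach, whole and background ROIs")
  wide <- lapply(rois, function(r) {
    s <- d[d$roi == r, ]
    s[order(s$t), "value"]
  })
  t <- sort(unique(d$t))
  frap_trace(t, wide[[1L]], wide[[2L]], wide[[3L]])
}

#' Double normalization of a FRAP trace
#'
#' Corrects the bleach-ROI signal for acquisition photobleaching and for
#' intensity differences between cells:
#' \deqn{N(t) = \frac{(I_{bleach} - I_{bg})(t) / (I_{whole} - I_{bg})(t)}
#'                   {\langle (I_{bleach} - I_{bg}) / (I_{whole} - I_{bg})
#'                    \rangle_{pre}}}
#' so that the pre-bleach mean of N is 1 and any bleaching that affects the
#' bleach and whole-cell ROIs equally cancels.
#'
#' Frames where the whole-cell signal does not exceed background are
#' dropped with a message; if no frame survives, an error is raised.
#'
#' @param trace a [frap_trace].
#' @return a data frame `t`, `N` of class `frap_norm`; the number of
#'   dropped frames is available as `attr(, "n_dropped")`.
#' @export
normalize_double <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  denom <- trace$whole - trace$background
  keep <- denom > 0
  if (!all(keep))
    message("normalize_double: dropping ", sum(!keep),
            " frame(s) with whole-cell signal <= background")
  if (!any(keep)) stop("all frames rejected: whole-cell <= background")
  tr <- trace[keep, ]
  ratio <- (tr$bleach - tr$background) / (tr$whole - tr$background)
  pre <- ratio[tr$t < 0]
  if (length(pre) < 1 || mean(pre) == 0)
    stop("cannot normalize: no usable pre-bleach frames")
  out <- data.frame(t = tr$t, N = ratio / mean(pre))
  structure(out, class = c("frap_norm", "data.frame"),
            n_dropped = sum(!keep))
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of \eqn{N(t) = I_0 + (F_\infty - I_0)(1 - e^{-kt})} to
#' the post-bleach (t >= 0) part of a double-normalized trace. The mobile
#' fraction is \eqn{(F_\infty - I_0)/(1 - I_0)} and the half-time of
#' recovery \eqn{t_{1/2} = \ln 2 / k}.
#'
#' Initial guesses are deterministic: \eqn{I_0} from the first post-bleach
#' point, \eqn{F_\infty} from the mean of the last 10% of frames, and
#' \eqn{k} from the time at which the trace first reaches half of
#' \eqn{F_\infty - I_0}.
#'
#' @param norm_trace a `frap_norm` from [normalize_double()].
#' @return an object of class `frap_fit` with components
#'   `mobile_fraction`, `t_half`, `k`, `I0_norm`, `plateau_norm`, `rmse`,
#'   `flags` and the underlying `nls` fit.
#' @export
fit_recovery <- function(norm_trace) {
  stopifnot(inherits(norm_trace, "frap_norm"))
  post <- norm_trace[norm_trace$t >= 0, ]
  if (nrow(post) < 10) stop("need at least 10 post-bleach frames")
  t <- post$t; N <- post$N
  I0_init <- N[1L]
  tail_n <- max(3L, ceiling(0.1 * length(N)))
  Finf_init <- mean(N[(length(N) - tail_n + 1L):length(N)])
  flags <- character(0)
  if (abs(I0_init - 1) < 1e-6 && stats::sd(N) < 1e-6)
    stop("degenerate trace: no bleach detected (N = 1 throughout)")
  if (Finf_init - I0_init < 1e-8) {
    # flat post-bleach trace: nothing recovers
    return(structure(list(
      mobile_fraction = 0, t_half = NA_real_, k = NA_real_,
      I0_norm = I0_init, plateau_norm = Finf_init,
      rmse = sqrt(mean((N - mean(N))^2)),
      flags = c("immobile"), fit = NULL, data = post), class = "frap_fit"))
  }
  half_level <- I0_init + (Finf_init - I0_init) / 2
  i_half <- which(N >= half_level)
  t_half_init <- if (length(i_half)) max(t[min(i_half)], t[2L]) else t[2L]
  k_init <- log(2) / t_half_init
  fit <- minpack.lm::nlsLM(
    N ~ I0 + (Finf - I0) * (1 - exp(-k * t)),
    data = data.frame(t = t, N = N),
    start = list(I0 = I0_init, Finf = Finf_init, k = k_init),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  if (co[["Finf"]] < co[["I0"]]) flags <- c(flags, "immobile")
  mf <- (co[["Finf"]] - co[["I0"]]) / (1 - co[["I0"]])
  if (mf < 0 || mf > 1) {
    flags <- c(flags, "mobile_fraction_clipped")
    mf <- min(max(mf, 0), 1)
  }
  structure(list(
    mobile_fraction = mf,
    t_half = log(2) / co[["k"]],
    k = co[["k"]],
    I0_norm = co[["I0"]],
    plateau_norm = co[["Finf"]],
    rmse = sqrt(mean(stats::resid(fit)^2)),
    flags = flags, fit = fit, data = post), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, digits = 4, ...) {
  cat("FRAP single-exponential recovery fit\n")
  cat("  mobile fraction:", format(100 * x$mobile_fraction, digits = digits),
      "%\n")
  cat("  t1/2:           ", format(x$t_half, digits = digits), "s\n")
  cat("  k:              ", format(x$k, digits = digits), "s^-1\n")
  cat("  RMSE:           ", format(x$rmse, digits = digits), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.frap_fit <- function(object, ...) {
  c(mobile_fraction = object$mobile_fraction, t_half = object$t_half,
    k = object$k, I0_norm = object$I0_norm,
    plateau_norm = object$plateau_norm)
}

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else newdata$t
  if (is.na(object$k)) return(rep(object$I0_norm, length(t)))
  object$I0_norm + (object$plateau_norm - object$I0_norm) *
    (1 - exp(-object$k * t))
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$N, xlab = "t (s)",
                 ylab = "normalized intensity", pch = 16, cex = 0.5, ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, data.frame(t = tt)), col = 2, lwd = 2)
  invisible(x)
}

#' @export
residuals.frap_fit <- function(object, ...) {
  object$data$N - predict(object)
}
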