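#' Granularity slope-contrast linear model with Dunnett adjustment
#'
#' Models the within-nucleus intensity standard deviation (granularity) as
#' a function of mean nuclear intensity, experimental group, their
#' interaction, and biological replicate:
#' `intensity_sd ~ mean_intensity * group + replicate` (ordinary least
#' squares). The slope between mean intensity and s.d. is compared for
#' every group against the control through the interaction terms, and the
#' family of slope contrasts is adjusted with Dunnett's
#' multiple-comparison correction.
#'
#' @param records data frame with columns `intensity_sd`,
#'   `mean_intensity`, `group` and `replicate` (one row per nucleus).
#' @param control_group the reference group level.
#' @param mc_seed seed for the Monte-Carlo Dunnett integration.
#' @param n_mc Monte-Carlo sample size.
#' @return an object of class `granularity_fit` with the underlying `lm`
#'   and a `contrasts` data frame (`group`, `estimate`, `se`, `t`,
#'   `p_raw`, `p_adj`).
#' @export
granularity_model <- function(records, control_group,
                              mc_seed = 1234L, n_mc = 1e5) {
  records <- as.data.frame(records)
  need <- c("intensity_sd", "mean_intensity", "group", "replicate")
  stopifnot(all(need %in% names(records)))
  records$group <- stats::relevel(factor(records$group),
                                  ref = as.character(control_group))
  records$replicate <- factor(records$replicate)
  if (nlevels(records$group) < 2)
    stop("need at least 2 groups including the control")
  if (min(table(records$group)) < 3)
    stop("need at least 3 nuclei per group")
  form <- intensity_sd ~ mean_intensity * group + replicate
  if (nlevels(records$replicate) < 2) {
    warning("single replicate level: dropping the replicate term")
    form <- intensity_sd ~ mean_intensity * group
  }
  fit <- stats::lm(form, data = records)
  cn <- names(stats::coef(fit))
  ix <- grep("^mean_intensity:group", cn)
  if (!length(ix)) stop("no interaction terms estimated (rank-deficient?)")
  est <- stats::coef(fit)[ix]
  V <- stats::vcov(fit)[ix, ix, drop = FALSE]
  adj <- dunnett_adjust(est, V, df = stats::df.residual(fit),
                        n_mc = n_mc, seed = mc_seed)
  contrasts <- data.frame(
    group = sub("^mean_intensity:group", "", cn[ix]),
    estimate = unname(est), se = sqrt(diag(V)),
    t = adj$t, p_raw = adj$p_raw, p_adj = adj$p_adj)
  structure(list(fit = fit, contrasts = contrasts,
                 control = as.character(control_group),
                 df = stats::df.residual(fit)),
            class = "granularity_fit")
}

#' @export
print.granularity_fit <- function(x, digits = 4, ...) {
  cat("Granularity slope-contrast model (control:", x$control, ")\n")
  cat("Slope differences vs control (Dunnett-adjusted):\n")
  print(format(x$contrasts, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.granularity_fit <- function(object, ...) {
  list(lm_summary = summary(object$fit), contrasts = object$contrasts)
}

#' @export
coef.granularity_fit <- function(object, ...) stats::coef(object$fit)

#' Dunnett many-to-one adjustment of contrast p-values
#'
#' Two-sided p-values from the distribution of the maximum absolute
#' component of a multivariate t vector with the contrast correlation
#' matrix, evaluated by seeded Monte-Carlo integration (a closed form does
#' not exist for general correlation). With one contrast this reduces to
#' the ordinary two-sided t-test; for independent contrasts it approaches
#' the Sidak bound \eqn{1 - (1 - p)^m}.
#'
#' @param estimates contrast estimates.
#' @param covariance their covariance matrix.
#' @param df residual degrees of freedom (Inf for the normal limit).
#' @param n_mc Monte-Carlo sample size (1e5 gives ~1e-3 accuracy).
#' @param seed RNG seed for the integration.
#' @return list with `t`, `p_raw` and `p_adj`.
#' @export
dunnett_adjust <- function(estimates, covariance, df, n_mc = 1e5,
                           seed = 1234L) {
  estimates <- as.numeric(estimates)
  covariance <- as.matrix(covariance)
  m <- length(estimates)
  stopifnot(nrow(covariance) == m, ncol(covariance) == m, m >= 1)
  se <- sqrt(diag(covariance))
  tval <- estimates / se
  p_raw <- 2 * stats::pt(-abs(tval), df)
  if (m == 1L) {
    return(list(t = tval, p_raw = p_raw, p_adj = p_raw))
  }
  R <- covariance / tcrossprod(se)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("covariance is not positive semidefinite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  maxabs <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n_mc * m), n_mc, m) %*% L
    if (is.finite(df)) {
      s <- sqrt(stats::rchisq(n_mc, df) / df)
      Z <- Z / s
    }
    apply(abs(Z), 1L, max)
  })
  p_adj <- vapply(abs(tval), function(ti) mean(maxabs >= ti), numeric(1))
  p_adj <- pmax(p_adj, p_raw)  # family-wise p cannot undercut the raw p
  list(t = tval, p_raw = p_raw, p_adj = p_adj)
}

#' Three-parameter log-logistic dose-response fit
#'
#' Nonlinear least-squares fit of the three-parameter log-logistic model
#' with lower limit 0:
#' \deqn{f(x) = \frac{d}{1 + \exp(b(\ln x - \ln e))}}
#' where `e` is the IC50, `d` the upper asymptote and `b` the slope.
#' Zero-dose controls are retained as observations of the upper limit
#' (the x -> 0 limit of the model). IC10, the dose giving 10% inhibition
#' relative to `d`, is \eqn{e \cdot 9^{-1/b}}.
#'
#' @param dose doses (>= 4 distinct positive values; zeros allowed as
#'   controls).
#' @param response measured responses (negative values permitted as
#'   noise).
#' @return an object of class `log_logistic_fit` with `b`, `d`, `e`,
#'   `IC50`, `IC10`, `vcov` and the underlying fit.
#' @export
fit_log_logistic <- function(dose, response) {
  stopifnot(length(dose) == length(response))
  pos <- dose > 0
  if (length(unique(dose[pos])) < 4)
    stop("need at least 4 distinct positive doses")
  if (stats::sd(response) < .Machine$double.eps^0.5 * max(abs(response), 1))
    stop("responses do not vary with dose: model not identifiable")
  d0 <- max(mean(response[!pos]), mean(response[dose == min(dose[pos])]),
            na.rm = TRUE)
  if (d0 <= 0) d0 <- max(response)
  # first dose where the mean response drops below half the upper estimate
  mu <- tapply(response[pos], dose[pos], mean)
  dl <- as.numeric(names(mu))
  below <- which(mu < d0 / 2)
  e0 <- if (length(below)) dl[min(below)] else stats::median(dl)
  if (e0 <= 0) e0 <- stats::median(dl)
  ll3 <- function(x, b, d, e)
    ifelse(x <= 0, d, d / (1 + exp(b * (log(x) - log(e)))))
  fit <- minpack.lm::nlsLM(
    response ~ ll3(dose, b, d, e),
    data = data.frame(dose = dose, response = response),
    start = list(b = 1, d = d0, e = e0),
    lower = c(-Inf, 1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  co <- stats::coef(fit)
  b <- co[["b"]]; d <- co[["d"]]; e <- co[["e"]]
  structure(list(
    b = b, d = d, e = e, IC50 = e, IC10 = e * 9^(-1 / b),
    vcov = stats::vcov(fit), fit = fit,
    data = data.frame(dose = dose, response = response)),
    class = "log_logistic_fit")
}

#' @export
print.log_logistic_fit <- function(x, digits = 4, ...) {
  cat("Three-parameter log-logistic fit (lower limit 0)\n")
  cat(sprintf("  b (slope): %s\n  d (upper): %s\n  e (IC50):  %s\n",
              format(x$b, digits = digits), format(x$d, digits = digits),
              format(x$e, digits = digits)))
  cat("  IC10:     ", format(x$IC10, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.log_logistic_fit <- function(object, ...) {
  c(b = object$b, d = object$d, e = object$e)
}

#' @export
predict.log_logistic_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dose else newdata$dose
  ifelse(x <= 0, object$d,
         object$d / (1 + exp(object$b * (log(x) - log(object$e)))))
}

#' @export
plot.log_logistic_fit <- function(x, ...) {
  d <- x$data[x$data$dose > 0, ]
  graphics::plot(d$dose, d$response, log = "x", xlab = "dose",
                 ylab = "response", pch = 16, ...)
  xx <- exp(seq(log(min(d$dose)), log(max(d$dose)), length.out = 100))
  graphics::lines(xx, predict(x, data.frame(dose = xx)), col = 2, lwd = 2)
  invisible(x)
}

#' Chromatographic LogD from the hydrophobicity index
#'
#' Affine conversion of the chromatographic hydrophobicity index (CHI) to
#' a lipophilicity measure: ChromLogD = 0.0857 * CHI - 2.
#'
#' @param CHI chromatographic hydrophobicity index (finite, vectorized).
#' @return ChromLogD values.
#' @export
chrom_logd <- function(CHI) {
  if (any(!is.finite(CHI))) stop("'CHI' must be finite")
  0.0857 * CHI - 2
}

#' Fold change by the 2^-ddCt method
#'
#' Relative expression of a target transcript in a treated sample versus
#' control, each normalized to a reference transcript:
#' \eqn{2^{-((Ct_{target,tx} - Ct_{ref,tx}) -
#' (Ct_{target,ctrl} - Ct_{ref,ctrl}))}}.
#'
#' @param ct_target_tx,ct_ref_tx Ct values in the treated sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values in the control sample.
#' @return fold change (vectorized).
#' @export
fold_change_ddct <- function(ct_target_tx, ct_ref_tx,
                             ct_target_ctrl, ct_ref_ctrl) {
  if (any(!is.finite(c(ct_target_tx, ct_ref_tx, ct_target_ctrl,
                       ct_ref_ctrl))))
    stop("Ct values must be finite")
  2^(-((ct_target_tx - ct_ref_tx) - (ct_target_ctrl - ct_ref_ctrl)))
}

#' Ovoid tumor volume from caliper measurements
#'
#' @param length,width,height caliper measurements in mm (> 0).
#' @return volume in mm^3: length x width x height x 0.5236.
#' @export
ovoid_volume <- function(length, width, height) {
  if (any(c(length, width, height) <= 0))
    stop("all dimensions must be > 0")
  length * width * height * 0.5236
}
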