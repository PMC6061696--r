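## NMR observable models: trans-H-bond scalar coupling from constant-time
## intensity ratios, and ion-binding chemical-shift isotherms.

#' Fit a trans-hydrogen-bond scalar coupling from constant-time intensities
#'
#' Globally least-squares fits `I_cross/I_ref = cos(pi * J * tau_m)` with a
#' single coupling `J` (Hz) shared across replicates. All replicate points
#' are pooled, so replicates are implicitly weighted by their point count.
#' The fit is initialized by a grid search over `J` in `[0, 20]` Hz with
#' 0.05 Hz steps (the smallest-J grid minimum wins when the cosine admits
#' several equivalent solutions) and refined by bounded local minimization.
#' Uncertainty is estimated by a residual bootstrap.
#'
#' @param series a [CTIntensitySeries-class] or a list of them (one per
#'   replicate).
#' @param gridMax,gridStep grid-search range and step in Hz.
#' @param nBoot number of residual-bootstrap resamples (0 to skip).
#' @param seed integer seed for the bootstrap.
#' @param minDelays minimum number of distinct delays required (default 3);
#'   lower it deliberately for degenerate checks such as reading `J` off a
#'   single cosine zero crossing, where `J = 1/(2 tau)`.
#' @return a list of class `"uturnJFit"`: `J` (Hz), `rss`, `residuals`
#'   (with replicate ids), `converged`, `gridStart` (Hz), `Jse` and `Jci`
#'   (bootstrap standard error and 2.5/97.5% interval, when `nBoot > 0`),
#'   `n` (points) and `seed`.
#' @examples
#' s <- genCTSeries(J = 2.7, seed = 1, noise = 0)
#' fitCTJCoupling(s, nBoot = 0)$J
#' @export
fitCTJCoupling <- function(series, gridMax = 20, gridStep = 0.05,
                           nBoot = 200L, seed = 1L, minDelays = 3L) {
  if (is(series, "CTIntensitySeries")) series <- list(series)
  stopifnot(all(vapply(series, is, TRUE, "CTIntensitySeries")))
  tau <- unlist(lapply(series, function(s) s@tau))
  ratio <- unlist(lapply(series, function(s) s@ratio))
  repl <- unlist(lapply(series, function(s) rep(s@replicate, length(s@tau))))
  if (length(unique(tau)) < minDelays)
    stop("fewer than ", minDelays, " distinct constant-time delays")
  rss <- function(J) sum((ratio - cos(pi * J * tau))^2)
  if (all(ratio == 1)) {
    warning("all intensity ratios are 1: no detectable coupling, J = 0")
    fit <- list(minimum = 0, objective = 0)
    gridStart <- 0
  } else {
    grid <- seq(0, gridMax, by = gridStep)
    sse <- vapply(grid, rss, 0)
    gridStart <- grid[which.min(sse)]     # ties: smallest J
    lo <- max(0, gridStart - gridStep)
    hi <- min(gridMax, gridStart + gridStep)
    fit <- optimize(rss, c(lo, hi), tol = 1e-12)
  }
  J <- fit$minimum
  res <- ratio - cos(pi * J * tau)
  out <- list(J = J, rss = sum(res^2),
              residuals = data.frame(tau = tau, replicate = repl,
                                     residual = res),
              converged = TRUE, gridStart = gridStart, n = length(tau),
              seed = as.integer(seed))
  if (nBoot > 0) {
    set.seed(seed)
    fitted <- cos(pi * J * tau)
    Jb <- vapply(seq_len(nBoot), function(b) {
      rb <- fitted + sample(res, replace = TRUE)
      sseB <- function(Jx) sum((rb - cos(pi * Jx * tau))^2)
      optimize(sseB, c(max(0, J - 1), J + 1), tol = 1e-10)$minimum
    }, 0)
    out$Jse <- sd(Jb)
    out$Jci <- unname(quantile(Jb, c(0.025, 0.975)))
  }
  structure(out, class = "uturnJFit")
}

#' @export
print.uturnJFit <- function(x, ...) {
  cat("Constant-time J fit: J =", sprintf("%.3f", x$J), "Hz")
  if (!is.null(x$Jse))
    cat(" +/-", sprintf("%.3f", x$Jse), "Hz (bootstrap)")
  cat("; rss =", signif(x$rss, 4), "on", x$n, "points\n")
  invisible(x)
}

isothermCurve <- function(conc, kd, ddmax, model) {
  h <- if (model == "cooperative2") 2 else 1
  ddmax * conc^h / (kd^h + conc^h)
}

#' Fit a chemical-shift binding isotherm
#'
#' Single-site model: `dd(c) = ddmax * c / (KD + c)`. Cooperative two-ion
#' model (Hill form with coefficient fixed at 2):
#' `dd(c) = ddmax * c^2 / (KD^2 + c^2)`. Fitted by nonlinear least squares
#' (Levenberg-Marquardt) with `KD > 0` bounded; `KD` is initialized at the
#' concentration nearest half of the maximum observed shift. The free
#' titrant concentration is taken equal to the total (no ligand-depletion
#' correction), valid for mM-scale titrant against uM-scale RNA.
#'
#' @param series a [TitrationSeries-class].
#' @param model `"single-site"` or `"cooperative2"`; defaults to the
#'   series' model tag.
#' @param nBoot residual-bootstrap resamples for the KD confidence interval
#'   (0 to skip).
#' @param seed integer seed for the bootstrap.
#' @return a list of class `"uturnIsothermFit"`: `KD` (same unit as the
#'   concentrations, mM by convention), `ddMax` (ppm), `model`, `rss`,
#'   `residuals`, `fitted`, `KDci` (when `nBoot > 0`), `n` and `seed`.
#' @examples
#' s <- genTitration(KD = 3, ddMax = 0.2, seed = 1, noise = 0)
#' fitBindingIsotherm(s)$KD
#' @export
fitBindingIsotherm <- function(series, model = NULL, nBoot = 0L, seed = 1L) {
  stopifnot(is(series, "TitrationSeries"))
  if (is.null(model)) model <- series@model
  model <- match.arg(model, c("single-site", "cooperative2"))
  conc <- series@conc; dd <- series@dshift
  if (length(conc) < 4L) stop("at least 4 titration points are required")
  rho <- suppressWarnings(cor(conc, dd, method = "spearman"))
  if (!is.na(rho) && rho < 0)
    stop("shift changes decrease with concentration; ",
         "flip the sign of dshift and refit")
  if (!(min(dd) < max(dd) / 2))
    warning("titration points may not span the half-saturation region")
  ddmax0 <- max(dd)
  kd0 <- conc[which.min(abs(dd - ddmax0 / 2))]
  if (kd0 <= 0) kd0 <- max(min(conc[conc > 0]), 1e-6)
  dat <- data.frame(conc = conc, dd = dd)
  h <- if (model == "cooperative2") 2 else 1
  fit <- minpack.lm::nlsLM(
    dd ~ ddmax * conc^h / (kd^h + conc^h),
    data = cbind(dat, h = h),
    start = list(kd = kd0, ddmax = ddmax0),
    lower = c(kd = 1e-12, ddmax = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  co <- coef(fit)
  fitted <- isothermCurve(conc, co[["kd"]], co[["ddmax"]], model)
  res <- dd - fitted
  out <- list(KD = co[["kd"]], ddMax = co[["ddmax"]], model = model,
              rss = sum(res^2), residuals = res, fitted = fitted,
              conc = conc, n = length(conc), seed = as.integer(seed))
  if (nBoot > 0) {
    set.seed(seed)
    kb <- vapply(seq_len(nBoot), function(b) {
      db <- fitted + sample(res, replace = TRUE)
      fb <- tryCatch(minpack.lm::nlsLM(
        db ~ ddmax * conc^h / (kd^h + conc^h),
        data = data.frame(conc = conc, db = db, h = h),
        start = list(kd = co[["kd"]], ddmax = co[["ddmax"]]),
        lower = c(kd = 1e-12, ddmax = -Inf)),
        error = function(e) NULL)
      if (is.null(fb)) NA_real_ else coef(fb)[["kd"]]
    }, 0)
    out$KDci <- unname(quantile(kb, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(out, class = "uturnIsothermFit")
}

#' @export
print.uturnIsothermFit <- function(x, ...) {
  cat("Isotherm fit (", x$model, "): KD = ", sprintf("%.4g", x$KD),
      " mM, ddMax = ", sprintf("%.4g", x$ddMax), " ppm, rss = ",
      signif(x$rss, 4), " on ", x$n, " points\n", sep = "")
  if (!is.null(x$KDci))
    cat("  KD 95% bootstrap interval: [",
        sprintf("%.4g", x$KDci[1]), ", ", sprintf("%.4g", x$KDci[2]),
        "] mM\n", sep = "")
  invisible(x)
}

#' Compare single-site and cooperative two-ion isotherm fits
#'
#' Fits both models to the same series and reports their residual sums of
#' squares together with an F-ratio. The two models have the same number of
#' parameters (they differ only in the fixed Hill coefficient), so the
#' ratio is the plain residual-variance ratio
#' `F = (rss_single/df) / (rss_coop/df)`; values far above 1 favor the
#' cooperative model. No automatic verdict is made.
#'
#' @param series a [TitrationSeries-class] (at least 4 points).
#' @return a list of class `"uturnModelComparison"`: `fits` (both
#'   [fitBindingIsotherm()] results), `table` (`data.frame` of rss and
#'   parameters) and `Fratio`.
#' @export
compareModels <- function(series) {
  stopifnot(is(series, "TitrationSeries"))
  if (length(series@conc) < 4L)
    stop("insufficient points to compare models (need at least 4)")
  f1 <- fitBindingIsotherm(series, "single-site")
  f2 <- fitBindingIsotherm(series, "cooperative2")
  df <- length(series@conc) - 2L
  structure(list(
    fits = list(`single-site` = f1, cooperative2 = f2),
    table = data.frame(model = c("single-site", "cooperative2"),
                       KD = c(f1$KD, f2$KD), ddMax = c(f1$ddMax, f2$ddMax),
                       rss = c(f1$rss, f2$rss)),
    Fratio = (f1$rss / df) / (f2$rss / df)),
    class = "uturnModelComparison")
}

#' @export
print.uturnModelComparison <- function(x, ...) {
  print(x$table)
  cat("residual-variance ratio (single-site / cooperative2):",
      signif(x$Fratio, 4), "\n")
  invisible(x)
}
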