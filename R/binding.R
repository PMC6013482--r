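## Thermal-shift (differential scanning fluorimetry) analysis: melting
## temperatures from the smoothed first derivative of the melt curve, and
## a single-site saturation fit of the DeltaTm titration yielding an
## apparent ligand Kd.

#' Extract melting transitions from a melt curve
#'
#' The fluorescence trace is smoothed with a 5-point quadratic
#' (Savitzky-Golay) filter; transitions are local maxima of dF/dT above a
#' height threshold relative to the global maximum derivative. Positions
#' are refined by parabolic interpolation. When several transitions are
#' present the first (lowest-temperature) one is the canonical Tm.
#'
#' @param temperature Ascending temperature grid, degrees C.
#' @param fluorescence Fluorescence values (arbitrary units).
#' @param prominence Threshold on both peak height and topographic
#'   prominence, as a fraction of the maximum derivative (default 0.05).
#' @param window Savitzky-Golay smoothing window (odd; default 11,
#'   applied to the trace and again to its derivative).
#' @return Ascending numeric vector of transition temperatures.
#' @export
extract_tm <- function(temperature, fluorescence, prominence = 0.05,
                       window = 11) {
  stopifnot(length(temperature) == length(fluorescence))
  if (length(temperature) < 10) stop("melt curve needs at least 10 points")
  if (any(diff(temperature) <= 0)) stop("temperature must be ascending")
  f <- sg_smooth(fluorescence, window)
  dT <- diff(temperature)
  d <- sg_smooth(diff(f) / dT, window)   # smooth the derivative as well
  tm_grid <- temperature[-length(temperature)] + dT / 2
  dmax <- max(d)
  if (dmax <= 1e-10 * max(abs(fluorescence), 1))
    stop("no transition: melt curve has no rising region")
  n <- length(d)
  cand <- which(d > prominence * dmax &
                  d >= c(-Inf, d[-n]) &
                  d >= c(d[-1], -Inf))
  cand <- cand[c(TRUE, diff(cand) > 1)]
  # discard the half-window margins where smoothing is undefined
  margin <- (window + 1) %/% 2
  cand <- cand[cand > margin & cand <= n - margin]
  peaks <- cand[peak_prominence(d, cand) >= prominence * dmax]
  if (length(peaks) == 0) stop("no transition above the prominence threshold")
  tms <- vapply(peaks, function(p) {
    if (p <= 1 || p >= n) return(tm_grid[p])
    parabolic_peak(tm_grid[(p - 1):(p + 1)], d[(p - 1):(p + 1)])
  }, 0)
  sort(tms)
}

# Topographic prominence of each candidate local maximum: height above
# the higher of the two key saddles toward the nearest higher terrain.
peak_prominence <- function(y, idx) {
  vapply(idx, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1)]
    right <- if (p < length(y)) y[(p + 1):length(y)] else numeric(0)
    key <- function(side_rev) {
      # walk outward until terrain exceeds the peak; the key saddle is
      # the minimum on that path (no higher terrain: side unbounded)
      higher <- which(side_rev > h)
      if (length(higher) == 0 || higher[1] == 1) return(-Inf)
      min(side_rev[seq_len(higher[1] - 1)])
    }
    saddle <- max(key(rev(left)), key(right))
    if (!is.finite(saddle)) h - min(y) else h - saddle
  }, 0)
}

# Quadratic Savitzky-Golay smoothing with an odd window; the filter
# coefficients come from the closed-form least-squares projection.
# Endpoints where the window does not fit are kept as-is.
sg_smooth <- function(y, window = 5) {
  n <- length(y)
  window <- max(5, window - (1 - window %% 2))  # force odd, >= 5
  if (n < window) return(y)
  m <- (window - 1) / 2
  i <- -m:m
  coef <- (3 * (3 * m^2 + 3 * m - 1) - 15 * i^2) /
    ((2 * m + 3) * (2 * m + 1) * (2 * m - 1))
  sm <- as.numeric(stats::filter(y, coef, sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]
  sm
}

parabolic_peak <- function(x, y) {
  denom <- y[1] - 2 * y[2] + y[3]
  if (abs(denom) < 1e-12) return(x[2])
  x[2] + 0.5 * (y[1] - y[3]) / denom * (x[3] - x[2])
}

#' Fit a single-site Kd to a DeltaTm titration
#'
#' Weighted least-squares fit of the saturation hyperbola
#' `DeltaTm(L) = DeltaTm_max * L / (Kd + L)`. Standard errors come from
#' the fit covariance; a fit whose Kd standard error exceeds the Kd (or
#' that fails to converge) is flagged unreliable but still returned.
#'
#' @param conc Ligand concentrations (same unit as the returned Kd;
#'   must include 0 and at least 4 distinct positive values).
#' @param dTm Melting-temperature shifts, degrees C (`dTm` at `conc == 0`
#'   is 0 by construction and is not fitted).
#' @param sd Optional per-point standard deviations used as weights.
#' @return A `KdFit`: `Kd`, `Kd_se`, `dTm_max`, `dTm_max_se`,
#'   `residual_norm`, `unreliable`.
#' @export
fit_kd <- function(conc, dTm, sd = NULL) {
  stopifnot(length(conc) == length(dTm))
  if (!any(conc == 0)) stop("titration must include the 0 concentration")
  pos <- conc > 0
  if (length(unique(conc[pos])) < 4)
    stop("need at least 4 distinct nonzero concentrations")
  L <- conc[pos]; y <- dTm[pos]
  w <- if (is.null(sd)) rep(1, sum(pos)) else 1 / sd[pos]^2
  dat <- data.frame(L = L, y = y)
  start <- list(dmax = max(y, 0.1), kd = stats::median(L))
  fit <- tryCatch(
    stats::nls(y ~ dmax * L / (kd + L), data = dat, start = start,
               weights = w, algorithm = "port",
               lower = c(dmax = -Inf, kd = 1e-9),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate data (e.g. all-zero shifts): report the flat model
    return(structure(list(Kd = NA_real_, Kd_se = NA_real_,
                          dTm_max = mean(y), dTm_max_se = NA_real_,
                          residual_norm = sqrt(sum(w * (y - mean(y))^2)),
                          unreliable = TRUE),
                     class = "KdFit"))
  }
  co <- summary(fit)$coefficients
  kd <- co["kd", "Estimate"]; kd_se <- co["kd", "Std. Error"]
  dmax <- co["dmax", "Estimate"]; dmax_se <- co["dmax", "Std. Error"]
  unreliable <- !is.finite(kd_se) || kd_se > kd
  structure(list(Kd = kd, Kd_se = kd_se, dTm_max = dmax,
                 dTm_max_se = dmax_se,
                 residual_norm = sqrt(sum(w * stats::resid(fit)^2)),
                 unreliable = unreliable),
            class = "KdFit")
}

#' @export
print.KdFit <- function(x, ...) {
  cat(sprintf("KdFit: Kd %.1f +/- %.1f, dTm_max %.2f +/- %.2f C%s\n",
              x$Kd, x$Kd_se, x$dTm_max, x$dTm_max_se,
              if (isTRUE(x$unreliable)) " [unreliable]" else ""))
  invisible(x)
}

#' Build a DeltaTm titration series from melt curves
#'
#' Convenience wrapper: extracts the canonical (first-transition) Tm of
#' every condition and subtracts the ligand-free Tm.
#'
#' @param curves Data frame with columns `temperature`, `fluorescence`,
#'   `conc`, optionally `replicate`.
#' @return Data frame `conc`, `dTm`, `sd` (across replicates where
#'   available).
#' @export
titration_from_curves <- function(curves) {
  if (!"replicate" %in% names(curves)) curves$replicate <- 1
  grp <- split(curves, list(curves$conc, curves$replicate), drop = TRUE)
  tm <- do.call(rbind, lapply(grp, function(g) {
    data.frame(conc = g$conc[1], replicate = g$replicate[1],
               tm = extract_tm(g$temperature, g$fluorescence)[1])
  }))
  tm0 <- mean(tm$tm[tm$conc == 0])
  if (!is.finite(tm0)) stop("titration must include the 0 concentration")
  agg <- split(tm, tm$conc)
  out <- do.call(rbind, lapply(agg, function(g) {
    data.frame(conc = g$conc[1], dTm = mean(g$tm) - tm0,
               sd = if (nrow(g) > 1) stats::sd(g$tm) else NA_real_)
  }))
  rownames(out) <- NULL
  out[order(out$conc), ]
}
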