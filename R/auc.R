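## Sedimentation velocity: a finite-volume Lamm-equation forward model in
## sector geometry (Scharfetter-Gummel exponential flux discretization,
## Crank-Nicolson time stepping) and a regularized non-negative c(s)
## distribution fit with diffusion tied to s through a single frictional
## ratio. s20,w standardization follows the usual viscosity/buoyancy
## correction.

# Bernoulli function B(x) = x / (exp(x) - 1), series near 0.
bernoulli_fn <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2
  out[!small] <- x[!small] / expm1(x[!small])
  out
}

#' Default sedimentation-velocity experiment design
#'
#' Sector cell from 6.0 to 7.2 cm, 200 radial points, 30 scans over 3 h,
#' 50,000 rpm.
#' @export
sv_design <- function(meniscus = 6.0, base = 7.2, n_radii = 200,
                      n_scans = 30, total_time = 10800, rpm = 50000) {
  stopifnot(meniscus < base, n_radii >= 20, n_scans >= 2)
  list(r = seq(meniscus, base, length.out = n_radii),
       times = seq(total_time / n_scans, total_time, length.out = n_scans),
       omega = rpm * 2 * pi / 60, rpm = rpm)
}

# Crank-Nicolson propagator for one species over one time step dt.
lamm_propagator <- function(r, s, D, omega, dt, pe_max = 50) {
  n <- length(r)
  dr <- r[2] - r[1]
  rf <- (r[-n] + r[-1]) / 2          # faces
  v <- s * omega^2 * rf              # sedimentation velocity at faces
  pe <- v * dr / D
  if (max(abs(pe)) > pe_max)
    stop(sprintf(
      "grid too coarse: cell Peclet %.1f exceeds %g; refine the radial grid",
      max(abs(pe)), pe_max))
  bm <- bernoulli_fn(-pe)            # weight on inner cell
  bp <- bernoulli_fn(pe)             # weight on outer cell
  # flux at face f between cells i, i+1: J = (D/dr) (bm c_i - bp c_{i+1});
  # dc_i/dt = (r_{f,i-1} J_{i-1} - r_{f,i} J_i) / (r_i dr), no-flux ends.
  L <- matrix(0, n, n)
  cf <- D / dr^2
  for (i in seq_len(n)) {
    if (i < n) {   # outer face i
      L[i, i] <- L[i, i] - cf * rf[i] * bm[i] / r[i]
      L[i, i + 1] <- L[i, i + 1] + cf * rf[i] * bp[i] / r[i]
    }
    if (i > 1) {   # inner face i-1
      L[i, i - 1] <- L[i, i - 1] + cf * rf[i - 1] * bm[i - 1] / r[i]
      L[i, i] <- L[i, i] - cf * rf[i - 1] * bp[i - 1] / r[i]
    }
  }
  M1 <- diag(n) - dt / 2 * L
  M2 <- diag(n) + dt / 2 * L
  solve(M1, M2)
}

# Concentration profiles of one species at the scan times, unit loading.
# The propagator is cached per distinct time step.
lamm_profiles <- function(r, times, omega, s, D, dt_max = 20) {
  grid_t <- c(0, times)
  c_now <- rep(1, length(r))
  out <- matrix(0, length(times), length(r))
  cache <- list()
  for (k in seq_along(times)) {
    span <- grid_t[k + 1] - grid_t[k]
    nstep <- max(ceiling(span / dt_max), 1)
    dt <- span / nstep
    key <- sprintf("%.9g", dt)
    if (is.null(cache[[key]]))
      cache[[key]] <- lamm_propagator(r, s, D, omega, dt)
    P <- cache[[key]]
    for (j in seq_len(nstep)) c_now <- drop(P %*% c_now)
    out[k, ] <- c_now
  }
  out
}

#' Simulate a sedimentation-velocity experiment
#'
#' Solves the Lamm equation for each species by implicit finite
#' differences in sector geometry, sums the species, and adds Gaussian
#' noise. Loading is uniform at each species' signal.
#'
#' @param species Data frame with columns `s` (Svedberg), `D` (cm^2/s),
#'   `signal` (absorbance units).
#' @param design Experiment design from [sv_design()].
#' @param noise_sd Gaussian noise, AU (default 0).
#' @param seed RNG seed.
#' @return An `SVExperiment`: `r`, `times`, `omega`, `rpm`, `scans`
#'   (scans x radii matrix), `noise_sd`, `species`.
#' @export
simulate_sv <- function(species, design = sv_design(), noise_sd = 0,
                        seed = 1) {
  species <- as.data.frame(species)
  stopifnot(all(c("s", "D", "signal") %in% names(species)),
            all(species$s > 0), all(species$D > 0), all(species$signal > 0))
  A <- matrix(0, length(design$times), length(design$r))
  for (i in seq_len(nrow(species))) {
    prof <- lamm_profiles(design$r, design$times, design$omega,
                          species$s[i] * 1e-13, species$D[i])
    A <- A + species$signal[i] * prof
  }
  if (noise_sd > 0) {
    A <- with_seed(seed,
                   A + matrix(stats::rnorm(length(A), 0, noise_sd), nrow(A)))
  }
  structure(list(r = design$r, times = design$times, omega = design$omega,
                 rpm = design$rpm, scans = A, noise_sd = noise_sd,
                 species = species),
            class = "SVExperiment")
}

#' Diffusion coefficient from s via a frictional ratio
#'
#' The c(s) linkage: for a given sedimentation coefficient and a single
#' global frictional ratio f/f0,
#' `D(s) = sqrt(2)/(18 pi) kT (eta f/f0)^(-3/2) ((1 - vbar rho)/(vbar s))^(1/2)`.
#'
#' @param s Sedimentation coefficient, Svedberg.
#' @param ff0 Frictional ratio f/f0 (default 1.2).
#' @param vbar Partial specific volume, mL/g (default 0.73).
#' @param rho Solvent density, g/mL (default water at 20 C).
#' @param eta Solvent viscosity, cP (default water at 20 C).
#' @param temperature Kelvin (default 293.15).
#' @return Diffusion coefficient, cm^2/s.
#' @export
diffusion_from_s <- function(s, ff0 = 1.2, vbar = 0.73, rho = 0.99823,
                             eta = 1.002, temperature = 293.15) {
  kT <- 1.380649e-16 * temperature        # erg
  eta_p <- eta / 100                       # cP -> Poise
  s_sec <- s * 1e-13
  sqrt(2) / (18 * pi) * kT * (eta_p * ff0)^(-3 / 2) *
    sqrt((1 - vbar * rho) / (vbar * s_sec))
}

#' Fit a continuous c(s) distribution
#'
#' Non-negative least squares of the scan matrix onto unit-signal
#' single-species Lamm solutions on an s grid, with D(s) tied to s by a
#' single frictional ratio, Tikhonov-regularized on the second
#' difference. Peaks are local maxima refined by parabolic interpolation.
#'
#' @param e An `SVExperiment`.
#' @param s_grid Sedimentation-coefficient grid, Svedberg.
#' @param ff0 Frictional ratio (default 1.2).
#' @param alpha Dimensionless regularization strength (default 0.01).
#' @param vbar,rho,eta,temperature Solvent parameters for the D(s)
#'   linkage (defaults water at 20 C).
#' @param peak_min_frac Peaks below this fraction of the maximum c(s)
#'   are ignored (default 0.02).
#' @return A `CsDistribution`: `s`, `c` (signal per Svedberg), `alpha`,
#'   `ff0`, `peaks` (data frame `s`, `height`), `total_signal`, `rmsd`.
#' @export
fit_cs <- function(e, s_grid, ff0 = 1.2, alpha = 0.01, vbar = 0.73,
                   rho = 0.99823, eta = 1.002, temperature = 293.15,
                   peak_min_frac = 0.02) {
  stopifnot(inherits(e, "SVExperiment"))
  ns <- length(s_grid)
  if (ns < 5) stop("s grid too coarse")
  basis <- matrix(0, length(e$scans), ns)
  for (k in seq_len(ns)) {
    D <- diffusion_from_s(s_grid[k], ff0, vbar, rho, eta, temperature)
    prof <- lamm_profiles(e$r, e$times, e$omega, s_grid[k] * 1e-13, D)
    basis[, k] <- as.vector(prof)
  }
  b <- as.vector(e$scans)
  ds <- diff(s_grid[1:2])
  D2 <- diag(-2, ns)
  D2[cbind(1:(ns - 1), 2:ns)] <- 1
  D2[cbind(2:ns, 1:(ns - 1))] <- 1
  scale2 <- sum(basis^2) / sum(D2^2)
  Areg <- rbind(basis, sqrt(alpha * scale2) * D2)
  breg <- c(b, numeric(ns))
  w <- nnls_solve(Areg, breg)        # signal attributed to each grid point
  cs <- w / ds                       # density: signal per Svedberg
  fitted <- drop(basis %*% w)
  rmsd <- sqrt(mean((b - fitted)^2))
  peaks <- find_peaks(s_grid, cs, peak_min_frac)
  structure(list(s = s_grid, c = cs, alpha = alpha, ff0 = ff0,
                 peaks = peaks, total_signal = sum(w), rmsd = rmsd),
            class = "CsDistribution")
}

find_peaks <- function(x, y, min_frac = 0.02) {
  n <- length(y)
  if (max(y) <= 0)
    return(data.frame(s = numeric(0), height = numeric(0)))
  thr <- min_frac * max(y)
  idx <- which(y > thr &
                 y >= c(-Inf, y[-n]) &
                 y >= c(y[-1], -Inf))
  idx <- idx[c(TRUE, diff(idx) > 1)]
  pos <- vapply(idx, function(p) {
    if (p <= 1 || p >= n) return(x[p])
    parabolic_peak(x[(p - 1):(p + 1)], y[(p - 1):(p + 1)])
  }, 0)
  data.frame(s = pos, height = y[idx])
}

#' @export
print.CsDistribution <- function(x, ...) {
  cat(sprintf("CsDistribution: %d peaks (%s S), total signal %.3f\n",
              nrow(x$peaks),
              paste(sprintf("%.2f", x$peaks$s), collapse = ", "),
              x$total_signal))
  invisible(x)
}

#' Standardize a sedimentation coefficient to water at 20 C
#'
#' `s20w = s_obs (eta_b / eta_20w) (1 - vbar rho_20w) / (1 - vbar rho_b)`.
#'
#' @param s_obs Observed sedimentation coefficient (any unit).
#' @param vbar Partial specific volume, mL/g.
#' @param rho_b,eta_b Buffer density (g/mL) and viscosity (cP).
#' @param rho_w,eta_w Reference water values at 20 C.
#' @return Standardized s20,w in the unit of `s_obs`.
#' @export
standardize_s <- function(s_obs, vbar, rho_b, eta_b,
                          rho_w = 0.99823, eta_w = 1.002) {
  if (abs(1 - vbar * rho_b) < 1e-12)
    stop("neutral buoyancy: 1 - vbar * rho is zero")
  s_obs * (eta_b / eta_w) * (1 - vbar * rho_w) / (1 - vbar * rho_b)
}

#' Write / read a scan matrix as delimited text
#'
#' First column radius; one column per scan; header row of scan times.
#' @param e An `SVExperiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv <- function(e, path) {
  m <- cbind(e$r, t(e$scans))
  colnames(m) <- c("radius_cm", sprintf("t%.0f", e$times))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
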