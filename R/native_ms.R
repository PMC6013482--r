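## Native electrospray mass spectrometry: simulate multi-charge envelopes
## of intact complexes and recover neutral masses by consensus
## charge-state assignment over adjacent peak pairs.

PROTON_MASS <- 1.00728  # Da, positive-mode charge carrier

#' Simulate a native ESI charge envelope
#'
#' Peaks at `m/z = (M + z * 1.00728) / z` for each charge state, with
#' Gaussian m/z noise and a Gaussian intensity profile over z.
#'
#' @param mass Neutral mass, Da.
#' @param charges Integer charge states (e.g. `20:28`).
#' @param seed RNG seed.
#' @param mz_noise_sd Gaussian m/z perturbation, Thomson (default 0).
#' @param z_center,z_width Intensity profile over charge (defaults: mean
#'   of `charges`, quarter of the range).
#' @return A `ChargeEnvelope` data frame (`mz`, `intensity`), with the
#'   true charges in attribute `charges`.
#' @export
simulate_envelope <- function(mass, charges, seed = 1, mz_noise_sd = 0,
                              z_center = mean(charges),
                              z_width = max(diff(range(charges)) / 4, 1)) {
  stopifnot(mass > 0, length(charges) > 0, all(charges >= 1))
  with_seed(seed, {
    mz <- (mass + charges * PROTON_MASS) / charges +
      stats::rnorm(length(charges), 0, mz_noise_sd)
    intensity <- exp(-(charges - z_center)^2 / (2 * z_width^2))
    out <- data.frame(mz = mz, intensity = intensity)[order(mz), ]
    rownames(out) <- NULL
    attr(out, "charges") <- sort(charges, decreasing = TRUE)
    class(out) <- c("ChargeEnvelope", class(out))
    out
  })
}

#' Read a 2-column peak list (m/z, intensity)
#' @param path File path.
#' @return A `ChargeEnvelope`.
#' @export
read_peaklist <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("peak list needs 2 columns: mz, intensity")
  out <- data.frame(mz = tab[[1]], intensity = tab[[2]])
  if (any(out$mz <= 0)) stop("non-positive m/z in peak list")
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("ChargeEnvelope", class(out))
  out
}

#' Deconvolve a charge envelope into neutral-mass solutions
#'
#' For each adjacent peak pair (descending m/z, `x1 > x2`) the candidate
#' charge of the higher-m/z peak is `z = round((x2 - mp) / (x1 - x2))`;
#' per-peak masses `M = z (x - mp)` are pooled and clustered; consensus
#' solutions are ranked by supporting-peak count, then mass spread.
#'
#' @param e A `ChargeEnvelope`.
#' @param z_range Charge search range, e.g. `10:40`.
#' @param proton Charge-carrier mass, Da (default 1.00728).
#' @param cluster_width Mass-clustering width, Da (default
#'   `2e-4 * median estimate`).
#' @return List of `MassSolution`s, each with `mass` (Da), `charges`,
#'   `n_peaks`, `mass_sd` (Da), `residual_th` (mean per-peak m/z
#'   residual).
#' @export
deconvolve <- function(e, z_range, proton = PROTON_MASS,
                       cluster_width = NULL) {
  stopifnot(inherits(e, "ChargeEnvelope"))
  if (nrow(e) < 2)
    stop("ambiguous: a single peak cannot determine charge")
  mz <- sort(e$mz, decreasing = TRUE)
  est <- list()
  for (i in seq_len(length(mz) - 1)) {
    x1 <- mz[i]; x2 <- mz[i + 1]
    z <- round((x2 - proton) / (x1 - x2))
    # the pair assigns charge z to x1 and z+1 to x2
    for (off in 0:1) {
      zz <- z + off
      if (zz %in% z_range)
        est[[length(est) + 1]] <- c(mass = zz * (mz[i + off] - proton),
                                    z = zz, peak = i + off)
    }
  }
  if (length(est) == 0)
    stop("no solution: no adjacent-pair charge estimate inside z_range")
  est <- do.call(rbind, est)
  if (is.null(cluster_width)) cluster_width <- 2e-4 * stats::median(est[, "mass"])
  ord <- order(est[, "mass"])
  est <- est[ord, , drop = FALSE]
  grp <- cumsum(c(1, diff(est[, "mass"]) > cluster_width))
  sols <- lapply(split(seq_len(nrow(est)), grp), function(idx) {
    sub <- est[idx, , drop = FALSE]
    mass <- mean(sub[, "mass"])
    zz <- sort(unique(sub[, "z"]))
    # per-peak m/z residual at the consensus mass
    resid <- abs((mass + sub[, "z"] * proton) / sub[, "z"] -
                   mz[sub[, "peak"]])
    structure(list(mass = mass, charges = zz,
                   n_peaks = length(unique(sub[, "peak"])),
                   mass_sd = if (nrow(sub) > 1) stats::sd(sub[, "mass"]) else 0,
                   residual_th = mean(resid)),
              class = "MassSolution")
  })
  sols <- sols[vapply(sols, function(s) s$n_peaks, 0) >= 2]
  if (length(sols) == 0)
    stop("no solution: no mass supported by at least two peaks")
  ord <- order(-vapply(sols, function(s) s$n_peaks, 0),
               vapply(sols, function(s) s$mass_sd, 0))
  unname(sols[ord])
}

#' @export
print.MassSolution <- function(x, ...) {
  cat(sprintf("MassSolution: %.1f Da (z %d-%d, %d peaks, sd %.2f Da)\n",
              x$mass, min(x$charges), max(x$charges), x$n_peaks, x$mass_sd))
  invisible(x)
}

#' Annotate mass solutions with oligomer stoichiometry
#'
#' @param solutions List of `MassSolution`s (or numeric masses).
#' @param monomer_mass Monomer mass, Da.
#' @return Data frame: `mass`, `n` (nearest oligomer number), `ppm`
#'   deviation from `n * monomer_mass`.
#' @export
species_report <- function(solutions, monomer_mass) {
  stopifnot(monomer_mass > 0)
  masses <- vapply(solutions, function(s)
    if (is.list(s)) s$mass else as.numeric(s), 0)
  n <- pmax(round(masses / monomer_mass), 1)
  ppm <- (masses - n * monomer_mass) / (n * monomer_mass) * 1e6
  data.frame(mass = masses, n = as.integer(n), ppm = ppm)
}
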