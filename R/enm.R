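## Anisotropic elastic-network model (ANM) and the iterative
## eigenvector-tracking procedure that drives one domain onto another.
##
## The network places a harmonic spring of uniform stiffness gamma between
## every Calpha pair closer than the cutoff. The Hessian is built from the
## standard ANM super-elements; six rigid-body modes are discarded after
## checking they are numerically zero, which doubles as a connectivity
## check.

#' Build an anisotropic network model from a Calpha model
#'
#' @param m A `CalphaModel`.
#' @param cutoff Interaction cutoff in angstrom (default 15).
#' @param gamma Uniform spring constant (energy / angstrom^2; default 1).
#' @return An `ENModel`: list with the source model, parameters, the
#'   3N x 3N Hessian, and the contact pair list.
#' @export
build_enm <- function(m, cutoff = 15, gamma = 1) {
  stopifnot(inherits(m, "CalphaModel"), cutoff > 0, gamma > 0)
  xyz <- m$xyz
  n <- nrow(xyz)
  dm <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dm) & dm <= cutoff & dm > 0, arr.ind = TRUE)
  comp <- connected_components(n, pairs)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop(sprintf(
      "disconnected network at cutoff %.1f A: %d components (sizes %s)",
      cutoff, max(comp), paste(as.integer(sizes), collapse = ", ")))
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    dv <- xyz[j, ] - xyz[i, ]
    S <- gamma * tcrossprod(dv) / sum(dv^2)
    bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
    H[bi, bj] <- H[bi, bj] - S
    H[bj, bi] <- H[bj, bi] - S
    H[bi, bi] <- H[bi, bi] + S
    H[bj, bj] <- H[bj, bj] + S
  }
  structure(list(model = m, cutoff = cutoff, gamma = gamma, hessian = H,
                 pairs = pairs),
            class = "ENModel")
}

connected_components <- function(n, pairs) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Normal modes of an elastic network
#'
#' Full symmetric eigendecomposition of the Hessian; eigenvalues are
#' returned ascending with the six rigid-body modes removed. An
#' unexpectedly small seventh eigenvalue signals a disconnected network.
#'
#' @param e An `ENModel`.
#' @param n_modes Number of non-rigid modes to keep (default 20).
#' @param rigid_tol Relative tolerance below which an eigenvalue counts
#'   as rigid (default `1e-12` times the largest eigenvalue; numerical
#'   zeros sit below 1e-14 while thin-linker soft modes can reach 1e-8,
#'   so the threshold separates the two populations).
#' @return A `ModeSet`: `values` (ascending), `vectors` (3N x k, unit
#'   norm), `n_discarded` (always 6 for a connected network).
#' @export
normal_modes <- function(e, n_modes = 20, rigid_tol = 1e-12) {
  stopifnot(inherits(e, "ENModel"))
  stopifnot_finite(e$hessian, "Hessian")
  ee <- eigen(e$hessian, symmetric = TRUE)
  vals <- rev(ee$values)
  vecs <- ee$vectors[, rev(seq_along(ee$values)), drop = FALSE]
  lam_max <- max(vals)
  thr <- rigid_tol * lam_max
  if (any(vals[1:6] > thr))
    stop("fewer than 6 numerically-zero modes; Hessian is inconsistent")
  if (length(vals) > 6 && vals[7] <= thr)
    stop("disconnected network: 7th eigenvalue is numerically zero")
  keep <- 7:min(6 + n_modes, length(vals))
  structure(list(values = pmax(vals[keep], 0),
                 vectors = vecs[, keep, drop = FALSE],
                 n_discarded = 6L),
            class = "ModeSet")
}

#' Overlap between two normal-mode eigenvectors
#'
#' Absolute cosine similarity, the standard sign-free measure used to
#' follow "the same" collective motion across changing geometries.
#'
#' @param v1,v2 Vectors of equal length.
#' @return Scalar in \[0, 1\].
#' @export
mode_overlap <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("eigenvectors differ in dimension")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector passed to mode_overlap")
  min(abs(sum(v1 * v2)) / (n1 * n2), 1)
}

# Pseudo-energy used for post-displacement relaxation: harmonic terms on
# sequential Calpha-Calpha distances of the topology reference plus a
# quadratic soft-sphere repulsion below `rep_cut` between non-bonded pairs.
relax_energy_grad <- function(x, bonds, d0, rep_cut = 4) {
  n <- length(x) / 3
  xyz <- matrix(x, n, 3, byrow = FALSE)
  g <- matrix(0, n, 3)
  dv <- xyz[bonds[, 2], , drop = FALSE] - xyz[bonds[, 1], , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  e <- sum((d - d0)^2)
  coef <- 2 * (d - d0) / pmax(d, 1e-8)
  gb <- dv * coef
  for (k in seq_len(nrow(bonds))) {
    g[bonds[k, 1], ] <- g[bonds[k, 1], ] - gb[k, ]
    g[bonds[k, 2], ] <- g[bonds[k, 2], ] + gb[k, ]
  }
  dm <- as.matrix(stats::dist(xyz))
  close_ <- which(upper.tri(dm) & dm < rep_cut, arr.ind = TRUE)
  if (nrow(close_) > 0) {
    bonded_key <- paste(bonds[, 1], bonds[, 2])
    keyf <- paste(close_[, 1], close_[, 2])
    keyr <- paste(close_[, 2], close_[, 1])
    close_ <- close_[!(keyf %in% bonded_key) & !(keyr %in% bonded_key), ,
                     drop = FALSE]
  }
  if (nrow(close_) > 0) {
    for (k in seq_len(nrow(close_))) {
      i <- close_[k, 1]; j <- close_[k, 2]
      r <- max(dm[i, j], 1e-8)
      e <- e + (rep_cut - r)^2
      gr <- -2 * (rep_cut - r) / r * (xyz[j, ] - xyz[i, ])
      g[i, ] <- g[i, ] - gr
      g[j, ] <- g[j, ] + gr
    }
  }
  list(e = e, g = as.vector(g))
}

sequential_bonds <- function(m) {
  n <- nrow(m$xyz)
  i <- seq_len(n - 1)
  same <- m$chain[i] == m$chain[i + 1]
  cbind(i[same], i[same] + 1L)
}

#' Displace a model along a mode and relax the geometry
#'
#' Coordinates move by `amplitude * mode`, then a Calpha-level relaxation
#' restores the sequential bond lengths of the topology reference under a
#' soft-sphere repulsion. This stands in for all-atom minimization at the
#' resolution of the network model.
#'
#' @param m Model to displace.
#' @param mode 3N displacement vector (need not be unit norm; the caller
#'   fixes the overall amplitude).
#' @param amplitude Displacement scale in angstrom applied to `mode`.
#' @param topology Reference `CalphaModel` supplying target bond lengths
#'   (default `m` itself).
#' @param relax_steps Maximum relaxation iterations (default 200).
#' @return The displaced+relaxed `CalphaModel`, with attribute
#'   `max_drift` (largest per-residue movement during relaxation, angstrom).
#' @export
displace_and_relax <- function(m, mode, amplitude, topology = m,
                               relax_steps = 200) {
  stopifnot(inherits(m, "CalphaModel"), amplitude >= 0)
  n <- nrow(m$xyz)
  if (length(mode) != 3 * n) stop("mode length must be 3N")
  disp <- matrix(mode, n, 3, byrow = TRUE)
  xyz1 <- m$xyz + amplitude * disp
  bonds <- sequential_bonds(topology)
  d0 <- sqrt(rowSums((topology$xyz[bonds[, 2], , drop = FALSE] -
                        topology$xyz[bonds[, 1], , drop = FALSE])^2))
  x0 <- as.vector(xyz1)
  e0 <- relax_energy_grad(x0, bonds, d0)$e
  opt <- stats::optim(
    x0,
    fn = function(x) relax_energy_grad(x, bonds, d0)$e,
    gr = function(x) relax_energy_grad(x, bonds, d0)$g,
    method = "L-BFGS-B",
    control = list(maxit = relax_steps, factr = 1e5))
  if (opt$value > e0 + 1e-8)
    stop("relaxation divergence: pseudo-energy increased")
  xyz2 <- matrix(opt$par, n, 3)
  out <- m
  out$xyz <- xyz2
  attr(out, "max_drift") <- max(sqrt(rowSums((xyz2 - xyz1)^2)))
  out
}

# Mode vector as N x 3 matrix.
mode_as_matrix <- function(mode, n) matrix(mode, n, 3, byrow = TRUE)

# Sign of a mode displacement chosen so domain centroids approach.
closure_sign <- function(m, mode, ia, ib, amplitude) {
  n <- nrow(m$xyz)
  dm3 <- mode_as_matrix(mode, n)
  cd <- function(s) {
    xyz <- m$xyz + s * amplitude * dm3
    sqrt(sum((colMeans(xyz[ia, , drop = FALSE]) -
                colMeans(xyz[ib, , drop = FALSE]))^2))
  }
  if (cd(1) <= cd(-1)) 1 else -1
}

#' Track the lowest-frequency closure mode until two domains touch
#'
#' Iterative conformational-transition search: at the first iteration the
#' lowest-frequency non-rigid mode whose displacement (in the
#' centroid-approaching sign) reduces the minimum inter-domain distance
#' is selected and recorded as the reference eigenvector. Each subsequent
#' iteration rebuilds the network on the relaxed geometry, selects the
#' non-rigid mode with the largest overlap with the reference, displaces,
#' and relaxes. The loop ends at Calpha-Calpha contact or at the
#' iteration cap.
#'
#' @param start Starting `CalphaModel`, domains labelled.
#' @param labelA,labelB The two domain labels to close.
#' @param cutoff,gamma Network parameters (see [build_enm()]).
#' @param step Maximum per-residue displacement per iteration, angstrom
#'   (default 0.5; keeps each step inside the harmonic regime).
#' @param contact Contact threshold on the minimum inter-domain
#'   Calpha-Calpha distance, angstrom (default 8).
#' @param max_iter Iteration cap (default 500); hitting it is reported as
#'   `converged = FALSE`, not an error.
#' @param n_modes Candidate modes evaluated per iteration (default 10).
#' @param rigid_tol Rigid-mode tolerance (see [normal_modes()]).
#' @return A `TrackingResult`: `trace` data frame (iteration, mode index,
#'   overlap with the reference eigenvector, amplitude, minimum
#'   inter-domain distance), `final` model, `converged` flag,
#'   `reference_mode` vector.
#' @export
track_closure <- function(start, labelA, labelB, cutoff = 15, gamma = 1,
                          step = 0.5, contact = 8, max_iter = 500,
                          n_modes = 10, rigid_tol = 1e-12) {
  stopifnot(inherits(start, "CalphaModel"))
  ia <- which(start$domain == labelA)
  ib <- which(start$domain == labelB)
  if (length(ia) == 0 || length(ib) == 0)
    stop("both domain labels must be present")
  d_min <- min_interdomain_distance(start, labelA, labelB)
  trace <- data.frame(iteration = integer(0), mode = integer(0),
                      overlap = numeric(0), amplitude = numeric(0),
                      min_distance = numeric(0))
  if (d_min <= contact) {
    return(structure(list(trace = trace, final = start, converged = TRUE,
                          reference_mode = NULL, start_distance = d_min),
                     class = "TrackingResult"))
  }
  m <- start
  ref <- NULL
  converged <- FALSE
  n <- nrow(start$xyz)
  for (it in seq_len(max_iter)) {
    ms <- normal_modes(build_enm(m, cutoff, gamma), n_modes = n_modes,
                       rigid_tol = rigid_tol)
    k <- ncol(ms$vectors)
    if (is.null(ref)) {
      order_idx <- seq_len(k)             # ascending frequency
    } else {
      ov <- vapply(seq_len(k),
                   function(j) mode_overlap(ms$vectors[, j], ref), 0)
      order_idx <- order(ov, decreasing = TRUE)  # best-tracking first
    }
    advanced <- FALSE
    for (j in order_idx) {
      vec <- ms$vectors[, j]
      amp <- step / max(sqrt(rowSums(mode_as_matrix(vec, n)^2)))
      s <- closure_sign(m, vec, ia, ib, amp)
      cand <- displace_and_relax(m, s * vec, amp, topology = start)
      nd <- min_interdomain_distance(cand, labelA, labelB)
      if (nd > d_min) {
        # centroid proxy failed; the opposite sign may still close the gap
        cand2 <- displace_and_relax(m, -s * vec, amp, topology = start)
        nd2 <- min_interdomain_distance(cand2, labelA, labelB)
        if (nd2 < nd) { cand <- cand2; nd <- nd2 }
      }
      if (nd <= d_min) {
        ovl <- if (is.null(ref)) 1 else mode_overlap(vec, ref)
        if (is.null(ref)) ref <- s * vec
        trace <- rbind(trace, data.frame(
          iteration = it, mode = j, overlap = ovl, amplitude = amp,
          min_distance = nd))
        m <- cand
        d_min <- nd
        advanced <- TRUE
        break
      }
    }
    if (!advanced) {
      if (is.null(ref))
        stop("stalled trajectory: no mode reduces the inter-domain distance")
      break   # no candidate mode advances: report non-convergence
    }
    if (d_min <= contact) { converged <- TRUE; break }
  }
  structure(list(trace = trace, final = m, converged = converged,
                 reference_mode = ref,
                 start_distance = min_interdomain_distance(start, labelA,
                                                           labelB)),
            class = "TrackingResult")
}

#' @export
print.TrackingResult <- function(x, ...) {
  cat(sprintf(
    "TrackingResult: %d iterations, %s, final min inter-domain %.2f A\n",
    nrow(x$trace), if (x$converged) "converged" else "not converged",
    if (nrow(x$trace) > 0) x$trace$min_distance[nrow(x$trace)]
    else x$start_distance))
  invisible(x)
}

#' Residue-residue contact list between two domains
#'
#' @param m A `CalphaModel`.
#' @param labelA,labelB Domain labels.
#' @param cutoff Contact cutoff in angstrom (default 8).
#' @return Data frame of contacting residue pairs and distances.
#' @export
domain_contacts <- function(m, labelA, labelB, cutoff = 8) {
  ia <- which(m$domain == labelA); ib <- which(m$domain == labelB)
  d <- cross_distance(m$xyz[ia, , drop = FALSE], m$xyz[ib, , drop = FALSE])
  hit <- which(d <= cutoff, arr.ind = TRUE)
  data.frame(resA = m$resno[ia][hit[, 1]], resB = m$resno[ib][hit[, 2]],
             distance = d[hit])
}
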