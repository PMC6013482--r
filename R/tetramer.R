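## C4-symmetric rigid-body tetramer modelling against a SAXS curve with
## inter-protomer distance restraints. One protomer pose — three Euler
## angles plus a radial offset from the 4-fold (z) axis — parameterizes
## the whole assembly; azimuth and axial translation are gauge freedoms
## of the scattering problem and are pinned to zero.

#' Build a C4 assembly from one protomer pose
#'
#' The protomer is rotated by z-y-z Euler angles, translated by `rho`
#' along +x, then replicated by 90-degree rotations about z. Chains are
#' labelled A-D.
#'
#' @param protomer A `CalphaModel`.
#' @param pose List with `angles` (3 Euler angles, radians) and `rho`
#'   (radial offset, angstrom).
#' @return List of four `CalphaModel` protomers.
#' @export
assemble_c4 <- function(protomer, pose) {
  stopifnot(inherits(protomer, "CalphaModel"))
  stopifnot(length(pose$angles) == 3, pose$rho >= 0)
  R0 <- euler_zyz(pose$angles[1], pose$angles[2], pose$angles[3])
  base <- protomer
  base$xyz <- protomer$xyz %*% t(R0)
  base$xyz[, 1] <- base$xyz[, 1] + pose$rho
  chains <- c("A", "B", "C", "D")
  lapply(0:3, function(k) {
    p <- base
    p$xyz <- base$xyz %*% t(rot_z(k * pi / 2))
    p$chain <- rep(chains[k + 1], length(p$chain))
    p
  })
}

assembly_xyz <- function(assembly) do.call(rbind, lapply(assembly, `[[`, "xyz"))

# Distance between copies of `resno` in adjacent protomers (equal for all
# neighbouring pairs by C4 symmetry).
homotypic_distances <- function(assembly, resno) {
  p1 <- assembly[[1]]; p2 <- assembly[[2]]
  vapply(resno, function(r) {
    k <- match(r, p1$resno)
    if (is.na(k)) stop("restraint residue not in protomer: ", r)
    sqrt(sum((p1$xyz[k, ] - p2$xyz[k, ])^2))
  }, 0)
}

# Inter-protomer clash penalty: quadratic below `cut` angstrom between
# Calpha atoms of adjacent and opposite protomers.
clash_penalty <- function(assembly, cut = 3) {
  pen <- 0
  for (a in 1:3) for (b in (a + 1):4) {
    d <- cross_distance(assembly[[a]]$xyz, assembly[[b]]$xyz)
    v <- d[d < cut]
    if (length(v) > 0) pen <- pen + sum((cut - v)^2)
  }
  pen
}

#' Restraint specification for tetramer modelling
#'
#' @param residues Homotypic restraint residues (default `c(157, 173, 305)`,
#'   the brace and pseudokinase-domain lysines crosslinked between
#'   neighbouring protomers).
#' @param bound Rigid-body upper bound, angstrom (default 35).
#' @param target Refinement harmonic target distance, angstrom (default 30).
#' @param k Harmonic force constant, energy units / angstrom^2 (default 10).
#' @return A `RestraintSpec` list.
#' @export
restraint_spec <- function(residues = c(157, 173, 305), bound = 35,
                           target = 30, k = 10) {
  stopifnot(bound > 0, target > 0, k >= 0)
  structure(list(residues = residues, bound = bound, target = target, k = k),
            class = "RestraintSpec")
}

tetramer_objective <- function(pose_vec, protomer, data, restraints,
                               w_restraint = 10, w_clash = 10) {
  pose <- list(angles = pose_vec[1:3], rho = max(pose_vec[4], 0))
  asm <- assemble_c4(protomer, pose)
  curve <- debye_scatter(assembly_xyz(asm), data$q)
  chi <- chi_fit(curve, data)$chi
  d <- homotypic_distances(asm, restraints$residues)
  pen <- sum(pmax(d - restraints$bound, 0)^2)
  chi^2 + w_restraint * pen + w_clash * clash_penalty(asm)
}

#' Rigid-body fit of a C4 tetramer to a SAXS curve
#'
#' Simulated-annealing minimization over the 4-parameter pose of
#' `chi^2 + w * sum(max(0, d - bound)^2) + w_clash * overlaps`, where `d`
#' are the homotypic inter-protomer restraint distances. Deterministic
#' given the seed.
#'
#' @param protomer A `CalphaModel`.
#' @param data Target `SAXSCurve`.
#' @param restraints A `RestraintSpec`.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param steps Annealing steps (default 400).
#' @param t0,tf Initial / final temperatures of the geometric schedule.
#' @param rot_step Maximum Euler-angle proposal, degrees (default 5).
#' @param rho_step Maximum radial-offset proposal, angstrom (default 2).
#' @param rho_init Initial radial offset (default: protomer Rg times 1.5).
#' @param w_restraint,w_clash Penalty weights.
#' @return A `TetramerModel`: `protomer`, `pose`, `assembly`, `chi`,
#'   `scale`, `restraint_distances`, `objective`, `trace`, `seed`.
#' @export
rigid_body_fit <- function(protomer, data, restraints = restraint_spec(),
                           seed, steps = 400, t0 = 2, tf = 0.005,
                           rot_step = 5, rho_step = 2, rho_init = NULL,
                           w_restraint = 10, w_clash = 10) {
  stopifnot(inherits(protomer, "CalphaModel"), inherits(data, "SAXSCurve"))
  if (missing(seed)) stop("rigid_body_fit requires an explicit seed")
  rho0 <- rho_init %||% (1.5 * coord_rg(protomer))
  obj <- function(p) tetramer_objective(p, protomer, data, restraints,
                                        w_restraint, w_clash)
  rot_rad <- rot_step * pi / 180
  with_seed(seed, {
    cur <- c(stats::runif(3, -pi, pi), rho0)
    cur_e <- obj(cur)
    best <- cur; best_e <- cur_e
    trace <- numeric(steps)
    accepted <- 0L
    cool <- (tf / t0)^(1 / max(steps - 1, 1))
    temp <- t0
    for (s in seq_len(steps)) {
      prop <- cur + c(stats::runif(3, -rot_rad, rot_rad),
                      stats::runif(1, -rho_step, rho_step))
      prop[4] <- abs(prop[4])
      e <- obj(prop)
      if (e < cur_e || stats::runif(1) < exp((cur_e - e) / temp)) {
        cur <- prop; cur_e <- e
        accepted <- accepted + 1L
        if (e < best_e) { best <- prop; best_e <- e }
      }
      trace[s] <- best_e
      temp <- temp * cool
    }
    if (accepted == 0L)
      warning("annealing stall: no proposal accepted; returning start pose")
    pose <- list(angles = best[1:3], rho = best[4])
    asm <- assemble_c4(protomer, pose)
    fit <- chi_fit(debye_scatter(assembly_xyz(asm), data$q), data)
    structure(list(protomer = protomer, pose = pose, assembly = asm,
                   chi = fit$chi, scale = fit$scale,
                   restraint_distances = homotypic_distances(
                     asm, restraints$residues),
                   objective = best_e, trace = trace, seed = seed),
              class = "TetramerModel")
  })
}

#' @export
print.TetramerModel <- function(x, ...) {
  cat(sprintf(
    "TetramerModel: chi %.3f, rho %.1f A, restraint distances %s A\n",
    x$chi, x$pose$rho,
    paste(sprintf("%.1f", x$restraint_distances), collapse = "/")))
  invisible(x)
}

#' Restrained local refinement of a tetramer pose
#'
#' Local (Nelder-Mead) optimization of the pose under harmonic wells
#' `k (d - target)^2` on the homotypic restraint pairs plus the clash
#' term; C4 symmetry is preserved by construction. Restraint energies
#' before and after are reported.
#'
#' @param t A `TetramerModel`.
#' @param spec A `RestraintSpec` (its `target` and `k` drive refinement).
#' @param w_clash Clash weight (default 10).
#' @param maxit Optimizer iteration cap (default 300).
#' @return The refined `TetramerModel`, with attribute `energies`
#'   (named before/after restraint energies).
#' @export
refine_restrained <- function(t, spec = restraint_spec(), w_clash = 10,
                              maxit = 300) {
  stopifnot(inherits(t, "TetramerModel"))
  energy <- function(p) {
    pose <- list(angles = p[1:3], rho = max(p[4], 0))
    asm <- assemble_c4(t$protomer, pose)
    d <- homotypic_distances(asm, spec$residues)
    spec$k * sum((d - spec$target)^2) + w_clash * clash_penalty(asm)
  }
  p0 <- c(t$pose$angles, t$pose$rho)
  e0 <- energy(p0)
  opt <- stats::optim(p0, energy, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  # keep the incoming pose unless the optimizer strictly improves on it
  p1 <- if (opt$value < e0 - 1e-12) opt$par else p0
  pose <- list(angles = p1[1:3], rho = max(p1[4], 0))
  asm <- assemble_c4(t$protomer, pose)
  out <- t
  out$pose <- pose
  out$assembly <- asm
  out$restraint_distances <- homotypic_distances(asm, spec$residues)
  attr(out, "energies") <- c(before = e0, after = min(opt$value, e0))
  out
}

#' Write a C4 assembly as a 4-chain PDB file
#'
#' @param assembly List of protomers from [assemble_c4()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  structs <- lapply(assembly, calpha_to_structure)
  atoms <- do.call(rbind, lapply(structs, function(s) s$atoms))
  write_structure(new_structure(atoms), path)
}
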