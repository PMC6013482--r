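## Seeded synthetic-data generators. Each generator has a controllable
## ground truth and, when writing files, serializes that truth as a
## key=value sidecar next to the artifact, so tests compare recovered
## values against recorded — never re-derived — truth.

#' Write / read a key=value ground-truth sidecar
#'
#' @param truth Named list of scalars or numeric vectors.
#' @param path Sidecar path (conventionally `<artifact>.truth`).
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(truth, path) {
  lines <- vapply(names(truth), function(k) {
    v <- truth[[k]]
    sprintf("%s=%s", k, paste(format(v, digits = 15, trim = TRUE),
                              collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sidecar
#' @export
read_sidecar <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines[nzchar(lines)]) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    vals <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[kv[1]]] <- if (all(is.finite(num))) num else vals
  }
  out
}

# Idealized alpha-helix Calpha trace: 1.5 A rise and 100-degree turn per
# residue at 2.3 A radius, axis along +x starting at `origin`.
helix_trace <- function(n, origin = c(0, 0, 0), phase = 0, direction = 1) {
  i <- seq_len(n) - 1
  theta <- phase + direction * i * 100 * pi / 180
  cbind(origin[1] + direction * i * 1.5,
        origin[2] + 2.3 * cos(theta),
        origin[3] + 2.3 * sin(theta))
}

#' Compact helical-bundle toy protomer
#'
#' `n_helices` idealized antiparallel helices packed side by side; a
#' globular stand-in for a folded domain at Calpha resolution.
#'
#' @param n_res Total residue count (split evenly across helices).
#' @param n_helices Number of helices (default 3).
#' @param spacing Inter-helix packing distance, angstrom (default 10).
#' @param seed Seed for the small coordinate jitter.
#' @param jitter Gaussian coordinate jitter, angstrom (default 0.02).
#' @return A `CalphaModel`.
#' @export
make_helix_bundle <- function(n_res = 60, n_helices = 3, spacing = 10,
                              seed = 1, jitter = 0.02) {
  per <- floor(n_res / n_helices)
  counts <- rep(per, n_helices)
  counts[n_helices] <- n_res - per * (n_helices - 1)
  xyz <- NULL
  for (h in seq_len(n_helices)) {
    dirn <- if (h %% 2 == 1) 1 else -1
    x0 <- if (dirn == 1) 0 else (counts[h] - 1) * 1.5
    org <- c(x0, (h - 1) * spacing, 0)
    xyz <- rbind(xyz, helix_trace(counts[h], org, phase = h, direction = dirn))
  }
  xyz <- with_seed(seed, xyz + matrix(stats::rnorm(length(xyz), 0, jitter),
                                      nrow(xyz)))
  calpha_model(xyz, resno = seq_len(n_res), chain = "A", domain = "bundle")
}

#' Two-domain dumbbell toy model
#'
#' Two helical lobes on a common axis joined by an extended linker; the
#' standard fixture for the domain-closure tracker. `separation` asks for
#' the minimum inter-lobe Calpha distance; because the linker chain must
#' remain connected, the realizable gap is capped at `3.85 * (linker + 1)`
#' angstrom and the generator uses the smaller of the two (the default
#' scenario lands within 2 angstrom of the request).
#'
#' @param nA,nB Residues per lobe (at least 10).
#' @param linker Linker residue count (default 5).
#' @param separation Requested inter-lobe gap, angstrom (default 25).
#' @param seed Seed for the coordinate jitter.
#' @param jitter Gaussian jitter, angstrom (default 0.01; kept small so
#'   sequential bonds stay within 3.8 +/- 0.1 angstrom by construction).
#' @return A `CalphaModel` with domains `A`, `linker`, `B`.
#' @export
make_two_domain_toy <- function(nA = 30, nB = 30, linker = 5,
                                separation = 25, seed = 1, jitter = 0.01) {
  stopifnot(nA >= 10, nB >= 10, linker >= 1)
  if (separation < 4.6)
    stop("separation smaller than the lobe radii sum (4.6 A)")
  gap <- min(separation, 3.85 * (linker + 1))
  lobeA <- helix_trace(nA, origin = c(-(nA - 1) * 1.5, 0, 0), phase = 0)
  endA <- lobeA[nA, ]
  # B starts `gap` beyond A's terminal residue, same helical phase/offset
  startB <- endA + c(gap, 0, 0)
  thetaB0 <- (nA - 1 + 0) * 100 * pi / 180
  lobeB <- helix_trace(nB, origin = c(startB[1], 0, 0), phase = thetaB0)
  # match B's first-residue (y, z) to A's last so the gap is exactly axial
  lobeB[, 2] <- lobeB[, 2] - lobeB[1, 2] + endA[2]
  lobeB[, 3] <- lobeB[, 3] - lobeB[1, 3] + endA[3]
  frac <- seq_len(linker) / (linker + 1)
  # small helical wiggle: a perfectly collinear strand would give the
  # elastic network spurious zero-energy perpendicular modes
  link <- cbind(endA[1] + frac * gap,
                endA[2] + 0.25 * cos(seq_len(linker) * 2.1),
                endA[3] + 0.25 * sin(seq_len(linker) * 2.1))
  xyz <- rbind(lobeA, link, lobeB)
  xyz <- with_seed(seed, xyz + matrix(stats::rnorm(length(xyz), 0, jitter),
                                      nrow(xyz)))
  calpha_model(xyz, resno = seq_len(nA + linker + nB), chain = "A",
               domain = c(rep("A", nA), rep("linker", linker),
                          rep("B", nB)))
}

#' Synthetic crosslink table with a controlled satisfaction rate
#'
#' Samples residue pairs from the model (or assembly) whose distances lie
#' inside or outside the linker bound so that exactly
#' `round(fraction * n_links)` links are satisfied; residues are assigned
#' chemistry-compatible amino-acid letters, one letter per residue across
#' the whole table.
#'
#' @param m A `CalphaModel` or list of protomers.
#' @param n_links Number of links.
#' @param fraction Satisfied fraction in \[0, 1\].
#' @param linkers Linker types to draw from (default `"DSS"`).
#' @param seed RNG seed.
#' @param margin Distance margin kept away from the bound, angstrom
#'   (default 1).
#' @param path Optional output path; when given, the table and a truth
#'   sidecar are written.
#' @return Data frame `residueA`, `residueB`, `linker`, `score`, `count`,
#'   with attribute `truth` (per-link ground-truth verdicts).
#' @export
make_crosslink_set <- function(m, n_links = 20, fraction = 1,
                               linkers = "DSS", seed = 1, margin = 1,
                               path = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  assembly <- if (inherits(m, "CalphaModel")) list(m) else m
  bounds <- default_linker_bounds()
  n_sat <- round(fraction * n_links)
  with_seed(seed, {
    resno <- assembly[[1]]$resno
    # minimal inter/intra distance per residue pair across assignments
    pool <- expand.grid(a = resno, b = resno)
    pool <- pool[pool$a < pool$b, ]
    dmin <- vapply(seq_len(nrow(pool)), function(i) {
      best <- Inf
      for (p in assembly) for (q in assembly) {
        ka <- match(pool$a[i], p$resno); kb <- match(pool$b[i], q$resno)
        d <- sqrt(sum((p$xyz[ka, ] - q$xyz[kb, ])^2))
        if (d < best) best <- d
      }
      best
    }, 0)
    aa_map <- setNames(rep(NA_character_, length(resno)),
                       as.character(resno))
    assign_pair <- function(ra, rb, linker) {
      chem <- XL_CHEMISTRY[[linker]]
      for (cand in list(c(chem$sideA[1], chem$sideB[1]),
                        c(chem$sideB[1], chem$sideA[1]))) {
        okA <- is.na(aa_map[as.character(ra)]) ||
          aa_map[as.character(ra)] == cand[1]
        okB <- is.na(aa_map[as.character(rb)]) ||
          aa_map[as.character(rb)] == cand[2]
        if (okA && okB) {
          aa_map[as.character(ra)] <<- cand[1]
          aa_map[as.character(rb)] <<- cand[2]
          return(TRUE)
        }
      }
      FALSE
    }
    rows <- list()
    linker_seq <- rep_len(linkers, n_links)
    want_sat <- c(rep(TRUE, n_sat), rep(FALSE, n_links - n_sat))
    ord <- sample(nrow(pool))
    used <- logical(nrow(pool))
    for (i in seq_len(n_links)) {
      bound <- bounds[linker_seq[i]]
      cand <- ord[!used[ord] &
                    (if (want_sat[i]) dmin[ord] <= bound - margin
                     else dmin[ord] > bound + margin)]
      placed <- FALSE
      for (ci in cand) {
        if (assign_pair(pool$a[ci], pool$b[ci], linker_seq[i])) {
          used[ci] <- TRUE
          rows[[i]] <- data.frame(
            residueA = sprintf("%s%d", aa_map[as.character(pool$a[ci])],
                               pool$a[ci]),
            residueB = sprintf("%s%d", aa_map[as.character(pool$b[ci])],
                               pool$b[ci]),
            linker = linker_seq[i], score = round(stats::runif(1, 50, 200), 1),
            count = sample(1:10, 1), true_satisfied = want_sat[i],
            true_distance = dmin[ci])
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("geometry cannot supply the requested satisfied fraction")
    }
    tab <- do.call(rbind, rows)
    truth <- tab[, c("true_satisfied", "true_distance")]
    tab <- tab[, c("residueA", "residueB", "linker", "score", "count")]
    attr(tab, "truth") <- truth
    if (!is.null(path)) {
      utils::write.table(tab, path, sep = ",", quote = FALSE,
                         row.names = FALSE)
      write_sidecar(list(n_links = n_links, fraction = fraction,
                         n_satisfied = n_sat, seed = seed),
                    paste0(path, ".truth"))
    }
    tab
  })
}

#' Synthetic peptide-level HDX table from a per-residue truth profile
#'
#' Tiles overlapping peptides across the covered range; each peptide's
#' deuteration is the mean of the true residue values over its aggregated
#' span (`start + exclude ... end`) plus Gaussian noise per replicate.
#'
#' @param truth Data frame `residue`, `percent_D` over contiguous
#'   residues.
#' @param mean_length Mean peptide length (default 10).
#' @param overlap Residues shared by consecutive peptides (default 5).
#' @param replicates Replicate count (default 3).
#' @param noise_sd Gaussian noise on peptide deuteration, percent
#'   (default 0).
#' @param exclude Prefix length the downstream aggregation will use
#'   (default 2); the generator averages truth over the same span.
#' @param time_s Exposure time label, seconds (default 300).
#' @param state State label (default "A").
#' @param seed RNG seed.
#' @param path Optional output path (+ truth sidecar).
#' @return An `hdx_peptides`-compatible data frame.
#' @export
make_hdx_table <- function(truth, mean_length = 10, overlap = 5,
                           replicates = 3, noise_sd = 0, exclude = 2,
                           time_s = 300, state = "A", seed = 1,
                           path = NULL) {
  truth <- as.data.frame(truth)
  stopifnot(all(c("residue", "percent_D") %in% names(truth)))
  if (any(diff(truth$residue) != 1))
    stop("truth profile must cover contiguous residues")
  lo <- min(truth$residue); hi <- max(truth$residue)
  with_seed(seed, {
    aa_pool <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]]  # no prolines
    seq_letters <- sample(aa_pool, hi - lo + 1, replace = TRUE)
    starts <- seq(lo, hi, by = max(mean_length - overlap, 1))
    rows <- list()
    for (st in starts) {
      len <- mean_length + sample(-2:2, 1)
      en <- min(st + len - 1, hi)
      if (en - st + 1 < exclude + 2) en <- min(st + exclude + 1, hi)
      span <- (st + exclude):en
      if (length(span) < 1 || st + exclude > en) next
      true_val <- mean(truth$percent_D[match(span, truth$residue)])
      pep_seq <- paste(seq_letters[(st - lo + 1):(en - lo + 1)],
                       collapse = "")
      for (rep_i in seq_len(replicates)) {
        rows[[length(rows) + 1]] <- data.frame(
          sequence = pep_seq, start = st, end = en, time_s = time_s,
          replicate = rep_i, state = state,
          percent_D = max(true_val + stats::rnorm(1, 0, noise_sd), 0))
      }
    }
    tab <- do.call(rbind, rows)
    covered <- sort(unique(unlist(lapply(
      split(tab, paste(tab$start, tab$end)),
      function(g) (g$start[1] + exclude):g$end[1]))))
    gaps <- setdiff(lo:hi, covered)
    if (length(gaps) > 0)
      warning("tiling leaves uncovered residues: ",
              paste(gaps, collapse = ","))
    if (!is.null(path)) {
      utils::write.table(tab, path, sep = ",", quote = FALSE,
                         row.names = FALSE)
      write_sidecar(list(residue = truth$residue,
                         percent_D = truth$percent_D, exclude = exclude,
                         noise_sd = noise_sd, seed = seed),
                    paste0(path, ".truth"))
    }
    class(tab) <- c("hdx_peptides", class(tab))
    tab
  })
}

#' Noisy Debye-model SAXS curve from coordinates
#'
#' @param xyz Coordinates or `CalphaModel`.
#' @param q Momentum-transfer grid.
#' @param rel_noise Relative Gaussian noise on I (default 0.02).
#' @param seed RNG seed.
#' @param path Optional output path (+ truth sidecar with the coordinate
#'   Rg and seed).
#' @return A `SAXSCurve`.
#' @export
make_saxs_curve <- function(xyz, q, rel_noise = 0.02, seed = 1,
                            path = NULL) {
  clean <- debye_scatter(xyz, q)
  with_seed(seed, {
    # mixed error model: counting-like term plus a constant floor, the
    # usual shape of processed SAXS uncertainties (a purely relative
    # sigma would give high-q points unrealistically extreme weights)
    sigma <- pmax(rel_noise * clean$I + 0.05 * rel_noise * max(clean$I),
                  1e-9 * max(clean$I))
    I <- clean$I + if (rel_noise > 0) stats::rnorm(length(q), 0, sigma) else 0
    out <- saxs_curve(q, I, sigma)
    if (!is.null(path)) {
      write_saxs(out, path)
      write_sidecar(list(rg = coord_rg(xyz), rel_noise = rel_noise,
                         seed = seed), paste0(path, ".truth"))
    }
    out
  })
}

#' Synthetic DeltaTm titration from a single-site binding model
#'
#' @param kd True dissociation constant (concentration unit of `conc`).
#' @param dtm_max True saturation shift, degrees C.
#' @param conc Concentration design (must include 0); default the
#'   standard two-fold dilution series 0-400.
#' @param noise_sd Gaussian noise per measurement, degrees C
#'   (default 0.2).
#' @param replicates Replicate count (default 3).
#' @param seed RNG seed.
#' @param path Optional output path (+ truth sidecar).
#' @return Data frame `conc`, `dTm`, `sd` (replicate-averaged), with the
#'   per-replicate table in attribute `replicates`.
#' @export
make_titration <- function(kd, dtm_max = 4,
                           conc = c(0, 6.25, 12.5, 25, 50, 100, 200, 400),
                           noise_sd = 0.2, replicates = 3, seed = 1,
                           path = NULL) {
  stopifnot(kd > 0, 0 %in% conc)
  with_seed(seed, {
    full <- expand.grid(conc = conc, replicate = seq_len(replicates))
    mu <- dtm_max * full$conc / (kd + full$conc)
    full$dTm <- mu + stats::rnorm(nrow(full), 0, noise_sd)
    full$dTm[full$conc == 0] <- 0       # anchored by construction
    agg <- do.call(rbind, lapply(split(full, full$conc), function(g) {
      data.frame(conc = g$conc[1], dTm = mean(g$dTm),
                 sd = if (nrow(g) > 1) stats::sd(g$dTm) else NA_real_)
    }))
    agg <- agg[order(agg$conc), ]
    rownames(agg) <- NULL
    agg$sd[agg$conc == 0] <- NA
    attr(agg, "replicates") <- full
    if (!is.null(path)) {
      utils::write.table(agg, path, sep = ",", quote = FALSE,
                         row.names = FALSE)
      write_sidecar(list(kd = kd, dtm_max = dtm_max, noise_sd = noise_sd,
                         seed = seed), paste0(path, ".truth"))
    }
    agg
  })
}

#' Synthetic two-sigmoid melt curve
#'
#' @param tm Transition temperatures, degrees C (one or more).
#' @param amplitude Amplitude per transition (recycled).
#' @param width Sigmoid width, degrees C (default 1.5).
#' @param t_range Temperature range (default 25-95).
#' @param n Points (default 141).
#' @param noise_sd Gaussian noise (default 0).
#' @param seed RNG seed.
#' @return Data frame `temperature`, `fluorescence`.
#' @export
make_melt_curve <- function(tm, amplitude = 1, width = 1.5,
                            t_range = c(25, 95), n = 141, noise_sd = 0,
                            seed = 1) {
  temperature <- seq(t_range[1], t_range[2], length.out = n)
  amplitude <- rep_len(amplitude, length(tm))
  f <- rowSums(vapply(seq_along(tm), function(i) {
    amplitude[i] / (1 + exp(-(temperature - tm[i]) / width))
  }, numeric(n)))
  f <- with_seed(seed, f + if (noise_sd > 0)
    stats::rnorm(n, 0, noise_sd) else 0)
  data.frame(temperature = temperature, fluorescence = f)
}

#' Tetramer-recovery scenario
#'
#' Emits everything needed to test rigid-body tetramer fitting end to
#' end: a toy protomer, a ground-truth C4 pose, the Debye SAXS curve of
#' the true assembly with noise, a homotypic restraint set satisfied by
#' the truth, and a sidecar with all latent parameters.
#'
#' @param dir Output directory (created if needed). `NULL` returns the
#'   objects without writing.
#' @param seed Master seed; sub-seeds are split deterministically.
#' @param n_res Protomer size (default 60).
#' @param rel_noise SAXS noise (default 0.02).
#' @return List: `protomer`, `pose`, `assembly`, `curve`,
#'   `restraint_residues`, `truth`.
#' @export
scenario_tetramer_recovery <- function(dir = NULL, seed = 1, n_res = 60,
                                       rel_noise = 0.02) {
  protomer <- make_helix_bundle(n_res, seed = split_seed(seed, 1))
  pose <- list(angles = c(0.4, 0.3, 0.2), rho = 18)
  assembly <- assemble_c4(protomer, pose)
  q <- seq(0.01, 0.25, length.out = 80)
  curve <- make_saxs_curve(assembly_xyz(assembly), q,
                           rel_noise = rel_noise,
                           seed = split_seed(seed, 2))
  # three spread-out residues whose homotypic distances satisfy the bound
  d_all <- homotypic_distances(assembly, protomer$resno)
  ok <- protomer$resno[d_all <= 33]
  res <- ok[round(seq(1, length(ok), length.out = 3))]
  truth <- list(angles = pose$angles, rho = pose$rho,
                restraint_residues = res,
                restraint_distances = homotypic_distances(assembly, res),
                rg = coord_rg(assembly_xyz(assembly)),
                rel_noise = rel_noise, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_structure(calpha_to_structure(protomer),
                    file.path(dir, "protomer.pdb"))
    write_assembly(assembly, file.path(dir, "true_assembly.pdb"))
    write_saxs(curve, file.path(dir, "target.dat"))
    write_sidecar(truth, file.path(dir, "scenario.truth"))
  }
  list(protomer = protomer, pose = pose, assembly = assembly,
       curve = curve, restraint_residues = res, truth = truth)
}

#' Seeded native-MS envelope generator (delegates to [simulate_envelope()])
#' @inheritParams simulate_envelope
#' @param path Optional peak-list output path (+ truth sidecar).
#' @return A `ChargeEnvelope`.
#' @export
make_envelope <- function(mass, charges, seed = 1, mz_noise_sd = 0,
                          path = NULL) {
  e <- simulate_envelope(mass, charges, seed = seed,
                         mz_noise_sd = mz_noise_sd)
  if (!is.null(path)) {
    writeLines(sprintf("%.6f %.6f", e$mz, e$intensity), path)
    write_sidecar(list(mass = mass, charges = charges,
                       mz_noise_sd = mz_noise_sd, seed = seed),
                  paste0(path, ".truth"))
  }
  e
}

#' Seeded sedimentation-velocity generator (delegates to [simulate_sv()])
#' @inheritParams simulate_sv
#' @param path Optional scan-matrix output path (+ truth sidecar).
#' @return An `SVExperiment`.
#' @export
make_sv <- function(species, design = sv_design(), noise_sd = 0.005,
                    seed = 1, path = NULL) {
  e <- simulate_sv(species, design, noise_sd = noise_sd, seed = seed)
  if (!is.null(path)) {
    write_sv(e, path)
    write_sidecar(list(s = species$s, D = species$D,
                       signal = species$signal, noise_sd = noise_sd,
                       seed = seed), paste0(path, ".truth"))
  }
  e
}
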