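## Pipeline driver: a JSON run configuration, strict key validation, a
## stage dispatcher, and a thin subcommand front end (see exec/tetraconf).
## Numeric results are written to a JSON report; logs go to stderr.

PIPELINE_SCHEMA <- list(
  top = c("stages", "seed", "outdir", "params"),
  stages = c("simulate", "track-closure", "xlink-validate", "hdx-map",
             "saxs-guinier", "saxs-pofr", "saxs-fit-tetramer",
             "nativems-deconv", "tsa-kd", "auc-cs"),
  params = list(
    "simulate" = c("scenario", "dir"),
    "track-closure" = c("structure", "labelA", "labelB", "cutoff", "gamma",
                        "step", "contact", "max_iter"),
    "xlink-validate" = c("links", "structure", "structures"),
    "hdx-map" = c("peptides", "time_point", "exclude_prefix", "stateA",
                  "stateB", "structure"),
    "saxs-guinier" = c("curve", "qrg_limit"),
    "saxs-pofr" = c("curve", "dmax", "alpha"),
    "saxs-fit-tetramer" = c("protomer", "curve", "residues", "bound",
                            "steps", "refine"),
    "nativems-deconv" = c("peaks", "z_min", "z_max", "monomer_mass"),
    "tsa-kd" = c("titration"),
    "auc-cs" = c("scans", "s_min", "s_max", "s_points", "ff0", "alpha")))

#' Validate a pipeline run configuration
#'
#' Unknown keys at the top level or inside any stage's parameter block
#' are rejected before anything runs.
#'
#' @param config A list (e.g. from `jsonlite::read_json`).
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), PIPELINE_SCHEMA$top)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stages <- unlist(config$stages)
  bad <- setdiff(stages, PIPELINE_SCHEMA$stages)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (st in names(config$params %||% list())) {
    if (!st %in% PIPELINE_SCHEMA$stages)
      stop("parameters for unknown stage: ", st)
    extra <- setdiff(names(config$params[[st]]), PIPELINE_SCHEMA$params[[st]])
    if (length(extra) > 0)
      stop(sprintf("unknown key(s) in stage '%s': %s", st,
                   paste(extra, collapse = ", ")))
  }
  invisible(config)
}

#' Run the analysis pipeline from a configuration
#'
#' Stages execute in the order given; each writes its numeric results
#' into the report bundle. A resolved-config snapshot and the seed are
#' stored alongside for provenance. Stage failure aborts with a nonzero
#' status but preserves completed stage reports.
#'
#' @param config Path to a JSON config file, or an equivalent list.
#' @return Report list (also written to `<outdir>/report.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  validate_config(config)
  outdir <- config$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1)
  report <- list(seed = seed, stages = list())
  jsonlite::write_json(config, file.path(outdir, "config_snapshot.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (st in unlist(config$stages)) {
    message("[tetraconf] stage: ", st)
    p <- config$params[[st]] %||% list()
    res <- run_stage(st, p, seed, outdir)
    report$stages[[st]] <- res
  }
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

run_stage <- function(stage, p, seed, outdir) {
  switch(stage,
    "simulate" = {
      sc <- p$scenario %||% "tetramer-recovery"
      if (sc != "tetramer-recovery") stop("unknown scenario: ", sc)
      out <- scenario_tetramer_recovery(dir = p$dir %||%
                                          file.path(outdir, sc),
                                        seed = seed)
      list(scenario = sc, rho = out$pose$rho,
           restraint_residues = out$restraint_residues)
    },
    "track-closure" = {
      s <- read_structure(p$structure)
      m <- extract_calpha(s)
      tr <- track_closure(m, p$labelA, p$labelB,
                          cutoff = p$cutoff %||% 15,
                          gamma = p$gamma %||% 1,
                          step = p$step %||% 0.5,
                          contact = p$contact %||% 8,
                          max_iter = p$max_iter %||% 500)
      utils::write.table(tr$trace, file.path(outdir, "closure_trace.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_structure(calpha_to_structure(tr$final),
                      file.path(outdir, "closure_final.pdb"))
      list(converged = tr$converged, iterations = nrow(tr$trace),
           final_distance = if (nrow(tr$trace) > 0)
             tr$trace$min_distance[nrow(tr$trace)] else tr$start_distance)
    },
    "xlink-validate" = {
      links <- parse_crosslinks(p$links)
      paths <- p$structures %||% p$structure
      protomers <- lapply(unlist(paths),
                          function(f) extract_calpha(read_structure(f)))
      rep_ <- map_distances(links, protomers)
      write_crosslink_report(rep_, file.path(outdir, "xlink_report.tsv"))
      list(n_links = nrow(rep_), score = satisfaction_score(rep_))
    },
    "hdx-map" = {
      peps <- load_peptides(p$peptides)
      ex <- p$exclude_prefix %||% 2
      pa <- per_residue_profile(peps, p$time_point, exclude_prefix = ex,
                                state = p$stateA)
      out <- pa
      if (!is.null(p$stateB)) {
        pb <- per_residue_profile(peps, p$time_point, exclude_prefix = ex,
                                  state = p$stateB)
        out <- differential(pa, pb)
      }
      write_profile(out, file.path(outdir, "hdx_profile.tsv"))
      if (!is.null(p$structure)) {
        s <- read_structure(p$structure)
        vals <- data.frame(chain = s$atoms$chain[1], resno = out$residue,
                           value = out[[2]])
        write_residue_map(s, vals, file.path(outdir, "hdx_map.pdb"))
      }
      list(n_residues = nrow(out), exclude_prefix = ex)
    },
    "saxs-guinier" = {
      g <- guinier_fit(read_saxs(p$curve), qrg_limit = p$qrg_limit %||% 1.3)
      list(rg = g$Rg, i0 = g$I0, qmax_rg = g$qmax_rg)
    },
    "saxs-pofr" = {
      curve <- read_saxs(p$curve)
      dmax <- p$dmax %||% estimate_dmax(curve,
                                        scan = seq(40, 300, by = 10),
                                        alpha = p$alpha %||% 0.01)
      pr <- pofr_transform(curve, dmax, alpha = p$alpha %||% 0.01)
      utils::write.table(data.frame(r = pr$r, P = pr$P),
                         file.path(outdir, "pofr.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(dmax = as.numeric(dmax), rg = pr$Rg, chi = pr$chi)
    },
    "saxs-fit-tetramer" = {
      prot <- extract_calpha(read_structure(p$protomer))
      curve <- read_saxs(p$curve)
      spec <- restraint_spec(residues = unlist(p$residues %||%
                                                 c(157, 173, 305)),
                             bound = p$bound %||% 35)
      fit <- rigid_body_fit(prot, curve, spec, seed = seed,
                            steps = p$steps %||% 400)
      if (isTRUE(p$refine)) fit <- refine_restrained(fit, spec)
      write_assembly(fit$assembly, file.path(outdir, "tetramer.pdb"))
      list(chi = fit$chi, rho = fit$pose$rho,
           restraint_distances = fit$restraint_distances)
    },
    "nativems-deconv" = {
      e <- read_peaklist(p$peaks)
      sols <- deconvolve(e, (p$z_min %||% 5):(p$z_max %||% 50))
      res <- list(mass = sols[[1]]$mass, n_peaks = sols[[1]]$n_peaks)
      if (!is.null(p$monomer_mass)) {
        sr <- species_report(sols, p$monomer_mass)
        res$stoichiometry <- sr$n[1]
      }
      res
    },
    "tsa-kd" = {
      tab <- utils::read.table(p$titration, header = TRUE,
                               sep = guess_sep(p$titration))
      fit <- fit_kd(tab$conc, tab$dTm,
                    sd = if ("sd" %in% names(tab)) tab$sd else NULL)
      list(kd = fit$Kd, kd_se = fit$Kd_se, dtm_max = fit$dTm_max,
           unreliable = fit$unreliable)
    },
    "auc-cs" = {
      tab <- utils::read.table(p$scans, header = TRUE, sep = "\t",
                               check.names = FALSE)
      times <- as.numeric(sub("^t", "", names(tab)[-1]))
      e <- structure(list(r = tab[[1]], times = times,
                          omega = 50000 * 2 * pi / 60, rpm = 50000,
                          scans = t(as.matrix(tab[, -1])), noise_sd = NA,
                          species = NULL), class = "SVExperiment")
      cs <- fit_cs(e, seq(p$s_min %||% 0.5, p$s_max %||% 15,
                          length.out = p$s_points %||% 100),
                   ff0 = p$ff0 %||% 1.2, alpha = p$alpha %||% 0.01)
      utils::write.table(data.frame(s = cs$s, c = cs$c),
                         file.path(outdir, "cs_distribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(peaks = cs$peaks$s, total_signal = cs$total_signal)
    },
    stop("unknown stage: ", stage))
}

#' Command-line entry point
#'
#' `tetraconf run <config.json>` executes the pipeline; every stage name
#' is also available as a subcommand taking `key=value` arguments that
#' mirror the config keys 1:1, e.g.
#' `tetraconf saxs-guinier curve=curve.dat outdir=out`.
#'
#' @param args Character vector (default `commandArgs(TRUE)`).
#' @return Exit status, invisibly (0 on success).
#' @export
pipeline_main <- function(args = commandArgs(TRUE)) {
  if (length(args) == 0) {
    cat("usage: tetraconf run <config.json> | <stage> key=value ...\n",
        "stages:", paste(PIPELINE_SCHEMA$stages, collapse = " "), "\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  status <- tryCatch({
    if (cmd == "run") {
      run_pipeline(args[2])
    } else if (cmd %in% PIPELINE_SCHEMA$stages) {
      kv <- strsplit(args[-1], "=", fixed = TRUE)
      p <- stats::setNames(
        lapply(kv, function(x) utils::type.convert(x[2], as.is = TRUE)),
        vapply(kv, `[`, "", 1))
      outdir <- p$outdir %||% "."
      seed <- as.integer(p$seed %||% 1)
      p$outdir <- NULL; p$seed <- NULL
      cfg <- list(stages = cmd, seed = seed, outdir = outdir,
                  params = stats::setNames(list(p), cmd))
      run_pipeline(cfg)
    } else {
      stop("unknown subcommand: ", cmd)
    }
    0L
  }, error = function(e) {
    message("[tetraconf] error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
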