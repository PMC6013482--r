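## Crosslinking-MS distance restraints: parse identified links, map them
## onto monomer or oligomer Calpha models, and score satisfaction against
## linker-specific upper bounds. Distances are Calpha-Calpha, the same
## criterion used to validate models against identified links.

# Reactive-side chemistry per linker. DMTMM forms zero-length amide bonds
# between an amine side (K) and a carboxylate side (D/E); DSS and BS3 are
# amine-reactive with known off-target reactivity at S/T/Y.
XL_CHEMISTRY <- list(
  DMTMM = list(sideA = c("K"), sideB = c("D", "E")),
  DSS = list(sideA = c("K", "S", "T", "Y"), sideB = c("K", "S", "T", "Y")),
  BS3 = list(sideA = c("K", "S", "T", "Y"), sideB = c("K", "S", "T", "Y")))

#' Default Calpha-Calpha upper bounds per linker (angstrom)
#'
#' Zero-length DMTMM links allow at most 30 angstrom between Calpha atoms;
#' the ~11-angstrom-spacer reagents DSS and BS3 allow 35.
#' @export
default_linker_bounds <- function() c(DMTMM = 30, DSS = 35, BS3 = 35)

parse_residue_token <- function(tok) {
  m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)$", tok))[[1]]
  if (length(m) != 3) return(NULL)
  list(aa = toupper(m[2]), resno = as.integer(m[3]))
}

chemistry_valid <- function(aaA, aaB, linker) {
  chem <- XL_CHEMISTRY[[linker]]
  (aaA %in% chem$sideA && aaB %in% chem$sideB) ||
    (aaB %in% chem$sideA && aaA %in% chem$sideB)
}

#' Parse a crosslink table
#'
#' Expects delimited text with a header naming at least `residueA`,
#' `residueB`, `linker`; optional `score` and `count`. Residue tokens are
#' amino-acid letter plus author residue number (e.g. `K157`). Rows whose
#' residues are incompatible with the linker chemistry are rejected, not
#' fatal; an unknown linker token is fatal.
#'
#' @param path Path to the table (comma, tab or semicolon separated).
#' @return Data frame of class `crosslink_set` with columns `resA`, `aaA`,
#'   `resB`, `aaB`, `linker`, `score`, `count`; rejected rows (with a
#'   reason) in attribute `rejects`.
#' @export
parse_crosslinks <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("residueA", "residueB", "linker")
  if (!all(need %in% names(tab)))
    stop("crosslink table needs columns: ", paste(need, collapse = ", "))
  bad_linker <- setdiff(unique(tab$linker), names(XL_CHEMISTRY))
  if (length(bad_linker) > 0)
    stop("unknown linker token(s): ", paste(bad_linker, collapse = ", "))
  out <- data.frame(resA = integer(0), aaA = character(0), resB = integer(0),
                    aaB = character(0), linker = character(0),
                    score = numeric(0), count = numeric(0))
  rejects <- data.frame(row = integer(0), reason = character(0))
  for (i in seq_len(nrow(tab))) {
    ra <- parse_residue_token(tab$residueA[i])
    rb <- parse_residue_token(tab$residueB[i])
    if (is.null(ra) || is.null(rb)) {
      rejects <- rbind(rejects, data.frame(row = i,
                                           reason = "malformed residue token"))
      next
    }
    if (!chemistry_valid(ra$aa, rb$aa, tab$linker[i])) {
      rejects <- rbind(rejects, data.frame(
        row = i, reason = sprintf("%s-%s incompatible with %s chemistry",
                                  ra$aa, rb$aa, tab$linker[i])))
      next
    }
    out <- rbind(out, data.frame(
      resA = ra$resno, aaA = ra$aa, resB = rb$resno, aaB = rb$aa,
      linker = tab$linker[i],
      score = if ("score" %in% names(tab)) tab$score[i] else NA_real_,
      count = if ("count" %in% names(tab)) tab$count[i] else NA_real_))
  }
  attr(out, "rejects") <- rejects
  class(out) <- c("crosslink_set", class(out))
  out
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else ","
}

#' Map crosslinks onto an assembly and judge restraint satisfaction
#'
#' For each link the reported distance is the minimum over all chain
#' assignments: both residues in the same protomer (intra) or in any
#' ordered pair of distinct protomers (inter). Homotypic links (same
#' residue on both sides) are necessarily inter-protomer and exclude the
#' self assignment. Satisfaction compares inclusively against the
#' linker's Calpha-Calpha upper bound.
#'
#' @param links A `crosslink_set` (or compatible data frame).
#' @param assembly A `CalphaModel` or list of protomer `CalphaModel`s.
#' @param bounds Named vector of upper bounds per linker
#'   (default [default_linker_bounds()]).
#' @return A `crosslink_report` data frame: per link the minimum distance,
#'   the assignment achieving it, satisfied flag, ambiguity count (number
#'   of assignments within bound), and an error string for unresolvable
#'   residues.
#' @export
map_distances <- function(links, assembly, bounds = default_linker_bounds()) {
  if (inherits(assembly, "CalphaModel")) assembly <- list(assembly)
  np <- length(assembly)
  out <- data.frame(resA = links$resA, aaA = links$aaA, resB = links$resB,
                    aaB = links$aaB, linker = links$linker,
                    bound = unname(bounds[links$linker]),
                    distance = NA_real_, assignment = NA_character_,
                    satisfied = NA, ambiguity = NA_integer_,
                    error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(links))) {
    posA <- lapply(assembly, function(p) {
      k <- match(links$resA[i], p$resno); if (is.na(k)) NULL else p$xyz[k, ]
    })
    posB <- lapply(assembly, function(p) {
      k <- match(links$resB[i], p$resno); if (is.na(k)) NULL else p$xyz[k, ]
    })
    if (any(vapply(posA, is.null, TRUE)) || any(vapply(posB, is.null, TRUE))) {
      out$error[i] <- "residue not resolvable in every protomer"
      next
    }
    homotypic <- links$resA[i] == links$resB[i]
    best <- Inf; best_lab <- NA_character_; amb <- 0L
    for (a in seq_len(np)) {
      for (b in seq_len(np)) {
        if (homotypic && a == b) next
        if (homotypic && a > b) next   # unordered for same-residue links
        d <- sqrt(sum((posA[[a]] - posB[[b]])^2))
        if (d <= out$bound[i]) amb <- amb + 1L
        if (d < best) {
          best <- d
          best_lab <- if (a == b) "intra" else sprintf("%d-%d", a, b)
        }
      }
    }
    out$distance[i] <- best
    out$assignment[i] <- best_lab
    out$satisfied[i] <- best <= out$bound[i]
    out$ambiguity[i] <- amb
  }
  class(out) <- c("crosslink_report", class(out))
  out
}

#' Partition links by inter-subunit assignability
#'
#' In a homo-oligomer only homotypic (like-to-like) links are unambiguous
#' evidence of inter-subunit contact; every heterotypic link could be
#' satisfied within one protomer.
#'
#' @param links A `crosslink_set` or report.
#' @return List with elements `unambiguous_inter` and `ambiguous`.
#' @export
classify_intersubunit <- function(links) {
  homotypic <- links$resA == links$resB & links$aaA == links$aaB
  list(unambiguous_inter = links[homotypic, , drop = FALSE],
       ambiguous = links[!homotypic, , drop = FALSE])
}

#' Weighted fraction of satisfied restraints
#'
#' @param report A `crosslink_report` from [map_distances()].
#' @param weights Optional per-link weights (default unit).
#' @return Fraction in \[0, 1\]; links with mapping errors are excluded.
#' @export
satisfaction_score <- function(report, weights = NULL) {
  ok <- is.na(report$error)
  if (sum(ok) == 0) stop("empty report: no mappable links to score")
  w <- if (is.null(weights)) rep(1, nrow(report)) else weights
  stopifnot(length(w) == nrow(report))
  sum(w[ok] * as.numeric(report$satisfied[ok])) / sum(w[ok])
}

#' Write a crosslink report as delimited text
#'
#' @param report A `crosslink_report`.
#' @param path Output path (tab separated).
#' @return `path`, invisibly.
#' @export
write_crosslink_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
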