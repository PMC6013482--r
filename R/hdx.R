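## Hydrogen-deuterium exchange: peptide-level deuteration tables are
## converted to per-residue profiles by pooling overlapping peptides, a
## configurable number of N-terminal peptide residues being excluded for
## their rapid back exchange. Differential profiles subtract two states
## residue by residue.

#' Load a peptide-level HDX table
#'
#' Delimited text with header columns `sequence`, `start`, `end`,
#' `time_s`, `replicate`, `state`, `percent_D`. Rows violating basic
#' invariants (sequence length vs span, deuteration outside \[0, 110\])
#' are rejected with a reason, not fatal.
#'
#' @param path Path to the table.
#' @return Data frame of class `hdx_peptides`; rejected rows in attribute
#'   `rejects`.
#' @export
load_peptides <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("sequence", "start", "end", "time_s", "replicate", "percent_D")
  if (!all(need %in% names(tab)))
    stop("HDX table needs columns: ", paste(need, collapse = ", "))
  if (!"state" %in% names(tab)) tab$state <- "default"
  reason <- rep(NA_character_, nrow(tab))
  span_ok <- tab$end >= tab$start
  reason[!span_ok] <- "end < start"
  len_ok <- nchar(tab$sequence) == tab$end - tab$start + 1
  reason[span_ok & !len_ok] <- "sequence length does not match span"
  d_ok <- tab$percent_D >= 0 & tab$percent_D <= 110
  reason[span_ok & len_ok & !d_ok] <- "deuteration outside [0, 110]"
  keep <- is.na(reason)
  out <- tab[keep, , drop = FALSE]
  rej <- cbind(tab[!keep, , drop = FALSE], reason = reason[!keep])
  attr(out, "rejects") <- rej
  class(out) <- c("hdx_peptides", class(out))
  out
}

#' Number of exchangeable backbone amides of a peptide
#'
#' The N-terminal residue and prolines (which lack an amide proton) after
#' position 1 do not contribute.
#'
#' @param sequence One-letter amino-acid string.
#' @return Integer count.
#' @export
theoretical_max_sites <- function(sequence) {
  if (nchar(sequence) == 0) stop("empty sequence")
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (!all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
    stop("non-amino-acid letter in sequence: ", sequence)
  max(length(aa) - 1 - sum(aa[-1] == "P"), 0)
}

#' Per-residue exchange profile from overlapping peptides
#'
#' Each peptide contributes its deuteration value to residues
#' `start + exclude_prefix ... end`. Replicates of a peptide are averaged
#' first; the residue value is the unweighted mean over covering
#' peptides. The SEM is computed across experimental replicates (each
#' replicate is pooled to a per-residue value, then the spread across
#' replicates is taken), and is defined only for two or more replicates.
#'
#' @param records An `hdx_peptides` table (one state).
#' @param time_point Exposure time in seconds to profile.
#' @param exclude_prefix N-terminal peptide residues excluded from the
#'   aggregation (default 2; 3 is the common stricter variant).
#' @param state Optional state filter when `records` holds several.
#' @return A `ResidueExchangeProfile` data frame: `residue`, `mean_D`,
#'   `sem_D`, `coverage` (covering-peptide count); attributes record the
#'   exclusion length and time point. Uncovered residues are absent.
#' @export
per_residue_profile <- function(records, time_point,
                                exclude_prefix = 2, state = NULL) {
  stopifnot(exclude_prefix >= 0)
  if (!is.null(state)) records <- records[records$state == state, , drop = FALSE]
  records <- records[records$time_s == time_point, , drop = FALSE]
  if (nrow(records) == 0) {
    warning("no peptides at the requested time point; empty profile")
    return(empty_profile(exclude_prefix, time_point))
  }
  pep_key <- paste(records$sequence, records$start, records$end)
  # replicate-averaged peptide values
  pep_mean <- tapply(records$percent_D, pep_key, mean)
  pep_info <- records[!duplicated(pep_key), c("start", "end")]
  rownames(pep_info) <- unique(pep_key)
  reps <- sort(unique(records$replicate))
  res_min <- min(records$start); res_max <- max(records$end)
  residues <- res_min:res_max
  acc_sum <- acc_n <- setNames(numeric(length(residues)), residues)
  # per-replicate accumulation for the SEM
  rep_sum <- matrix(0, length(residues), length(reps),
                    dimnames = list(residues, reps))
  rep_n <- rep_sum
  for (key in names(pep_mean)) {
    first <- pep_info[key, "start"] + exclude_prefix
    last <- pep_info[key, "end"]
    if (first > last) next
    span <- as.character(first:last)
    acc_sum[span] <- acc_sum[span] + pep_mean[[key]]
    acc_n[span] <- acc_n[span] + 1
    rows <- records[pep_key == key, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      rc <- as.character(rows$replicate[k])
      rep_sum[span, rc] <- rep_sum[span, rc] + rows$percent_D[k]
      rep_n[span, rc] <- rep_n[span, rc] + 1
    }
  }
  covered <- acc_n > 0
  if (!any(covered)) {
    warning("all residues uncovered after prefix exclusion; empty profile")
    return(empty_profile(exclude_prefix, time_point))
  }
  rep_val <- rep_sum / ifelse(rep_n > 0, rep_n, NA)
  sem <- apply(rep_val, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  out <- data.frame(residue = residues[covered],
                    mean_D = unname(acc_sum[covered] / acc_n[covered]),
                    sem_D = unname(sem[covered]),
                    coverage = as.integer(unname(acc_n[covered])))
  attr(out, "exclude_prefix") <- exclude_prefix
  attr(out, "time_point") <- time_point
  class(out) <- c("ResidueExchangeProfile", class(out))
  out
}

empty_profile <- function(exclude_prefix, time_point) {
  out <- data.frame(residue = integer(0), mean_D = numeric(0),
                    sem_D = numeric(0), coverage = integer(0))
  attr(out, "exclude_prefix") <- exclude_prefix
  attr(out, "time_point") <- time_point
  class(out) <- c("ResidueExchangeProfile", class(out))
  out
}

#' Differential uptake between two states
#'
#' Residue-wise `A - B`; defined only where both states are covered.
#'
#' @param profileA,profileB `ResidueExchangeProfile`s at the same time
#'   point.
#' @return A `DifferentialProfile` data frame: `residue`, `delta_D`,
#'   propagated `sem_D`.
#' @export
differential <- function(profileA, profileB) {
  common <- intersect(profileA$residue, profileB$residue)
  if (length(common) == 0)
    warning("disjoint coverage: differential profile is empty")
  ia <- match(common, profileA$residue)
  ib <- match(common, profileB$residue)
  sem <- sqrt(ifelse(is.na(profileA$sem_D[ia]), 0, profileA$sem_D[ia])^2 +
                ifelse(is.na(profileB$sem_D[ib]), 0, profileB$sem_D[ib])^2)
  sem[is.na(profileA$sem_D[ia]) & is.na(profileB$sem_D[ib])] <- NA
  out <- data.frame(residue = common,
                    delta_D = profileA$mean_D[ia] - profileB$mean_D[ib],
                    sem_D = sem)
  class(out) <- c("DifferentialProfile", class(out))
  out
}

#' Export a per-residue or differential profile as delimited text
#'
#' @param profile A profile data frame.
#' @param path Output path (tab separated).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
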