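## Structure container and flat-file I/O (PDB read/write, mmCIF read).
## No structure package ships with the target environment, so the two
## formats are parsed here directly: fixed-column records for PDB and the
## _atom_site loop for mmCIF. Parsing is restricted to the atom records
## needed by a Calpha-level pipeline.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

new_structure <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("chain", "resno", "resname", "atom", "x", "y", "z", "occ", "bfac",
           "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty polymer: structure has no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in structure")
  key <- paste(atoms$chain, atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) records after altloc resolution")
  seqs <- lapply(split(atoms, atoms$chain), function(ch) {
    res <- ch[!duplicated(ch$resno), c("resno", "resname")]
    res <- res[order(res$resno), ]
    aa <- unname(AA3TO1[res$resname])
    aa[is.na(aa)] <- "X"
    data.frame(resno = res$resno, aa = aa, stringsAsFactors = FALSE)
  })
  structure(list(atoms = atoms, sequence = seqs), class = "Structure")
}

#' Read a macromolecular structure from PDB or mmCIF text
#'
#' Polymer atom records are read into a flat atom table; heteroatoms and
#' waters are excluded unless requested. Alternate locations are resolved
#' by keeping the highest-occupancy conformer of each atom, which makes
#' Calpha extraction deterministic.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param format `"pdb"`, `"cif"`, or `"auto"` (by file extension).
#' @param include_het Keep HETATM records (waters are always dropped).
#' @return A `Structure`: list with an `atoms` data frame (chain, resno,
#'   resname, atom, x, y, z, occ, bfac, element) and a per-chain `sequence`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           include_het = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  atoms <- if (format == "pdb") parse_pdb_atoms(path, include_het)
           else parse_cif_atoms(path, include_het)
  if (nrow(atoms) == 0) stop("empty polymer: no atom records parsed from ", path)
  atoms <- resolve_altloc(atoms)
  new_structure(atoms)
}

parse_pdb_atoms <- function(path, include_het) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (include_het & rec == "HETATM")
  # honor the first model only
  end_first <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(end_first) > 0) keep <- keep & seq_along(lines) < end_first[1]
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(chain = character(0)))
  fx <- function(a, b) trimws(substr(lines, a, b))
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(fx(a, b)))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stop(sprintf("parse error in PDB record %d: bad %s field: '%s'",
                   bad[1], what, fx(a, b)[bad[1]]))
    v
  }
  resname <- fx(18, 20)
  at <- data.frame(
    chain = fx(22, 22), resno = as.integer(num(23, 26, "residue number")),
    resname = resname, atom = fx(13, 16), alt = fx(17, 17),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occ = suppressWarnings(as.numeric(fx(55, 60))),
    bfac = suppressWarnings(as.numeric(fx(61, 66))),
    element = fx(77, 78), stringsAsFactors = FALSE)
  at$occ[!is.finite(at$occ)] <- 1
  at$bfac[!is.finite(at$bfac)] <- 0
  at[at$resname != "HOH", , drop = FALSE]
}

parse_cif_atoms <- function(path, include_het) {
  lines <- readLines(path, warn = FALSE)
  tag_idx <- grep("^_atom_site\\.", lines)
  if (length(tag_idx) == 0) stop("parse error: no _atom_site loop in ", path)
  tags <- sub("^_atom_site\\.", "", trimws(lines[tag_idx]))
  body_start <- max(tag_idx) + 1
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(#|loop_|_)", ln) || ln == "stop_") break
    body <- c(body, ln)
  }
  if (length(body) == 0) stop("parse error: empty _atom_site loop in ", path)
  toks <- strsplit(body, "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf != length(tags)))
    stop(sprintf("parse error in mmCIF atom row %d: %d tokens, %d expected",
                 which(nf != length(tags))[1], nf[nf != length(tags)][1],
                 length(tags)))
  m <- do.call(rbind, toks)
  colnames(m) <- tags
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% tags) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  grp <- pick("group_PDB")
  keep <- grp == "ATOM" | (include_het & grp == "HETATM")
  strip_q <- function(v) gsub("^['\"]|['\"]$", "", v)
  at <- data.frame(
    chain = pick("auth_asym_id", "label_asym_id"),
    resno = suppressWarnings(as.integer(pick("auth_seq_id", "label_seq_id"))),
    resname = pick("auth_comp_id", "label_comp_id"),
    atom = strip_q(pick("auth_atom_id", "label_atom_id")),
    alt = pick("label_alt_id"),
    x = suppressWarnings(as.numeric(pick("Cartn_x"))),
    y = suppressWarnings(as.numeric(pick("Cartn_y"))),
    z = suppressWarnings(as.numeric(pick("Cartn_z"))),
    occ = suppressWarnings(as.numeric(pick("occupancy"))),
    bfac = suppressWarnings(as.numeric(pick("B_iso_or_equiv"))),
    element = pick("type_symbol"), stringsAsFactors = FALSE)
  at <- at[keep, , drop = FALSE]
  if ("pdbx_PDB_model_num" %in% tags) {
    mod <- m[keep, "pdbx_PDB_model_num"]
    at <- at[mod == mod[1], , drop = FALSE]
  }
  at$alt[at$alt %in% c(".", "?")] <- ""
  at$occ[!is.finite(at$occ)] <- 1
  at$bfac[!is.finite(at$bfac)] <- 0
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad) > 0)
    stop("parse error: non-numeric coordinates in mmCIF atom row ", bad[1])
  at[at$resname != "HOH", , drop = FALSE]
}

# Keep the highest-occupancy alternate conformer of every atom.
resolve_altloc <- function(at) {
  key <- paste(at$chain, at$resno, at$atom)
  ord <- order(key, -at$occ)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$atom)), , drop = FALSE]
  at$alt <- NULL
  at[order(match(at$chain, unique(at$chain)), at$resno), , drop = FALSE]
}

#' Write a Structure as PDB text
#'
#' @param s A `Structure`.
#' @param path Output file path.
#' @param bfac Optional replacement vector for the temperature-factor
#'   column (one value per atom row).
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, bfac = NULL) {
  stopifnot(inherits(s, "Structure"))
  at <- s$atoms
  if (!is.null(bfac)) {
    stopifnot(length(bfac) == nrow(at))
    at$bfac <- bfac
  }
  # temperature-factor column is 6.2f: clamp out-of-range values
  clamp <- at$bfac < -9.99 | at$bfac > 999.99
  if (any(clamp)) {
    warning(sum(clamp), " temperature-factor values clamped to column range")
    at$bfac <- pmin(pmax(at$bfac, -9.99), 999.99)
  }
  name4 <- ifelse(nchar(at$atom) >= 4, substr(at$atom, 1, 4),
                  sprintf(" %-3s", at$atom))
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)) %% 100000, name4, at$resname,
    substr(paste0(at$chain, " "), 1, 1), at$resno,
    at$x, at$y, at$z, at$occ, at$bfac,
    formatC(at$element, width = 2, flag = " "))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Map per-residue scalars onto the temperature-factor column of a PDB file
#'
#' Every atom of a mapped residue carries the residue's value; residues
#' absent from `values` carry the `sentinel`. Used to paint differential
#' HDX uptake or restraint violations onto a model for molecular graphics.
#'
#' @param s A `Structure`.
#' @param values Data frame with columns `chain`, `resno`, `value`.
#' @param path Output PDB path.
#' @param sentinel Value written for unmapped residues (default `-1`, chosen to fit the 6.2f column).
#' @return `path`, invisibly.
#' @export
write_residue_map <- function(s, values, path, sentinel = -1) {
  stopifnot(inherits(s, "Structure"))
  values <- as.data.frame(values)
  if (!all(c("chain", "resno", "value") %in% names(values)))
    stop("values needs columns chain, resno, value")
  key <- paste(s$atoms$chain, s$atoms$resno)
  vkey <- paste(values$chain, values$resno)
  idx <- match(key, vkey)
  bf <- ifelse(is.na(idx), sentinel, values$value[idx])
  write_structure(s, path, bfac = bf)
}

#' @export
print.Structure <- function(x, ...) {
  nres <- sum(!duplicated(paste(x$atoms$chain, x$atoms$resno)))
  cat(sprintf("Structure: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms), nres,
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}
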