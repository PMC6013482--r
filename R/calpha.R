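## CalphaModel: the coarse-grained substrate of the elastic-network,
## crosslink and assembly machinery. One coordinate triple per residue,
## with chain/residue bookkeeping and a domain label per residue.

#' Construct a Calpha model
#'
#' @param xyz N x 3 coordinate matrix (angstrom).
#' @param resno Integer residue numbers (author numbering, no renumbering).
#' @param chain Chain identifier per residue (recycled if length 1).
#' @param domain Domain label per residue (recycled if length 1).
#' @return A `CalphaModel`.
#' @export
calpha_model <- function(xyz, resno = seq_len(nrow(xyz)), chain = "A",
                         domain = "all") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must be an N x 3 matrix")
  n <- nrow(xyz)
  if (n < 2) stop("CalphaModel needs at least 2 residues")
  stopifnot_finite(xyz, "coordinates")
  chain <- rep_len(as.character(chain), n)
  domain <- rep_len(as.character(domain), n)
  resno <- as.integer(rep_len(resno, n))
  if (anyDuplicated(paste(chain, resno)))
    stop("duplicate (chain, residue number) in CalphaModel")
  structure(list(xyz = unname(xyz), resno = resno, chain = chain,
                 domain = domain),
            class = "CalphaModel")
}

#' @export
print.CalphaModel <- function(x, ...) {
  cat(sprintf("CalphaModel: %d residues, domains: %s\n", nrow(x$xyz),
              paste(sprintf("%s(%d)", names(table(x$domain)),
                            as.integer(table(x$domain))), collapse = " ")))
  invisible(x)
}

#' Extract a Calpha model from a Structure
#'
#' Residues lacking a Calpha atom are dropped and listed in the attached
#' gap report. A domain map assigns a label to inclusive residue-number
#' ranges (author numbering); unmapped residues get label `"other"`.
#'
#' @param s A `Structure`.
#' @param chains Chains to keep (default all).
#' @param domain_map Named list of `c(first, last)` residue ranges, e.g.
#'   `list("4HB" = c(2, 154), brace = c(155, 189), PsKD = c(190, 471))`.
#' @return A `CalphaModel` with attribute `gap_report` (data frame of
#'   residues without a Calpha).
#' @export
extract_calpha <- function(s, chains = NULL, domain_map = NULL) {
  stopifnot(inherits(s, "Structure"))
  at <- s$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0) stop("empty selection: no atoms in requested chains")
  res <- at[!duplicated(paste(at$chain, at$resno)), c("chain", "resno")]
  ca <- at[at$atom == "CA", , drop = FALSE]
  gap <- res[!paste(res$chain, res$resno) %in% paste(ca$chain, ca$resno), ,
             drop = FALSE]
  if (nrow(ca) == 0) stop("empty selection: no Calpha atoms present")
  dom <- rep("other", nrow(ca))
  if (!is.null(domain_map)) {
    for (lab in names(domain_map)) {
      rng <- domain_map[[lab]]
      dom[ca$resno >= rng[1] & ca$resno <= rng[2]] <- lab
    }
  }
  m <- calpha_model(as.matrix(ca[, c("x", "y", "z")]), resno = ca$resno,
                    chain = ca$chain, domain = dom)
  attr(m, "gap_report") <- gap
  m
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Rotation and translation minimizing the RMSD between paired Calpha
#' positions, solved in closed form by SVD with the proper-rotation
#' (det +1) correction. Default pairing matches identical residue numbers
#' present in both models.
#'
#' @param mobile,target `CalphaModel`s.
#' @param pairing Optional 2-column matrix of row indices (mobile, target).
#' @return A `Superposition`: list with `rotation` (3 x 3), `translation`,
#'   `rmsd` (angstrom), `n` (paired residues). Apply as
#'   `xyz %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, target, pairing = NULL) {
  stopifnot(inherits(mobile, "CalphaModel"), inherits(target, "CalphaModel"))
  if (is.null(pairing)) {
    common <- intersect(mobile$resno, target$resno)
    pairing <- cbind(match(common, mobile$resno), match(common, target$resno))
  }
  pairing <- as.matrix(pairing)
  if (nrow(pairing) < 3)
    stop("degenerate geometry: need at least 3 paired residues")
  X <- mobile$xyz[pairing[, 1], , drop = FALSE]
  Y <- target$xyz[pairing[, 2], , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv_x <- svd(Xc)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1))
    stop("degenerate geometry: paired residues are collinear")
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- cy - drop(R %*% cx)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(list(rotation = R, translation = t_, rmsd = rmsd,
                 n = nrow(pairing)),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.3f A over %d residues\n", x$rmsd, x$n))
  invisible(x)
}

# Apply a rigid transform to a CalphaModel.
transform_model <- function(m, rotation = diag(3), translation = c(0, 0, 0)) {
  m$xyz <- m$xyz %*% t(rotation) +
    matrix(translation, nrow(m$xyz), 3, byrow = TRUE)
  m
}

#' Minimum Calpha-Calpha distance between two labelled domains
#'
#' @param m A `CalphaModel`.
#' @param labelA,labelB Domain labels.
#' @return Minimum distance in angstrom over all cross-domain pairs.
#' @export
min_interdomain_distance <- function(m, labelA, labelB) {
  stopifnot(inherits(m, "CalphaModel"))
  ia <- which(m$domain == labelA)
  ib <- which(m$domain == labelB)
  if (length(ia) == 0) stop("domain label not present: ", labelA)
  if (length(ib) == 0) stop("domain label not present: ", labelB)
  A <- m$xyz[ia, , drop = FALSE]
  B <- m$xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

# CalphaModel -> Structure (CA-only), for PDB export of models/assemblies.
calpha_to_structure <- function(m, bfac = 0) {
  stopifnot(inherits(m, "CalphaModel"))
  n <- nrow(m$xyz)
  new_structure(data.frame(
    chain = m$chain, resno = m$resno, resname = "ALA", atom = "CA",
    x = m$xyz[, 1], y = m$xyz[, 2], z = m$xyz[, 3],
    occ = 1, bfac = rep_len(bfac, n), element = "C",
    stringsAsFactors = FALSE))
}

# Pairwise distance between residue sets of two models (used by the
# crosslink mapper and the tetramer restraints).
cross_distance <- function(xyzA, xyzB) {
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") - 2 * xyzA %*% t(xyzB)
  sqrt(pmax(d2, 0))
}
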