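test_that("PDB text reads back identically and round-trips coordinates", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.500   2.500   3.500  1.00 10.00           C",
    "ATOM      3  CA  GLY A   2       4.250   5.125   6.375  1.00 11.00           C",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 3)
  expect_equal(sort(unique(s$atoms$resno)), c(1, 2))
  expect_equal(s$sequence$A$aa, c("A", "G"))
  # write-then-read reproduces coordinates to PDB precision (3 decimals)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f2)
  s2 <- read_structure(f2)
  expect_equal(unname(as.matrix(s2$atoms[, c("x", "y", "z")])),
               unname(as.matrix(s$atoms[, c("x", "y", "z")])),
               tolerance = 1e-3)
  # idempotence of extraction through a write/read cycle
  m1 <- extract_calpha(s)
  m2 <- extract_calpha(s2)
  expect_equal(m1$xyz, m2$xyz, tolerance = 1e-3)
})

test_that("mmCIF atom_site loops parse, altlocs resolve by occupancy", {
  cif <- c("data_x", "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_alt_id",
           "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "ATOM 1 C CA A ALA A 1 1.0 2.0 3.0 0.40 10.0",
           "ATOM 2 C CA B ALA A 1 9.0 9.0 9.0 0.60 10.0",
           "ATOM 3 C CA . GLY A 2 4.0 5.0 6.0 1.00 11.0", "#")
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 2)
  # higher-occupancy altloc kept
  expect_equal(s$atoms$x[s$atoms$resno == 1], 9.0)
  expect_error(read_structure(withr::local_tempfile(fileext = ".cif")),
               "file not found")
})

test_that("extract_calpha reports gaps and maps domains", {
  at <- data.frame(chain = "A", resno = rep(1:3, each = 2),
                   resname = "ALA",
                   atom = rep(c("N", "CA"), 3),
                   x = as.numeric(1:6), y = 0, z = 0, occ = 1, bfac = 0,
                   element = "C")
  at <- at[!(at$resno == 2 & at$atom == "CA"), ]  # residue 2 lacks CA
  s <- tetraconf:::new_structure(at)
  m <- extract_calpha(s)
  expect_equal(nrow(m$xyz), 2)
  expect_equal(attr(m, "gap_report")$resno, 2)
  # hMLKL-style domain map partitions the residues
  b <- make_helix_bundle(30, seed = 1)
  s2 <- tetraconf:::calpha_to_structure(b)
  m2 <- extract_calpha(s2, domain_map = list("4HB" = c(1, 10),
                                             brace = c(11, 15),
                                             PsKD = c(16, 30)))
  expect_equal(as.vector(table(m2$domain)[c("4HB", "brace", "PsKD")]),
               c(10, 5, 15))
  expect_error(extract_calpha(s, chains = "Z"), "empty selection")
})

test_that("Kabsch superposition: identity, rigid recovery, oracle rmsd", {
  m <- make_helix_bundle(25, seed = 3)
  expect_equal(kabsch_superpose(m, m)$rmsd, 0, tolerance = 1e-9)
  R <- tetraconf:::euler_zyz(0.7, 0.4, -0.9)
  m2 <- tetraconf:::transform_model(m, R, c(5, -3, 11))
  expect_lt(kabsch_superpose(m2, m)$rmsd, 1e-6)
  # 4-point toy, one point perturbed by 1 A: compare with brute-force
  # minimization over rotations (grid + local refinement)
  X <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
  Y <- X
  Y[2, ] <- Y[2, ] + c(1, 0, 0)
  sup <- kabsch_superpose(calpha_model(X, 1:4), calpha_model(Y, 1:4))
  brute <- function(X, Y) {
    obj <- function(p) {
      R <- tetraconf:::euler_zyz(p[1], p[2], p[3])
      Xr <- sweep(X, 2, colMeans(X)) %*% t(R)
      Yc <- sweep(Y, 2, colMeans(Y))
      sqrt(mean(rowSums((Xr - Yc)^2)))
    }
    best <- Inf
    for (a in seq(0, 2 * pi, length.out = 7))
      for (b in seq(0, pi, length.out = 5))
        for (g in seq(0, 2 * pi, length.out = 7)) {
          o <- stats::optim(c(a, b, g), obj, method = "Nelder-Mead",
                            control = list(reltol = 1e-12))
          if (o$value < best) best <- o$value
        }
    best
  }
  expect_equal(sup$rmsd, brute(X, Y), tolerance = 1e-5)
  expect_error(kabsch_superpose(calpha_model(X[1:2, ] + 0, 1:2),
                                calpha_model(Y[1:2, ] + 0, 1:2)),
               "degenerate")
})

test_that("superposition rmsd is invariant under rigid transforms of inputs", {
  m <- make_helix_bundle(20, seed = 5)
  n <- nrow(m$xyz)
  pert <- m
  pert$xyz <- pert$xyz + matrix(stats::rnorm(3 * n, 0, 0.5), n, 3)
  base <- kabsch_superpose(pert, m)$rmsd
  for (k in 1:5) {
    R <- tetraconf:::euler_zyz(k, k / 2, -k)
    r1 <- kabsch_superpose(tetraconf:::transform_model(pert, R, c(k, 0, -k)),
                           m)$rmsd
    r2 <- kabsch_superpose(pert,
                           tetraconf:::transform_model(m, R, c(0, k, k)))$rmsd
    expect_equal(r1, base, tolerance = 1e-6)
    expect_equal(r2, base, tolerance = 1e-6)
  }
})

test_that("min_interdomain_distance matches the exhaustive oracle and is symmetric", {
  m <- two_point_model(gap = 10)
  expect_equal(min_interdomain_distance(m, "A", "B"), 10)
  expect_equal(min_interdomain_distance(m, "B", "A"), 10)
  overlapping <- calpha_model(rbind(c(0, 0, 0), c(0, 0, 0) + 1e-12,
                                    c(5, 0, 0)),
                              resno = 1:3, domain = c("A", "B", "B"))
  expect_equal(min_interdomain_distance(overlapping, "A", "B"), 0,
               tolerance = 1e-9)
  # random 20+20 toy vs O(N^2) loop
  set.seed(42)
  xyz <- matrix(stats::rnorm(120, 0, 20), 40, 3)
  m2 <- calpha_model(xyz, 1:40, domain = rep(c("A", "B"), each = 20))
  oracle <- Inf
  for (i in 1:20) for (j in 21:40)
    oracle <- min(oracle, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  expect_equal(min_interdomain_distance(m2, "A", "B"), oracle)
  expect_error(min_interdomain_distance(m2, "A", "C"), "label not present")
})

test_that("write_residue_map paints scalars into the B-factor column", {
  b <- make_helix_bundle(20, seed = 2)
  s <- tetraconf:::calpha_to_structure(b)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_residue_map(s, data.frame(chain = "A", resno = 1:20, value = 0), f)
  expect_true(all(read_structure(f)$atoms$bfac == 0))
  write_residue_map(s, data.frame(chain = "A", resno = 10, value = 25), f)
  back <- read_structure(f)$atoms
  expect_true(all(back$bfac[back$resno == 10] == 25))
  expect_true(all(back$bfac[back$resno != 10] == -1))
  # differential HDX profile round trip to 0.01
  truth <- data.frame(residue = 1:20,
                      percent_D = round(stats::runif(20, 0, 100), 2))
  tab <- suppressWarnings(make_hdx_table(truth, noise_sd = 0, seed = 4))
  prof <- per_residue_profile(tab, 300)
  write_residue_map(s, data.frame(chain = "A", resno = prof$residue,
                                  value = prof$mean_D), f)
  back <- read_structure(f)$atoms
  got <- back$bfac[back$atom == "CA"][match(prof$residue,
                                            back$resno[back$atom == "CA"])]
  expect_equal(got, prof$mean_D, tolerance = 0.011)
})
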