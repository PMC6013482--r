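test_that("guinier_fit: exact Gaussian curve, analytic sphere, error path", {
  q <- seq(0.002, 0.05, length.out = 80)
  exact <- saxs_curve(q, 100 * exp(-q^2 * 50^2 / 3), rep(0.1, 80))
  g <- guinier_fit(exact)
  expect_equal(g$Rg, 50, tolerance = 1e-6)
  expect_equal(g$I0, 100, tolerance = 1e-6)
  expect_lte(g$qmax_rg, 1.3)
  # sphere of radius 40: Rg = 40 sqrt(3/5), within 1%
  sph <- sphere_curve(R = 40)
  expect_equal(guinier_fit(sph)$Rg, 40 * sqrt(3 / 5), tolerance = 0.01)
  # monotonically increasing intensity has no Guinier region
  rising <- saxs_curve(q, 1 + q, rep(0.01, 80))
  expect_error(guinier_fit(rising), "no Guinier region")
})

test_that("pofr_transform recovers the sphere distance distribution", {
  sph <- sphere_curve(R = 40)
  p <- pofr_transform(sph, dmax = 80)
  expect_equal(p$P[1], 0)
  expect_equal(p$P[length(p$P)], 0)
  expect_true(all(p$P >= 0))
  ref <- sphere_pofr(p$r, 40)
  expect_lt(max(abs(p$P / max(p$P) - ref / max(ref))), 0.02)
  # self-consistency: back-transform fits noise-free data
  expect_lte(p$chi, 1.5)
  # real-space Rg close to the coordinate value
  expect_equal(p$Rg, 40 * sqrt(3 / 5), tolerance = 0.02)
  expect_error(pofr_transform(sph, 80, alpha = 0), "alpha > 0")
})

test_that("P(r) integral is proportional to the zero-angle intensity", {
  sph <- sphere_curve(R = 30)
  p <- pofr_transform(sph, dmax = 60)
  integral <- sum(p$P) * diff(p$r[1:2])
  i0 <- guinier_fit(sph)$I0
  expect_equal(integral, i0, tolerance = 0.01)
})

test_that("estimate_dmax brackets the true size and rejects pure noise", {
  sph <- sphere_curve(R = 40)
  dm <- estimate_dmax(sph, scan = seq(40, 150, by = 5))
  expect_lt(abs(dm - 80) / 80, 0.10)
  # two-point dumbbell at 100 A
  q <- seq(0.005, 0.3, length.out = 200)
  I2 <- 2 + 2 * tetraconf:::sinc(q * 100)
  dumb <- saxs_curve(q, I2, rep(0.02, 200))
  dm2 <- estimate_dmax(dumb, scan = seq(60, 150, by = 5))
  expect_lt(abs(dm2 - 100), 11)   # within grid resolution of the spike
  # pure noise never satisfies the decay + residual criteria
  set.seed(1)
  noise <- saxs_curve(q, stats::rnorm(200, 0, 1), rep(0.5, 200))
  expect_error(estimate_dmax(noise, scan = seq(40, 120, by = 10)),
               "unbounded Dmax")
})

test_that("debye_scatter: closed forms and rigid-transform invariance", {
  q <- seq(0.01, 0.3, length.out = 40)
  one <- debye_scatter(matrix(c(0, 0, 0), 1, 3), q)
  expect_true(all(one$I == 1))
  d <- 25
  two <- debye_scatter(rbind(c(0, 0, 0), c(d, 0, 0)), q)
  expect_equal(two$I, 2 + 2 * sin(q * d) / (q * d), tolerance = 1e-12)
  # I(0) = (sum f)^2 with non-unit form factors
  withf <- debye_scatter(rbind(c(0, 0, 0), c(5, 0, 0)), 1e-8, f = c(2, 3))
  expect_equal(withf$I, 25, tolerance = 1e-6)
  # rigid transforms leave the curve unchanged
  b <- make_helix_bundle(30, seed = 5)
  base <- debye_scatter(b, q)$I
  br <- tetraconf:::transform_model(b, tetraconf:::euler_zyz(1, 0.5, 2),
                                    c(30, -10, 5))
  expect_equal(debye_scatter(br, q)$I, base, tolerance = 1e-9)
  # Guinier Rg of a computed curve matches the coordinate Rg within 1%
  crv <- debye_scatter(b, seq(0.005, 0.1, length.out = 60),
                       sigma = 0.005)
  expect_equal(guinier_fit(crv)$Rg, tetraconf:::coord_rg(b),
               tolerance = 0.01)
})

test_that("chi_fit: scale invariance and a hand-computed case", {
  q <- seq(0.01, 0.1, length.out = 20)
  model <- saxs_curve(q, exp(-q * 10), rep(0.01, 20))
  data1 <- saxs_curve(q, exp(-q * 10), rep(0.01, 20))
  f1 <- chi_fit(model, data1)
  expect_equal(f1$chi, 0, tolerance = 1e-9)
  expect_equal(f1$scale, 1, tolerance = 1e-12)
  data2 <- saxs_curve(q, 2 * exp(-q * 10), rep(0.01, 20))
  f2 <- chi_fit(model, data2)
  expect_equal(f2$chi, 0, tolerance = 1e-9)
  expect_equal(f2$scale, 2, tolerance = 1e-12)
  # 3-point hand oracle: I_m = (1,2,3), I_d = (2,3,5), sigma = 1
  qq <- c(0.01, 0.02, 0.03)
  m3 <- saxs_curve(qq, c(1, 2, 3), c(1, 1, 1))
  d3 <- saxs_curve(qq, c(2, 3, 5), c(1, 1, 1))
  sc <- (2 * 1 + 3 * 2 + 5 * 3) / (1 + 4 + 9)   # 23/14
  chi <- sqrt(((2 - sc)^2 + (3 - 2 * sc)^2 + (5 - 3 * sc)^2) / 2)
  f3 <- chi_fit(m3, d3)
  expect_equal(f3$scale, sc)
  expect_equal(f3$chi, chi)
  expect_error(chi_fit(m3, d3[1, ]), "at least 2")
})

test_that("assemble_c4 is exactly four-fold symmetric", {
  prot <- make_helix_bundle(30, seed = 3)
  asm <- assemble_c4(prot, list(angles = c(0.7, 0.2, -0.4), rho = 15))
  expect_equal(length(asm), 4)
  expect_equal(sum(vapply(asm, function(p) nrow(p$xyz), 0)),
               4 * nrow(prot$xyz))
  rot <- tetraconf:::assembly_xyz(asm) %*% t(tetraconf:::rot_z(pi / 2))
  perm <- rbind(asm[[2]]$xyz, asm[[3]]$xyz, asm[[4]]$xyz, asm[[1]]$xyz)
  expect_lt(max(abs(rot - perm)), 1e-9)
  # single-point protomer at rho = 10: adjacent copies are 10*sqrt(2) apart
  pt <- calpha_model(rbind(c(0, 0, 0), c(0, 0, 3.8)), resno = 1:2)
  asm2 <- assemble_c4(pt, list(angles = c(0, 0, 0), rho = 10))
  expect_equal(sqrt(sum((asm2[[1]]$xyz[1, ] - asm2[[2]]$xyz[1, ])^2)),
               10 * sqrt(2), tolerance = 1e-9)
  # homotypic restraint distances are equal for all neighbouring pairs
  d12 <- sqrt(sum((asm[[1]]$xyz[10, ] - asm[[2]]$xyz[10, ])^2))
  d23 <- sqrt(sum((asm[[2]]$xyz[10, ] - asm[[3]]$xyz[10, ])^2))
  expect_equal(d12, d23, tolerance = 1e-9)
})

test_that("restraint penalty makes a violating pose score strictly worse", {
  sc <- fixture_scenario()
  spec_tight <- restraint_spec(residues = sc$restraint_residues, bound = 35)
  spec_loose <- restraint_spec(residues = sc$restraint_residues, bound = 1e6)
  pose_bad <- c(0.4, 0.3, 0.2, 40)   # rho far out: restraints > 35
  obj_tight <- tetraconf:::tetramer_objective(pose_bad, sc$protomer,
                                              sc$curve, spec_tight)
  obj_loose <- tetraconf:::tetramer_objective(pose_bad, sc$protomer,
                                              sc$curve, spec_loose)
  d <- tetraconf:::homotypic_distances(
    assemble_c4(sc$protomer, list(angles = pose_bad[1:3], rho = 40)),
    sc$restraint_residues)
  expect_true(any(d > 35))
  expect_gt(obj_tight, obj_loose)   # identical chi, extra penalty only
  expect_equal(obj_tight - obj_loose, 10 * sum(pmax(d - 35, 0)^2),
               tolerance = 1e-9)
})

test_that("rigid_body_fit recovers the synthetic C4 target and is reproducible", {
  sc <- fixture_scenario()
  fit <- fixture_tetramer_fit()
  expect_lte(fit$chi, 1.5)
  expect_true(all(fit$restraint_distances <= 35))
  fit2 <- rigid_body_fit(sc$protomer, sc$curve,
                         restraint_spec(residues = sc$restraint_residues),
                         seed = 42, steps = 400)
  expect_identical(fit$pose, fit2$pose)       # bit-for-bit given the seed
  expect_identical(fit$trace, fit2$trace)
  # C4 symmetry exact in the returned model
  rot <- tetraconf:::assembly_xyz(fit$assembly) %*%
    t(tetraconf:::rot_z(pi / 2))
  perm <- rbind(fit$assembly[[2]]$xyz, fit$assembly[[3]]$xyz,
                fit$assembly[[4]]$xyz, fit$assembly[[1]]$xyz)
  expect_lt(max(abs(rot - perm)), 1e-9)
})

test_that("refine_restrained: fixed point at the target, descent from afar, k->0 limit", {
  prot <- calpha_model(rbind(c(0, 0, 0), c(0, 0, 3.8)), resno = 1:2)
  mk <- function(rho) {
    structure(list(protomer = prot, pose = list(angles = c(0, 0, 0),
                                                rho = rho),
                   assembly = assemble_c4(prot, list(angles = c(0, 0, 0),
                                                     rho = rho)),
                   chi = NA, scale = NA, restraint_distances = NA,
                   objective = NA, trace = NULL, seed = 1),
              class = "TetramerModel")
  }
  spec <- restraint_spec(residues = 1, target = 30)
  at30 <- refine_restrained(mk(30 / sqrt(2)), spec)
  expect_equal(at30$pose$rho, 30 / sqrt(2), tolerance = 1e-4)
  expect_equal(at30$restraint_distances, 30, tolerance = 1e-3)
  from40 <- refine_restrained(mk(40 / sqrt(2)), spec)
  expect_lt(abs(from40$restraint_distances - 30), 10)
  en <- attr(from40, "energies")
  expect_lte(en["after"], en["before"])
  # k -> 0 limit reproduces the clash-only optimum: start from a
  # clashing pose and compare with an explicit clash-only minimization
  prot2 <- make_helix_bundle(30, seed = 12)
  mk2 <- function(rho) {
    structure(list(protomer = prot2, pose = list(angles = c(0, 0, 0),
                                                 rho = rho),
                   assembly = assemble_c4(prot2, list(angles = c(0, 0, 0),
                                                      rho = rho)),
                   chi = NA, scale = NA, restraint_distances = NA,
                   objective = NA, trace = NULL, seed = 1),
              class = "TetramerModel")
  }
  spec_zero <- restraint_spec(residues = 1, target = 30, k = 0)
  r_zero <- refine_restrained(mk2(2), spec_zero)
  clash_only <- function(p) {
    asm <- assemble_c4(prot2, list(angles = p[1:3], rho = max(p[4], 0)))
    10 * tetraconf:::clash_penalty(asm)
  }
  oracle <- stats::optim(c(0, 0, 0, 2), clash_only, method = "Nelder-Mead",
                         control = list(maxit = 300, reltol = 1e-10))
  expect_equal(r_zero$pose$rho, max(oracle$par[4], 0), tolerance = 1e-6)
  expect_equal(clash_only(c(r_zero$pose$angles, r_zero$pose$rho)),
               oracle$value, tolerance = 1e-6)
})
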