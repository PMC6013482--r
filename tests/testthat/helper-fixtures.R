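# Shared fixtures. The two expensive computations (dumbbell closure
# tracking, C4 rigid-body fit) are cached so module tests and the
# acceptance suite reuse one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

fixture_dumbbell <- function() cached("dumbbell", make_two_domain_toy(seed = 7))

fixture_closure <- function() {
  cached("closure", track_closure(fixture_dumbbell(), "A", "B",
                                  step = 1, n_modes = 25, max_iter = 800))
}

fixture_scenario <- function() cached("scenario",
                                      scenario_tetramer_recovery(seed = 11))

fixture_tetramer_fit <- function() {
  cached("tetramer_fit", {
    sc <- fixture_scenario()
    rigid_body_fit(sc$protomer, sc$curve,
                   restraint_spec(residues = sc$restraint_residues),
                   seed = 42, steps = 400)
  })
}

# Analytic sphere scattering curve (radius R), mixed error model.
sphere_curve <- function(R = 40, I0 = 100, qmax = 0.25, n = 150) {
  q <- seq(0.004, qmax, length.out = n)
  I <- I0 * (3 * (sin(q * R) - q * R * cos(q * R)) / (q * R)^3)^2
  saxs_curve(q, I, 0.01 * I + 0.001 * I0)
}

# Closed-form sphere pair-distance distribution on a given r grid.
sphere_pofr <- function(r, R) {
  u <- r / (2 * R)
  p <- r^2 * (1 - 1.5 * u + 0.5 * u^3)
  p[u > 1] <- 0
  p
}

# Two-residue-per-domain toy with a known inter-domain gap.
two_point_model <- function(gap = 10) {
  calpha_model(rbind(c(0, 0, 0), c(3.8, 0, 0),
                     c(3.8 + gap, 0, 0), c(7.6 + gap, 0, 0)),
               resno = 1:4, domain = c("A", "A", "B", "B"))
}
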