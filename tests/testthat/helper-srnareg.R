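# Shared fixtures: random parameter draws from the GSA sampling box and the
# Ishigami benchmark for the Sobol estimators.

draw_box_params <- function(n, seed) {
  sample_parameters(default_sampling_spec(), n, seed = seed)
}

row_as_params <- function(row) {
  do.call(srna_params, as.list(row[PARAM_NAMES]))
}

# long-time integration oracle for steady states (independent of the
# bisection solver)
integrate_to_steady <- function(params, topology = srna_topology(),
                                t_end = 1e7) {
  p <- unclass(params)
  rhs <- function(t, y, parms) list(srnareg:::derivatives_raw(y, p, topology))
  y0 <- unclass(baseline_steady_state(params))
  y0["s"] <- 0
  sol <- deSolve::ode(y0, c(0, t_end), rhs, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-12)
  sol[2, SPECIES_NAMES]
}

ishigami <- function(X, a = 7, b = 0.1) {
  sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
}

ishigami_spec <- function() {
  validate <- srnareg:::validate_sampling_spec
  validate(data.frame(name = c("x1", "x2", "x3"), dist = "uniform",
                      lower = -pi, upper = pi))
}

# analytic first-order variance decomposition of the Ishigami function
ishigami_S1 <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V <- a^2 / 8 + b * pi^4 / 5 + b^2 * pi^8 / 18 + 0.5
  c(V1 / V, V2 / V, 0)
}
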