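test_that("derivatives reproduce the mass-action terms", {
  p <- default_params()
  topo <- srna_topology()

  # empty cell: only synthesis fluxes are active
  d0 <- derivatives(srna_state(), p, topo)
  expect_equal(d0[["mpre"]], 1.8)
  expect_equal(d0[["s"]], 0.36)
  expect_equal(unname(d0[c("cpre", "m", "cm", "ctr", "p")]), rep(0, 5))

  # null system
  zero <- do.call(srna_params, as.list(setNames(rep(0, 13), PARAM_NAMES)))
  expect_equal(unname(unclass(derivatives(srna_state(), zero, topo))),
               rep(0, 7))

  # term-by-term hand evaluation at a mixed state
  st <- srna_state(mpre = 10, s = 100)
  d <- derivatives(st, p, topo)
  bind <- 0.0022 * 10 * 100
  expect_equal(d[["cpre"]], bind)  # 2.2
  expect_equal(d[["mpre"]], 1.8 - (0.064 + 0.0032) * 10 - bind)
  expect_equal(d[["m"]], 0.064 * 10)
  expect_equal(d[["s"]], 0.36 - 0.0015 * 100 - bind)
  expect_equal(d[["cm"]], 0)
  expect_equal(d[["ctr"]], 0)
  expect_equal(d[["p"]], 0)

  # richer state, every term written out independently
  st2 <- srna_state(mpre = 3, cpre = 2, m = 40, cm = 5, ctr = 1.5,
                    s = 20, p = 1e5)
  d2 <- derivatives(st2, p, topo)
  expect_equal(d2[["mpre"]], 1.8 - (0.064 + 0.0032) * 3 -
                 0.0022 * 3 * 20 + 0.3 * 2)
  expect_equal(d2[["cpre"]], 0.0022 * 3 * 20 -
                 (0.3 + 0.064 + 0.0032 + 0.68) * 2)
  expect_equal(d2[["m"]], 0.064 * 3 - 0.0032 * 40 - 0.0022 * 40 * 20 +
                 0.3 * 5)
  expect_equal(d2[["cm"]], 0.064 * 2 + 0.0022 * 40 * 20 -
                 (0.3 + 0.0063) * 5)
  expect_equal(d2[["ctr"]], 0.68 * 2 - (0.3 + 0.0063) * 1.5)
  expect_equal(d2[["s"]], 0.36 - 0.0015 * 20 - 0.0022 * (3 + 40) * 20 +
                 0.3 * (2 + 5 + 1.5))
  expect_equal(d2[["p"]], 14 * 40 + 1.96 * 5 - 0.00018 * 1e5)
})

test_that("topology flags gate the corresponding reactions", {
  p <- default_params()
  st <- srna_state(mpre = 3, cpre = 2, m = 40, cm = 5, ctr = 1.5,
                   s = 20, p = 1e5)
  # no recycling: ctr keeps its sRNA
  d <- derivatives(st, p, srna_topology(recycling_from_trunc = FALSE))
  expect_equal(d[["ctr"]], 0.68 * 2 - 0.0063 * 1.5)
  expect_equal(d[["s"]], 0.36 - 0.0015 * 20 - 0.0022 * (3 + 40) * 20 +
                 0.3 * (2 + 5))
  # no cotranscriptional regulation
  d <- derivatives(st, p, srna_topology(coreg_active = FALSE))
  expect_equal(d[["ctr"]], -(0.3 + 0.0063) * 1.5)
  expect_equal(d[["cpre"]], 0.0022 * 3 * 20 - (0.3 + 0.064 + 0.0032) * 2)
  # no mature binding: m and cm exchange no sRNA
  d <- derivatives(st, p, srna_topology(mature_binding = FALSE))
  expect_equal(d[["m"]], 0.064 * 3 - 0.0032 * 40)
  expect_equal(d[["cm"]], 0.064 * 2 - 0.0063 * 5)
  # no complex translation
  d <- derivatives(st, p, srna_topology(complex_translation = FALSE))
  expect_equal(d[["p"]], 14 * 40 - 0.00018 * 1e5)
})

test_that("invalid states and parameters are rejected by field name", {
  p <- default_params()
  st <- srna_state(mpre = 5)
  st_bad <- unclass(st); st_bad["cm"] <- -1
  expect_error(derivatives(st_bad, p), "cm")
  p_bad <- unclass(p); p_bad["beta_ms"] <- -0.1
  expect_error(derivatives(st, p_bad), "beta_ms")
  expect_error(srna_params(base = p, k_on = NaN), "k_on")
  expect_error(srna_params(k_init = 1), "missing parameters")
})

test_that("no species flows out of an empty pool", {
  set.seed(11)
  topo_grid <- list(srna_topology(),
                    srna_topology(recycling_from_trunc = FALSE),
                    srna_topology(mature_binding = FALSE),
                    srna_topology(coreg_active = FALSE,
                                  complex_translation = FALSE))
  pars <- draw_box_params(25, seed = 12)
  for (i in seq_len(nrow(pars))) {
    p <- row_as_params(pars[i, ])
    topo <- topo_grid[[1 + (i %% length(topo_grid))]]
    x <- setNames(runif(7, 0, 100), SPECIES_NAMES)
    for (sp in SPECIES_NAMES) {
      x0 <- x; x0[sp] <- 0
      d <- derivatives(x0, p, topo)
      expect_gte(d[[sp]], -1e-12)
    }
  }
})

test_that("total sRNA obeys the bookkeeping identity", {
  set.seed(21)
  pars <- draw_box_params(30, seed = 22)
  for (i in seq_len(nrow(pars))) {
    p <- row_as_params(pars[i, ])
    x <- srna_state(mpre = runif(1, 0, 50), cpre = runif(1, 0, 50),
                    m = runif(1, 0, 500), cm = runif(1, 0, 100),
                    ctr = runif(1, 0, 100), s = runif(1, 0, 500),
                    p = runif(1, 0, 1e6))
    d <- derivatives(x, p, srna_topology())
    total <- d[["s"]] + d[["cpre"]] + d[["cm"]] + d[["ctr"]]
    expected <- p[["alpha_s"]] - p[["beta_s"]] * x[["s"]] -
      p[["beta_ms"]] * (x[["cm"]] + x[["ctr"]]) -
      p[["beta_mpre"]] * x[["cpre"]]
    # large binding/release terms cancel in the sum, so allow float slack
    expect_equal(total, expected, tolerance = 1e-9)
  }
})

test_that("k_on = 0 decouples mRNA and protein from the sRNA", {
  p <- srna_params(base = default_params(), k_on = 0)
  x1 <- srna_state(mpre = 10, m = 200, s = 5, p = 1e4)
  x2 <- srna_state(mpre = 10, m = 200, s = 500, p = 1e4)
  d1 <- derivatives(x1, p); d2 <- derivatives(x2, p)
  expect_equal(d1[c("mpre", "m", "p")], d2[c("mpre", "m", "p")])
})

test_that("unit conversions match the molar/molecule correspondence", {
  # 1e3 and 1e8 M^-1 s^-1 at a 1e-15 L cell volume
  expect_equal(kon_molar_to_per_molecule(1e3, 1e-15), 1.66e-6,
               tolerance = 5e-3)
  expect_equal(kon_molar_to_per_molecule(1e8, 1e-15), 0.166,
               tolerance = 5e-3)
  expect_equal(kon_molar_to_per_molecule(0, 1e-15), 0)
  expect_error(kon_molar_to_per_molecule(1e3, 0), "volume")
  expect_error(kon_molar_to_per_molecule(-1), "non-negative")

  p <- default_params()
  expect_equal(kd_molar(p), (0.3 / 0.0022) / 6.022e8, tolerance = 1e-12)
  expect_equal(kd_molar(p), 2.26e-7, tolerance = 2e-3)
  expect_equal(kd_molar(srna_params(base = p, k_off = 0)), 0)
  # sampling-box extremes: tightest binder is ~3e-10 M
  expect_equal(kd_molar(srna_params(base = p, k_off = 0.03, k_on = 0.166)),
               3.0e-10, tolerance = 2e-3)
  expect_error(kd_molar(srna_params(base = p, k_on = 0)), "k_on")

  expect_equal(half_life(0.0023), log(2) / 0.0023)
  expect_equal(half_life(0.0023) / 60, 5, tolerance = 0.01)   # ~5 min
  expect_equal(half_life(0.06), 11.55, tolerance = 1e-3)      # ~10 s
  expect_equal(half_life(log(2)), 1)
  expect_error(half_life(0), "positive")
})

test_that("model configuration round-trips through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  p <- srna_params(base = default_params(), k_on = 0.01, beta_p = 0)
  topo <- srna_topology(recycling_from_trunc = FALSE,
                        complex_translation = FALSE)
  write_model_config(p, topo, path)
  cfg <- read_model_config(path)
  expect_equal(unclass(cfg$params), unclass(p))
  expect_equal(unclass(cfg$topology), unclass(topo))
})
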