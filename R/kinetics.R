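# Time-course simulation of the sRNA induction experiment and the four
# scenario variants (full model, no recycling, translation-only,
# stability + translation).

#' Named scenario presets for the induction experiment
#'
#' Returns the parameter set and topology of one of the four canonical
#' scenarios:
#' \describe{
#'   \item{full}{reference defaults, all topology flags on.}
#'   \item{no_recycling}{defaults, but the sRNA may not dissociate from the
#'     truncated mRNA/sRNA complex.}
#'   \item{translation_only}{no cotranscriptional regulation and no
#'     co-degradation beyond basal mRNA turnover (`k_coreg = 0`,
#'     `beta_ms = 0.0032`, `k_ms = 0`).}
#'   \item{stability_translation}{co-degradation plus translational
#'     repression without cotranscriptional regulation (`k_coreg = 0`,
#'     `beta_ms = 0.02`, `k_ms = 0.18`, `k_init = 1.2`).}
#' }
#'
#' @param name one of `"full"`, `"no_recycling"`, `"translation_only"`,
#'   `"stability_translation"`.
#' @return list with elements `name`, `params`, `topology`.
#' @export
#' @examples
#' scenario_preset("no_recycling")$topology
scenario_preset <- function(name) {
  valid <- c("full", "no_recycling", "translation_only",
             "stability_translation")
  if (length(name) != 1 || !name %in% valid)
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  params <- default_params()
  topology <- srna_topology()
  if (name == "no_recycling") {
    topology <- srna_topology(recycling_from_trunc = FALSE)
  } else if (name == "translation_only") {
    params <- srna_params(base = params, k_coreg = 0, beta_ms = 0.0032,
                          k_ms = 0)
  } else if (name == "stability_translation") {
    params <- srna_params(base = params, k_coreg = 0, beta_ms = 0.02,
                          k_ms = 0.18, k_init = 1.2)
  }
  list(name = name, params = params, topology = topology)
}

#' Pre-induction initial state
#'
#' The steady state of the cell before sRNA induction: no sRNA is present
#' (`alpha_s` effectively 0, hence no complexes), and mRNA/protein sit at
#' their unregulated baseline. Simulations of the induction experiment start
#' here with `alpha_s` switched to its scenario value at t = 0.
#'
#' @param params [srna_params()].
#' @return [srna_state()].
#' @export
initial_state_preinduction <- function(params) {
  p <- validate_params(params)
  st <- baseline_steady_state(srna_params(base = p, alpha_s = 0, k_on = 0))
  st[["s"]] <- 0
  validate_state(st)
}

#' Default output grid of the induction experiment
#'
#' 97 points over 0-1440 s (15 s spacing), covering the 24-minute
#' post-induction window.
#' @return numeric vector of times in seconds.
#' @export
default_time_grid <- function() seq(0, 1440, by = 15)

#' Simulate a time course of the regulation model
#'
#' Integrates the mass-action system with a stiff-capable solver
#' (`deSolve::ode`, lsoda) at relative tolerance 1e-10 and returns the
#' states on the requested grid.
#'
#' @param params [srna_params()].
#' @param topology [srna_topology()].
#' @param times strictly increasing time grid in seconds (the first entry
#'   is the time of the initial state).
#' @param initial initial [srna_state()]; defaults to the pre-induction
#'   steady state.
#' @param scenario optional scenario label stored with the trajectory.
#' @return data frame of class `"srna_trajectory"` with columns `time` and
#'   the 7 species.
#' @export
#' @examples
#' tr <- simulate_trajectory(default_params(), times = seq(0, 600, 60))
#' head(tr)
simulate_trajectory <- function(params, topology = srna_topology(),
                                times = default_time_grid(),
                                initial = initial_state_preinduction(params),
                                scenario = NA_character_) {
  p <- validate_params(params)
  initial <- validate_state(initial)
  if (length(times) < 1 || any(diff(times) <= 0))
    stop("times must be non-empty and strictly increasing")
  if (length(times) == 1) {
    out <- data.frame(time = times, t(unclass(initial)))
  } else {
    rhs <- function(t, y, parms) {
      y[y < 0] <- 0
      list(derivatives_raw(y, unclass(p), topology))
    }
    sol <- deSolve::ode(y = unclass(initial), times = times, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-10)
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failed for parameters: ",
           paste(sprintf("%s=%g", PARAM_NAMES, p), collapse = ", "))
    out <- as.data.frame(unclass(sol))
    out[SPECIES_NAMES] <- lapply(out[SPECIES_NAMES], function(v) pmax(v, 0))
  }
  attr(out, "scenario") <- scenario
  class(out) <- c("srna_trajectory", "data.frame")
  out
}

#' Simulate a named scenario of the induction experiment
#'
#' Convenience wrapper: fetches the [scenario_preset()], builds the
#' pre-induction initial state and simulates on the default 24-minute grid.
#'
#' @param name scenario name, see [scenario_preset()].
#' @param times time grid, default [default_time_grid()].
#' @return `"srna_trajectory"` data frame.
#' @export
simulate_scenario <- function(name, times = default_time_grid()) {
  sc <- scenario_preset(name)
  simulate_trajectory(sc$params, sc$topology, times = times,
                      scenario = sc$name)
}

#' Observable read-outs of a trajectory
#'
#' Collapses the species into what a typical induction experiment measures:
#' `observed_mrna = mpre + cpre + m + cm` (free and complexed full-length
#' mRNA; the truncated message is excluded), `observed_srna = s + cpre +
#' cm + ctr` (free and complexed sRNA, including sRNA trapped in truncated
#' complexes), and `protein = p`.
#'
#' @param trajectory `"srna_trajectory"` data frame.
#' @param include_trunc_in_mrna count truncated complexes toward observed
#'   mRNA as well, default `FALSE`.
#' @return data frame of class `"srna_observed"` with columns `time`,
#'   `observed_mrna`, `observed_srna`, `protein`.
#' @export
observe <- function(trajectory, include_trunc_in_mrna = FALSE) {
  need <- c("time", SPECIES_NAMES)
  if (!all(need %in% names(trajectory)))
    stop("trajectory must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(
    time = trajectory$time,
    observed_mrna = trajectory$mpre + trajectory$cpre + trajectory$m +
      trajectory$cm +
      if (include_trunc_in_mrna) trajectory$ctr else 0,
    observed_srna = trajectory$s + trajectory$cpre + trajectory$cm +
      trajectory$ctr,
    protein = trajectory$p)
  attr(out, "scenario") <- attr(trajectory, "scenario")
  class(out) <- c("srna_observed", "data.frame")
  out
}

#' Write a trajectory as tidy TSV
#'
#' Long format: one row per (time, species) pair with columns
#' `time`, `species`, `value`, `scenario`.
#'
#' @param trajectory `"srna_trajectory"` data frame.
#' @param path file to write.
#' @return the tidy data frame, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  scen <- attr(trajectory, "scenario")
  if (is.null(scen)) scen <- NA_character_
  long <- do.call(rbind, lapply(SPECIES_NAMES, function(sp) {
    data.frame(time = trajectory$time, species = sp,
               value = trajectory[[sp]], scenario = scen)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(long)
}
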