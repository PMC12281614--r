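# Reaction network of sRNA-mediated regulation: parameter/topology/state
# containers, the mass-action derivative function, and unit helpers.

#' Names of the 13 rate constants of the regulation model
#' @export
PARAM_NAMES <- c("k_init", "k_elon", "alpha_s", "k_on", "k_off", "k_coreg",
                 "beta_m", "beta_s", "beta_ms", "beta_mpre", "beta_p",
                 "k_m", "k_ms")

#' Names of the 7 molecular species
#'
#' `mpre` free precursor mRNA, `cpre` precursor/sRNA complex, `m` free mature
#' mRNA, `cm` mature mRNA/sRNA complex, `ctr` truncated mRNA/sRNA complex,
#' `s` free sRNA (all molecule counts), and `p` protein (arbitrary units).
#' @export
SPECIES_NAMES <- c("mpre", "cpre", "m", "cm", "ctr", "s", "p")

#' Default rate constants of the SgrS/ptsG-like reference parameterization
#'
#' The reference single-cell parameter set used throughout the package:
#' transcription initiation `k_init = 1.8` molecules/s, elongation/maturation
#' `k_elon = 0.064`/s, sRNA synthesis `alpha_s = 0.36` molecules/s,
#' association `k_on = 0.0022` per molecule per second, dissociation
#' `k_off = 0.3`/s, cotranscriptional regulation (processing + termination
#' lumped) `k_coreg = 0.68`/s, decay rates `beta_m = 0.0032`,
#' `beta_s = 0.0015`, `beta_ms = 0.0063`, `beta_mpre = 0.0032`,
#' `beta_p = 0.00018`/s, and translation rates `k_m = 14`, `k_ms = 1.96`
#' AU per molecule per second.
#'
#' @return A validated [srna_params()] object.
#' @export
#' @examples
#' default_params()
default_params <- function() {
  srna_params(k_init = 1.8, k_elon = 0.064, alpha_s = 0.36, k_on = 0.0022,
              k_off = 0.3, k_coreg = 0.68, beta_m = 0.0032, beta_s = 0.0015,
              beta_ms = 0.0063, beta_mpre = 0.0032, beta_p = 0.00018,
              k_m = 14, k_ms = 1.96)
}

#' Construct a parameter set for the regulation model
#'
#' Builds the named vector of the 13 rate constants. All values must be
#' finite and non-negative. Starting from an existing set (`base`), any
#' subset of parameters can be overridden by name.
#'
#' @param ... named rate constants (see [PARAM_NAMES]).
#' @param base optional existing parameter set to override; if `NULL` every
#'   parameter must be supplied.
#' @return A named numeric vector of class `"srna_params"`.
#' @export
#' @examples
#' srna_params(base = default_params(), k_on = 0)
srna_params <- function(..., base = NULL) {
  override <- list(...)
  if (is.null(base)) {
    vals <- override
    missing <- setdiff(PARAM_NAMES, names(vals))
    if (length(missing) > 0)
      stop("missing parameters: ", paste(missing, collapse = ", "))
  } else {
    base <- validate_params(base)
    vals <- as.list(base)
    vals[names(override)] <- override
  }
  unknown <- setdiff(names(vals), PARAM_NAMES)
  if (length(unknown) > 0)
    stop("unknown parameters: ", paste(unknown, collapse = ", "))
  p <- vapply(vals[PARAM_NAMES], function(x) as.numeric(x)[1], numeric(1))
  names(p) <- PARAM_NAMES
  class(p) <- "srna_params"
  validate_params(p)
}

#' @export
print.srna_params <- function(x, ...) {
  cat("<srna_params> 13 rate constants\n")
  print(unclass(x), ...)
  invisible(x)
}

validate_params <- function(params) {
  p <- unclass(params)
  if (!is.numeric(p) || is.null(names(p)))
    stop("parameters must be a named numeric vector")
  missing <- setdiff(PARAM_NAMES, names(p))
  if (length(missing) > 0)
    stop("missing parameters: ", paste(missing, collapse = ", "))
  p <- p[PARAM_NAMES]
  bad <- names(p)[!is.finite(p) | p < 0]
  if (length(bad) > 0)
    stop("parameters must be finite and non-negative; offending: ",
         paste(bad, collapse = ", "))
  class(p) <- "srna_params"
  p
}

#' Topology switches of the regulation model
#'
#' Selects which interactions of the reaction network are active. The
#' `"full"` topology (all flags `TRUE`) is the default.
#'
#' @param recycling_from_trunc may the sRNA dissociate from the truncated
#'   mRNA/sRNA complex (sRNA recycling)?
#' @param coreg_active is the cotranscriptional regulation reaction
#'   (`k_coreg`) enabled?
#' @param mature_binding may free mature mRNA bind the sRNA?
#' @param complex_translation is translation from the mature complex
#'   (`k_ms`) enabled?
#' @return A named logical vector of class `"srna_topology"`.
#' @export
srna_topology <- function(recycling_from_trunc = TRUE, coreg_active = TRUE,
                          mature_binding = TRUE, complex_translation = TRUE) {
  flags <- c(recycling_from_trunc = recycling_from_trunc,
             coreg_active = coreg_active,
             mature_binding = mature_binding,
             complex_translation = complex_translation)
  if (!is.logical(flags) || anyNA(flags))
    stop("topology flags must be TRUE/FALSE")
  class(flags) <- "srna_topology"
  flags
}

#' @export
print.srna_topology <- function(x, ...) {
  cat("<srna_topology>", paste(names(x), unclass(x), sep = "=",
                               collapse = " "), "\n")
  invisible(x)
}

#' Construct a state vector of the 7 molecular species
#'
#' @param mpre,cpre,m,cm,ctr,s molecule counts (see [SPECIES_NAMES]).
#' @param p protein, arbitrary units.
#' @return Named numeric vector of class `"srna_state"`.
#' @export
srna_state <- function(mpre = 0, cpre = 0, m = 0, cm = 0, ctr = 0,
                       s = 0, p = 0) {
  x <- c(mpre = mpre, cpre = cpre, m = m, cm = cm, ctr = ctr, s = s, p = p)
  validate_state(x)
}

validate_state <- function(state) {
  x <- unclass(state)
  if (!is.numeric(x) || is.null(names(x)))
    stop("state must be a named numeric vector")
  missing <- setdiff(SPECIES_NAMES, names(x))
  if (length(missing) > 0)
    stop("missing species: ", paste(missing, collapse = ", "))
  x <- x[SPECIES_NAMES]
  bad <- names(x)[!is.finite(x) | x < 0]
  if (length(bad) > 0)
    stop("state components must be finite and non-negative; offending: ",
         paste(bad, collapse = ", "))
  class(x) <- "srna_state"
  x
}

#' Time derivatives of the regulation model
#'
#' Evaluates the mass-action rate of change of each species. The reactions:
#' the precursor is initiated at `k_init`, matures at `k_elon`, decays
#' cotranscriptionally at `beta_mpre`, or binds free sRNA at `k_on` (reversed
#' at `k_off`). The bound precursor matures into the mature complex or is
#' processed/terminated at `k_coreg` into a truncated complex, from which the
#' sRNA is recycled by dissociation when the topology allows it. Mature
#' mRNA decays at `beta_m`; complexes are co-degraded at `beta_ms`
#' (destroying the bound sRNA with them). Protein is made at `k_m` from free
#' mature mRNA and `k_ms` from the mature complex and decays at `beta_p`.
#'
#' @param state non-negative [srna_state()].
#' @param params [srna_params()].
#' @param topology [srna_topology()]; flags gate the corresponding terms.
#' @return Named numeric vector of per-second derivatives, one per species.
#' @export
#' @examples
#' derivatives(srna_state(), default_params(), srna_topology())
derivatives <- function(state, params, topology = srna_topology()) {
  x <- validate_state(state)
  p <- validate_params(params)
  derivatives_raw(unclass(x), unclass(p), topology)
}

# unchecked core, shared with the deSolve right-hand side
derivatives_raw <- function(x, p, topology) {
  rec <- as.numeric(topology[["recycling_from_trunc"]])
  cor <- as.numeric(topology[["coreg_active"]])
  mb  <- as.numeric(topology[["mature_binding"]])
  ct  <- as.numeric(topology[["complex_translation"]])
  bind_pre <- p[["k_on"]] * x[["mpre"]] * x[["s"]]
  bind_m   <- mb * p[["k_on"]] * x[["m"]] * x[["s"]]
  c(mpre = p[["k_init"]] - (p[["k_elon"]] + p[["beta_mpre"]]) * x[["mpre"]] -
          bind_pre + p[["k_off"]] * x[["cpre"]],
    cpre = bind_pre - (p[["k_off"]] + p[["k_elon"]] + p[["beta_mpre"]] +
                         cor * p[["k_coreg"]]) * x[["cpre"]],
    m    = p[["k_elon"]] * x[["mpre"]] - p[["beta_m"]] * x[["m"]] -
          bind_m + mb * p[["k_off"]] * x[["cm"]],
    cm   = p[["k_elon"]] * x[["cpre"]] + bind_m -
          (mb * p[["k_off"]] + p[["beta_ms"]]) * x[["cm"]],
    ctr  = cor * p[["k_coreg"]] * x[["cpre"]] -
          (rec * p[["k_off"]] + p[["beta_ms"]]) * x[["ctr"]],
    s    = p[["alpha_s"]] - p[["beta_s"]] * x[["s"]] - bind_pre - bind_m +
          p[["k_off"]] * (x[["cpre"]] + mb * x[["cm"]] + rec * x[["ctr"]]),
    p    = p[["k_m"]] * x[["m"]] + ct * p[["k_ms"]] * x[["cm"]] -
          p[["beta_p"]] * x[["p"]])
}

#' Convert a molar association rate to single-cell molecule units
#'
#' Association rates measured in vitro (M^-1 s^-1) are converted to per
#' molecule per second in a cell of the given volume:
#' `kon / (N_A * volume)`, with Avogadro's number `N_A = 6.022e23`.
#'
#' @param kon_M association rate constant, M^-1 s^-1 (>= 0).
#' @param volume_L cell volume in litres (> 0), default 1e-15 L.
#' @return rate in molecules^-1 s^-1.
#' @export
#' @examples
#' kon_molar_to_per_molecule(1e3)   # 1.66e-6
#' kon_molar_to_per_molecule(1e8)   # 0.166
kon_molar_to_per_molecule <- function(kon_M, volume_L = 1e-15) {
  if (any(!is.finite(kon_M)) || any(kon_M < 0))
    stop("kon_M must be finite and non-negative")
  if (!is.finite(volume_L) || volume_L <= 0)
    stop("volume_L must be positive")
  kon_M / (.N_AVOGADRO * volume_L)
}

#' Molar dissociation constant of the sRNA-mRNA interaction
#'
#' `Kd = (k_off / k_on) / (N_A * volume)`, in molar units.
#'
#' @param params [srna_params()] with `k_on > 0`.
#' @param volume_L cell volume in litres, default 1e-15 L.
#' @return dissociation constant in M.
#' @export
kd_molar <- function(params, volume_L = 1e-15) {
  p <- validate_params(params)
  if (!is.finite(volume_L) || volume_L <= 0)
    stop("volume_L must be positive")
  if (p[["k_on"]] <= 0)
    stop("kd_molar is undefined for k_on = 0")
  (p[["k_off"]] / p[["k_on"]]) / (.N_AVOGADRO * volume_L)
}

#' Half-life of a first-order decay process
#'
#' @param rate decay rate constant, s^-1 (> 0); vectorized.
#' @return half-life `log(2)/rate` in seconds.
#' @export
#' @examples
#' half_life(0.0023) / 60   # ~5 minutes
half_life <- function(rate) {
  if (any(!is.finite(rate)) || any(rate <= 0))
    stop("rate must be positive")
  log(2) / rate
}

#' Write model configuration (parameters + topology) to JSON
#'
#' @param params [srna_params()].
#' @param topology [srna_topology()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, topology, path) {
  params <- validate_params(params)
  cfg <- list(parameters = as.list(unclass(params)),
              topology = as.list(unclass(topology)))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read model configuration from JSON
#'
#' @param path file written by [write_model_config()].
#' @return list with elements `params` and `topology`.
#' @export
read_model_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(srna_params, as.list(cfg$parameters))
  topology <- do.call(srna_topology, as.list(cfg$topology))
  list(params = params, topology = topology)
}
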