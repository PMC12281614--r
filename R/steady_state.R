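# Steady states of the regulation model and the log2 protein
# regulation-strength statistic.
#
# Given the free-sRNA level s, all mRNA species are linear in the remaining
# equations and solve in closed form; the sRNA balance then yields a scalar
# residual in s that is monotone decreasing and bracketed in
# [0, alpha_s/beta_s]. The solver bisects that bracket, vectorized across
# parameter sets so GSA designs with 1e5+ rows evaluate in one pass.

# Closed-form mRNA/complex/protein levels conditional on free sRNA s.
# P: list of equal-length numeric vectors (the 13 parameters); s: vector.
.species_given_s <- function(s, P, topology) {
  rec <- as.numeric(topology[["recycling_from_trunc"]])
  cor <- as.numeric(topology[["coreg_active"]])
  mb  <- as.numeric(topology[["mature_binding"]])
  ct  <- as.numeric(topology[["complex_translation"]])

  ks <- P$k_on * s
  Bc <- P$k_off + P$k_elon + P$beta_mpre + cor * P$k_coreg   # cpre sink
  # precursor balance with cpre = ks*mpre/Bc substituted
  eff <- ifelse(Bc > 0, 1 - P$k_off / Bc, 1)
  mpre <- P$k_init / (P$k_elon + P$beta_mpre + ks * eff)
  cpre <- ifelse(Bc > 0, ks * mpre / Bc, 0)

  kofm <- mb * P$k_off
  Dm <- kofm + P$beta_ms                                     # cm sink
  m <- (P$k_elon * mpre + kofm * P$k_elon * cpre / Dm) /
       (P$beta_m + mb * ks * P$beta_ms / Dm)
  cm <- (P$k_elon * cpre + mb * ks * m) / Dm

  Dtr <- rec * P$k_off + P$beta_ms                           # ctr sink
  ctr <- if (cor == 0) rep(0, length(mpre)) else cor * P$k_coreg * cpre / Dtr

  p <- (P$k_m * m + ct * P$k_ms * cm) / P$beta_p
  list(mpre = mpre, cpre = cpre, m = m, cm = cm, ctr = ctr, p = p)
}

# sRNA balance residual at free-sRNA level s (monotone decreasing in s)
.srna_residual <- function(s, P, topology) {
  rec <- as.numeric(topology[["recycling_from_trunc"]])
  mb  <- as.numeric(topology[["mature_binding"]])
  sp <- .species_given_s(s, P, topology)
  P$alpha_s - P$beta_s * s - P$k_on * (sp$mpre + mb * sp$m) * s +
    P$k_off * (sp$cpre + mb * sp$cm + rec * sp$ctr)
}

# Vectorized steady-state solver. P is a list of equal-length parameter
# vectors. Returns a list of species vectors (incl. s).
.steady_state_vec <- function(P, topology, max_iter = 120L) {
  n <- length(P$k_init)
  s_max <- ifelse(P$beta_s > 0, P$alpha_s / P$beta_s, 0)
  lo <- rep(0, n)
  hi <- s_max
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    pos <- .srna_residual(mid, P, topology) > 0
    lo <- ifelse(pos, mid, lo)
    hi <- ifelse(pos, hi, mid)
  }
  s <- (lo + hi) / 2
  sp <- .species_given_s(s, P, topology)
  c(list(s = s), sp)
}

.params_as_list <- function(params) {
  p <- unclass(validate_params(params))
  lapply(as.list(p), as.numeric)
}

#' Closed-form baseline steady state (no sRNA binding)
#'
#' The steady state of the decoupled system with `k_on = 0`:
#' `mpre* = k_init/(k_elon + beta_mpre)`, `m* = k_elon * mpre* / beta_m`,
#' `s* = alpha_s/beta_s`, `p* = k_m * m* / beta_p`, all complexes zero.
#'
#' @param params [srna_params()]; `k_elon + beta_mpre`, `beta_m` and
#'   `beta_p` must be positive, and `beta_s` must be positive when
#'   `alpha_s > 0`.
#' @return [srna_state()] at the baseline steady state.
#' @export
#' @examples
#' baseline_steady_state(default_params())
baseline_steady_state <- function(params) {
  p <- validate_params(params)
  if (p[["k_elon"]] + p[["beta_mpre"]] <= 0)
    stop("k_elon + beta_mpre must be positive for a baseline steady state")
  if (p[["beta_m"]] <= 0) stop("beta_m must be positive")
  if (p[["beta_p"]] <= 0) stop("beta_p must be positive")
  if (p[["alpha_s"]] > 0 && p[["beta_s"]] <= 0)
    stop("beta_s must be positive when alpha_s > 0")
  mpre <- p[["k_init"]] / (p[["k_elon"]] + p[["beta_mpre"]])
  m <- p[["k_elon"]] * mpre / p[["beta_m"]]
  s <- if (p[["alpha_s"]] > 0) p[["alpha_s"]] / p[["beta_s"]] else 0
  srna_state(mpre = mpre, m = m, s = s, p = p[["k_m"]] * m / p[["beta_p"]])
}

#' Steady state of the full regulation model
#'
#' Solves for the steady state by reducing the system to a scalar monotone
#' residual in the free-sRNA level, bracketed in `[0, alpha_s/beta_s]`, and
#' bisecting to machine precision; the remaining species follow in closed
#' form. The returned state is checked to have a scaled derivative max-norm
#' below `tol`.
#'
#' @param params [srna_params()].
#' @param topology [srna_topology()].
#' @param tol relative tolerance on the scaled derivative norm, default 1e-10.
#' @return [srna_state()] at the steady state.
#' @export
#' @examples
#' steady_state(default_params(), srna_topology())
steady_state <- function(params, topology = srna_topology(), tol = 1e-10) {
  p <- validate_params(params)
  if (p[["k_on"]] == 0 || p[["alpha_s"]] == 0) {
    st <- baseline_steady_state(p)
    if (p[["alpha_s"]] == 0) st[["s"]] <- 0
    return(validate_state(st))
  }
  if (p[["beta_s"]] <= 0) stop("beta_s must be positive when alpha_s > 0")
  if (p[["beta_m"]] <= 0) stop("beta_m must be positive")
  if (p[["beta_p"]] <= 0) stop("beta_p must be positive")
  if (p[["beta_ms"]] <= 0 && !(topology[["mature_binding"]] &&
                               p[["k_off"]] > 0))
    stop("beta_ms must be positive (mature complex has no other sink)")
  P <- .params_as_list(p)
  sol <- .steady_state_vec(P, topology)
  st <- srna_state(mpre = sol$mpre, cpre = sol$cpre, m = sol$m, cm = sol$cm,
                   ctr = sol$ctr, s = sol$s, p = sol$p)
  dx <- derivatives_raw(unclass(st), unclass(p), topology)
  scale <- pmax(abs(unclass(st)), 1e-30)
  resid <- max(abs(dx) / pmax(scale, max(scale) * 1e-12))
  if (!is.finite(resid) || resid > tol * 1e4)
    stop("steady-state solver failed to converge; scaled residual = ",
         format(resid), " (bracket residuals: ",
         format(.srna_residual(0, P, topology)), ", ",
         format(.srna_residual(P$alpha_s / P$beta_s, P, topology)), ")")
  st
}

#' Protein regulation strength: steady-state log2 ratio
#'
#' Regulation strength is the log2 ratio of the steady-state protein level
#' with the sRNA active to the level with binding disabled (`k_on = 0`):
#' negative values are repression, positive values activation. Fully
#' saturated repression (scenario protein underflows to zero) is reported
#' as the capped value (default -50) and flagged.
#'
#' @param params [srna_params()].
#' @param topology [srna_topology()].
#' @param cap value reported for saturated repression, default -50.
#' @return A list of class `"regulation_result"`: `p_scenario`,
#'   `p_baseline`, `log2_ratio`, `saturated`, and the scenario `steady`
#'   state.
#' @export
#' @examples
#' regulation_strength(default_params())$log2_ratio
regulation_strength <- function(params, topology = srna_topology(),
                                cap = -50) {
  p <- validate_params(params)
  base <- baseline_steady_state(p)
  p_base <- base[["p"]]
  if (p_base <= 0)
    stop("baseline protein level is zero; regulation strength undefined")
  st <- steady_state(p, topology)
  p_scen <- st[["p"]]
  saturated <- p_scen <= 0 || !is.finite(log2(p_scen / p_base)) ||
    log2(p_scen / p_base) < cap
  ratio <- if (saturated) cap else log2(p_scen / p_base)
  structure(list(p_scenario = p_scen, p_baseline = p_base,
                 log2_ratio = ratio, saturated = saturated, steady = st),
            class = "regulation_result")
}

#' @export
print.regulation_result <- function(x, ...) {
  cat(sprintf("<regulation_result> log2(p/p0) = %.4f (%s)\n", x$log2_ratio,
              if (x$log2_ratio < 0) "repression" else
                if (x$log2_ratio > 0) "activation" else "no net regulation"))
  cat(sprintf("  p_scenario = %.4g AU, p_baseline = %.4g AU\n",
              x$p_scenario, x$p_baseline))
  invisible(x)
}

#' Regulation strength for a batch of parameter sets
#'
#' Vectorized evaluation of the steady-state log2 regulation-strength
#' statistic over many parameter sets at once (one bisection pass across all
#' rows). This is the work-horse of the global sensitivity analysis.
#'
#' @param par_matrix numeric matrix or data frame with one column per
#'   parameter in [PARAM_NAMES] and one row per parameter set.
#' @param topology [srna_topology()].
#' @param cap saturation cap for the log2 ratio, default -50.
#' @return numeric vector of log2 ratios, one per row (`NA` for rows where
#'   the solve failed).
#' @export
regulation_strength_batch <- function(par_matrix,
                                      topology = srna_topology(),
                                      cap = -50) {
  par_matrix <- as.data.frame(par_matrix)
  missing <- setdiff(PARAM_NAMES, names(par_matrix))
  if (length(missing) > 0)
    stop("missing parameter columns: ", paste(missing, collapse = ", "))
  P <- lapply(par_matrix[PARAM_NAMES], as.numeric)
  for (nm in PARAM_NAMES)
    if (any(!is.finite(P[[nm]]) | P[[nm]] < 0))
      stop("parameters must be finite and non-negative; offending: ", nm)
  sol <- .steady_state_vec(P, topology)
  p_base <- P$k_m * (P$k_elon * P$k_init /
                       ((P$k_elon + P$beta_mpre) * P$beta_m)) / P$beta_p
  ratio <- log2(sol$p / p_base)
  ratio[P$k_on == 0] <- 0
  sat <- is.finite(p_base) & p_base > 0 & (!is.finite(ratio) | ratio < cap)
  ratio[sat] <- cap
  ratio[!is.finite(p_base) | p_base <= 0] <- NA_real_
  ratio
}

#' Export regulation results as a TSV row set
#'
#' @param results list of `"regulation_result"` objects (or a single one).
#' @param path file to write.
#' @return the data frame written, invisibly.
#' @export
write_regulation_tsv <- function(results, path) {
  if (inherits(results, "regulation_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(p_scenario = r$p_scenario, p_baseline = r$p_baseline,
               log2_ratio = r$log2_ratio, saturated = r$saturated,
               t(unclass(r$steady)))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
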