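# Variance-based global sensitivity analysis of regulation strength:
# sampling specification, Saltelli design, Sobol S1/ST estimators (Saltelli
# and Jansen), bootstrap confidence intervals and 2-D binned summaries.

#' Default sampling specification of the sensitivity analysis
#'
#' One row per model parameter with its sampling distribution:
#' `k_init` and `alpha_s` uniform on 0.1-2 molecules/s; `k_on` log-uniform on
#' 1.66e-6 to 0.166 molecules^-1 s^-1 (1e3-1e8 M^-1 s^-1 at a 1e-15 L cell
#' volume); `k_off` log-uniform on 0.03-100 s^-1; the RNA decay rates
#' `beta_m`, `beta_s`, `beta_ms`, `beta_mpre` log-uniform on 0.0023-0.06 s^-1
#' (half-lives of ~5 min down to ~10 s); `beta_p` log-uniform on 5e-4 to
#' 0.05 s^-1; `k_m` and `k_ms` uniform on 0.1-30 AU molecule^-1 s^-1.
#' `k_elon` (0.02-0.2 s^-1) and `k_coreg` (0.068-6.8 s^-1) are sampled
#' log-uniformly over one decade around the reference defaults; both ranges
#' are configurable through the returned data frame.
#'
#' @return data frame of class `"sampling_spec"` with columns `name`,
#'   `dist` (one of `"uniform"`, `"loguniform"`, `"fixed"`), `lower`,
#'   `upper`.
#' @export
#' @examples
#' default_sampling_spec()
default_sampling_spec <- function() {
  spec <- data.frame(
    name = c("k_init", "k_elon", "alpha_s", "k_on", "k_off", "k_coreg",
             "beta_m", "beta_s", "beta_ms", "beta_mpre", "beta_p",
             "k_m", "k_ms"),
    dist = c("uniform", "loguniform", "uniform", "loguniform", "loguniform",
             "loguniform", "loguniform", "loguniform", "loguniform",
             "loguniform", "loguniform", "uniform", "uniform"),
    lower = c(0.1, 0.02, 0.1, 1.66e-6, 0.03, 0.068,
              0.0023, 0.0023, 0.0023, 0.0023, 5e-4, 0.1, 0.1),
    upper = c(2, 0.2, 2, 0.166, 100, 6.8,
              0.06, 0.06, 0.06, 0.06, 0.05, 30, 30),
    stringsAsFactors = FALSE)
  validate_sampling_spec(spec)
}

validate_sampling_spec <- function(spec) {
  spec <- as.data.frame(spec)
  need <- c("name", "dist", "lower", "upper")
  if (!all(need %in% names(spec)))
    stop("sampling spec needs columns: ", paste(need, collapse = ", "))
  if (!all(spec$dist %in% c("uniform", "loguniform", "fixed")))
    stop("dist must be one of uniform, loguniform, fixed")
  varied <- spec$dist != "fixed"
  if (any(varied & !(spec$lower < spec$upper)))
    stop("lower < upper required for sampled parameters: ",
         paste(spec$name[varied & !(spec$lower < spec$upper)],
               collapse = ", "))
  if (any(spec$dist == "loguniform" & spec$lower <= 0))
    stop("log-uniform requires positive lower bound: ",
         paste(spec$name[spec$dist == "loguniform" & spec$lower <= 0],
               collapse = ", "))
  class(spec) <- c("sampling_spec", "data.frame")
  spec
}

# map unit-hypercube samples (matrix n x nrow(spec)) to parameter values
.map_unit_samples <- function(u, spec) {
  out <- matrix(NA_real_, nrow(u), nrow(spec),
                dimnames = list(NULL, spec$name))
  for (j in seq_len(nrow(spec))) {
    lo <- spec$lower[j]; hi <- spec$upper[j]
    out[, j] <- switch(spec$dist[j],
      uniform    = lo + u[, j] * (hi - lo),
      loguniform = exp(log(lo) + u[, j] * (log(hi) - log(lo))),
      fixed      = rep(lo, nrow(u)))
  }
  out
}

#' Draw independent Monte-Carlo samples of the model parameters
#'
#' Plain (non-Saltelli) random sampling from the per-parameter
#' distributions, for distribution summaries and threshold analyses.
#'
#' @param spec a `"sampling_spec"`, default [default_sampling_spec()].
#' @param n number of parameter sets.
#' @param seed optional integer seed.
#' @return data frame with one column per parameter, `n` rows.
#' @export
sample_parameters <- function(spec = default_sampling_spec(), n,
                              seed = NULL) {
  spec <- validate_sampling_spec(spec)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  u <- matrix(runif(n * nrow(spec)), nrow = n)
  as.data.frame(.map_unit_samples(u, spec))
}

#' Saltelli evaluation design for Sobol indices
#'
#' Builds the standard A/B/AB_i scheme: two independent base matrices A and
#' B of `n_base` rows each, plus for every varied parameter i a matrix AB_i
#' equal to A with column i taken from B. The total number of evaluation
#' rows is `n_base * (k + 2)` for `k` varied parameters. Unit-hypercube
#' draws are mapped through each parameter's distribution (log-uniform is
#' uniform on the log scale).
#'
#' @param spec a `"sampling_spec"`.
#' @param n_base base-sample count (>= 2).
#' @param seed integer seed; the design is reproducible for a fixed seed.
#' @return list of class `"saltelli_design"`: `rows` (evaluation matrix),
#'   `n_base`, `varied` (names of varied parameters), `spec`, `seed`,
#'   `block` (row labels `"A"`, `"B"`, `"AB:<name>"`).
#' @export
#' @examples
#' d <- saltelli_design(default_sampling_spec(), n_base = 64, seed = 1)
#' nrow(d$rows)  # 64 * (13 + 2)
saltelli_design <- function(spec = default_sampling_spec(), n_base,
                            seed = 1L) {
  spec <- validate_sampling_spec(spec)
  if (n_base < 2) stop("n_base must be >= 2")
  varied <- spec$name[spec$dist != "fixed"]
  k <- length(varied)
  if (k == 0) stop("no varied parameters in sampling spec")
  set.seed(seed)
  uA <- matrix(runif(n_base * nrow(spec)), nrow = n_base)
  uB <- matrix(runif(n_base * nrow(spec)), nrow = n_base)
  A <- .map_unit_samples(uA, spec)
  B <- .map_unit_samples(uB, spec)
  blocks <- vector("list", k + 2)
  blocks[[1]] <- A
  blocks[[2]] <- B
  labels <- c(rep("A", n_base), rep("B", n_base))
  for (i in seq_len(k)) {
    ABi <- A
    ABi[, varied[i]] <- B[, varied[i]]
    blocks[[i + 2]] <- ABi
    labels <- c(labels, rep(paste0("AB:", varied[i]), n_base))
  }
  structure(list(rows = do.call(rbind, blocks), n_base = n_base,
                 varied = varied, spec = spec, seed = seed, block = labels),
            class = "saltelli_design")
}

#' @export
print.saltelli_design <- function(x, ...) {
  cat(sprintf("<saltelli_design> n_base = %d, %d varied parameters, %d rows\n",
              x$n_base, length(x$varied), nrow(x$rows)))
  invisible(x)
}

#' Evaluate a Saltelli design through the regulation model
#'
#' Computes the steady-state log2 regulation strength for every design row
#' with the vectorized solver. Rows whose solve fails are flagged `NA`; if
#' more than `max_failure_frac` of rows fail the run aborts.
#'
#' @param design a `"saltelli_design"` (or any matrix/data frame with the
#'   13 parameter columns).
#' @param topology [srna_topology()].
#' @param cap saturation cap passed to [regulation_strength_batch()].
#' @param max_failure_frac abort threshold on the failed-row fraction,
#'   default 0.01.
#' @return numeric vector of log2 ratios, one per design row.
#' @export
evaluate_design <- function(design, topology = srna_topology(), cap = -50,
                            max_failure_frac = 0.01) {
  rows <- if (inherits(design, "saltelli_design")) design$rows else design
  y <- regulation_strength_batch(rows, topology = topology, cap = cap)
  n_fail <- sum(!is.finite(y))
  if (n_fail > 0) {
    warning(n_fail, " design rows failed to solve and are flagged NA")
    if (n_fail > max_failure_frac * length(y))
      stop("more than ", 100 * max_failure_frac,
           "% of design rows failed to solve (", n_fail, "/", length(y), ")")
    y[!is.finite(y)] <- NA_real_
  }
  y
}

# split an output vector into yA, yB (n) and yAB (n x k) per the design
.split_outputs <- function(design, y) {
  n <- design$n_base
  k <- length(design$varied)
  if (length(y) != n * (k + 2))
    stop("outputs length does not match the design (expected ",
         n * (k + 2), ", got ", length(y), ")")
  list(yA = y[seq_len(n)], yB = y[n + seq_len(n)],
       yAB = matrix(y[-seq_len(2 * n)], nrow = n, ncol = k,
                    dimnames = list(NULL, design$varied)))
}

# point estimates from split outputs; Saltelli 2010 estimator for S1,
# Jansen estimator for ST
.sobol_point <- function(yA, yB, yAB) {
  k <- ncol(yAB)
  S1 <- ST <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    ok <- is.finite(yA) & is.finite(yB) & is.finite(yAB[, i])
    V <- var(c(yA[ok], yB[ok]))
    if (!is.finite(V) || V <= 0) next
    S1[i] <- mean(yB[ok] * (yAB[ok, i] - yA[ok])) / V
    ST[i] <- mean((yA[ok] - yAB[ok, i])^2) / (2 * V)
  }
  list(S1 = S1, ST = ST)
}

#' First- and total-order Sobol sensitivity indices
#'
#' S1 quantifies the direct contribution of each parameter to the output
#' variance (Saltelli estimator); ST additionally includes all interactions
#' involving the parameter (Jansen estimator). Raw estimates are returned;
#' a `clipped` column gives values clipped to [-0.1, 1.1] for reporting.
#' Rows with missing outputs are excluded pairwise per parameter.
#'
#' @param design a `"saltelli_design"`.
#' @param outputs numeric vector from [evaluate_design()], aligned with the
#'   design rows.
#' @return data frame of class `"sobol_result"` with columns `parameter`,
#'   `S1`, `ST`, `S1_clipped`, `ST_clipped`.
#' @export
sobol_indices <- function(design, outputs) {
  if (!inherits(design, "saltelli_design"))
    stop("design must be a saltelli_design")
  sp <- .split_outputs(design, outputs)
  ok <- is.finite(c(sp$yA, sp$yB))
  if (var(c(sp$yA, sp$yB)[ok]) <= 0)
    stop("output variance is zero; Sobol indices are undefined")
  pt <- .sobol_point(sp$yA, sp$yB, sp$yAB)
  out <- data.frame(parameter = design$varied, S1 = pt$S1, ST = pt$ST,
                    S1_clipped = pmin(pmax(pt$S1, -0.1), 1.1),
                    ST_clipped = pmin(pmax(pt$ST, -0.1), 1.1),
                    stringsAsFactors = FALSE)
  class(out) <- c("sobol_result", "data.frame")
  out
}

#' Bootstrap confidence intervals for Sobol indices
#'
#' Resamples the base-sample indices jointly across the A, B and AB_i
#' blocks and recomputes both estimators per replicate; percentile
#' (2.5/97.5) intervals are attached to the point estimates. Degenerate
#' (zero-variance) resamples are skipped with a warning.
#'
#' @param design a `"saltelli_design"`.
#' @param outputs vector from [evaluate_design()].
#' @param n_boot bootstrap replicates, default 100.
#' @param seed integer seed for the resampling.
#' @param conf confidence level, default 0.95.
#' @return `"sobol_result"` data frame with added columns `S1_lo`, `S1_hi`,
#'   `ST_lo`, `ST_hi`, and attribute `n_boot_used`.
#' @export
bootstrap_ci <- function(design, outputs, n_boot = 100, seed = 1L,
                         conf = 0.95) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  res <- sobol_indices(design, outputs)
  sp <- .split_outputs(design, outputs)
  n <- design$n_base
  k <- length(design$varied)
  set.seed(seed)
  S1b <- STb <- matrix(NA_real_, n_boot, k)
  used <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    yA <- sp$yA[idx]; yB <- sp$yB[idx]; yAB <- sp$yAB[idx, , drop = FALSE]
    ok <- is.finite(c(yA, yB))
    v <- var(c(yA, yB)[ok])
    if (!is.finite(v) || v <= 0) {
      warning("skipping zero-variance bootstrap resample")
      next
    }
    pt <- .sobol_point(yA, yB, yAB)
    used <- used + 1L
    S1b[b, ] <- pt$S1
    STb[b, ] <- pt$ST
  }
  alpha <- (1 - conf) / 2
  qs <- function(mat) apply(mat, 2, quantile, probs = c(alpha, 1 - alpha),
                            na.rm = TRUE)
  q1 <- qs(S1b); qT <- qs(STb)
  res$S1_lo <- q1[1, ]; res$S1_hi <- q1[2, ]
  res$ST_lo <- qT[1, ]; res$ST_hi <- qT[2, ]
  attr(res, "n_boot_used") <- used
  res
}

#' Two-dimensional binned summary with conditional means
#'
#' Histograms (x, y) pairs on a rectangular grid and computes the mean of y
#' within each x-bin; optionally the conditional mean is smoothed with a
#' local (lowess) smoother across bin centres.
#'
#' @param x,y numeric vectors of equal, positive length (non-finite pairs
#'   are dropped).
#' @param x_breaks,y_breaks bin edges (or a single bin count, default 50).
#' @param smooth apply lowess smoothing to the conditional mean?
#' @param smooth_f lowess span, default 0.3.
#' @return list of class `"binned_summary"`: `x_breaks`, `y_breaks`,
#'   `counts` (matrix, x-bins by y-bins), `x_mid`, `cond_mean`,
#'   `cond_mean_smooth` (NULL unless `smooth`), `n`.
#' @export
binned_conditional_summary <- function(x, y, x_breaks = 50, y_breaks = 50,
                                       smooth = FALSE, smooth_f = 0.3) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("no finite (x, y) pairs to bin")
  if (length(x_breaks) == 1)
    x_breaks <- seq(min(x), max(x), length.out = x_breaks + 1)
  if (length(y_breaks) == 1)
    y_breaks <- seq(min(y), max(y), length.out = y_breaks + 1)
  xi <- findInterval(x, x_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  yi <- findInterval(y, y_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  nx <- length(x_breaks) - 1; ny <- length(y_breaks) - 1
  counts <- matrix(0L, nx, ny)
  tab <- table(factor(xi, levels = seq_len(nx)),
               factor(yi, levels = seq_len(ny)))
  counts[] <- as.integer(tab)
  cond <- rep(NA_real_, nx)
  means <- tapply(y, factor(xi, levels = seq_len(nx)), mean)
  cond[as.integer(names(means))] <- as.numeric(means)
  x_mid <- (head(x_breaks, -1) + tail(x_breaks, -1)) / 2
  sm <- NULL
  if (smooth) {
    keep <- is.finite(cond)
    if (sum(keep) >= 3) {
      lw <- lowess(x_mid[keep], cond[keep], f = smooth_f)
      sm <- rep(NA_real_, nx)
      sm[keep] <- approx(lw$x, lw$y, xout = x_mid[keep], rule = 2)$y
    }
  }
  structure(list(x_breaks = x_breaks, y_breaks = y_breaks, counts = counts,
                 x_mid = x_mid, cond_mean = cond, cond_mean_smooth = sm,
                 n = length(x)),
            class = "binned_summary")
}

#' Per-sample GSA table with derived quantities
#'
#' Draws `n` parameter sets, computes the steady-state log2 regulation
#' strength for each, and attaches the derived quantities used in the
#' interdependency analyses: the molar dissociation constant `Kd_M`
#' (k_off/k_on at a 1e-15 L cell volume), the translation-rate ratio
#' `km_kms_ratio` (k_m/k_ms) and the decay-rate ratio `bm_bms_ratio`
#' (beta_m/beta_ms).
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param spec sampling specification, default [default_sampling_spec()].
#' @param topology [srna_topology()].
#' @param volume_L cell volume for the Kd conversion, default 1e-15 L.
#' @return data frame: 13 parameter columns, `log2_ratio`, `Kd_M`,
#'   `km_kms_ratio`, `bm_bms_ratio`.
#' @export
gsa_sample_table <- function(n, seed = 1L,
                             spec = default_sampling_spec(),
                             topology = srna_topology(),
                             volume_L = 1e-15) {
  par <- sample_parameters(spec, n, seed = seed)
  par$log2_ratio <- regulation_strength_batch(par[PARAM_NAMES],
                                              topology = topology)
  par$Kd_M <- (par$k_off / par$k_on) / (.N_AVOGADRO * volume_L)
  par$km_kms_ratio <- par$k_m / par$k_ms
  par$bm_bms_ratio <- par$beta_m / par$beta_ms
  par
}

#' Threshold summary of a per-sample GSA table
#'
#' Extracts the headline threshold quantities: the maximum Kd among samples
#' whose regulation exceeds 1.5-fold in magnitude (strong regulation
#' requires sufficiently tight binding), the maximum k_m/k_ms ratio among
#' samples showing net activation, the fraction of repressed samples, and
#' the mean log2 ratio (negative = overall skew toward repression).
#'
#' @param table data frame from [gsa_sample_table()].
#' @param fold fold-change defining "strong" regulation, default 1.5.
#' @return list: `max_kd_strong_regulation_M`, `max_km_kms_activation`,
#'   `frac_repression`, `mean_log2_ratio`, `n`.
#' @export
threshold_summary <- function(table, fold = 1.5) {
  ok <- is.finite(table$log2_ratio)
  tab <- table[ok, ]
  strong <- abs(tab$log2_ratio) > log2(fold)
  act <- tab$log2_ratio > 0
  list(
    max_kd_strong_regulation_M =
      if (any(strong)) max(tab$Kd_M[strong]) else NA_real_,
    max_km_kms_activation =
      if (any(act)) max(tab$km_kms_ratio[act]) else NA_real_,
    frac_repression = mean(tab$log2_ratio < 0),
    mean_log2_ratio = mean(tab$log2_ratio),
    n = nrow(tab))
}
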