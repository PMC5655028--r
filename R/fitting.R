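#' Replicated fold-change expression series
#'
#' Container for a gene's fold-change-relative-to-dark time course, either
#' as a replicate matrix (rows = time points) or as per-point mean and
#' standard error. All fold changes must be positive; fitting additionally
#' requires at least three distinct time points.
#'
#' @param gene_id Gene label.
#' @param times Sampling times, days, sorted, `>= 0`.
#' @param replicates Optional numeric matrix of fold changes,
#'   `length(times)` rows; mean/SE/n are derived from it.
#' @param mean,se,n Optional per-point summaries (used when `replicates` is
#'   absent); `se` must be positive wherever `n > 1`.
#' @return An object of class `expression_series` with fields `gene_id`,
#'   `times`, `replicates`, `mean`, `se`, `n`.
#' @export
expression_series <- function(gene_id, times, replicates = NULL,
                              mean = NULL, se = NULL, n = NULL) {
  if (!is.numeric(times) || is.unsorted(times) || any(times < 0))
    stop("`times` must be sorted non-negative days", call. = FALSE)
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    if (nrow(replicates) != length(times))
      stop("`replicates` must have one row per time point", call. = FALSE)
    if (any(replicates <= 0))
      stop("fold changes must be positive", call. = FALSE)
    n <- rep(ncol(replicates), length(times))
    mean <- rowMeans(replicates)
    se <- if (ncol(replicates) > 1)
      apply(replicates, 1, sd) / sqrt(ncol(replicates)) else rep(NA_real_, length(times))
  } else {
    if (is.null(mean)) stop("supply `replicates` or `mean`", call. = FALSE)
    if (any(mean <= 0)) stop("fold changes must be positive", call. = FALSE)
    if (is.null(n)) n <- rep(1L, length(times))
    if (!is.null(se) && any(!is.na(se) & n > 1 & se <= 0))
      stop("`se` must be positive wherever n > 1", call. = FALSE)
  }
  structure(list(gene_id = gene_id, times = as.numeric(times),
                 replicates = replicates, mean = as.numeric(mean),
                 se = if (is.null(se)) rep(NA_real_, length(times)) else as.numeric(se),
                 n = as.integer(n)),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("Expression series for %s: %d time points (%g-%g days), n = %s\n",
              x$gene_id, length(x$times), min(x$times), max(x$times),
              paste(unique(x$n), collapse = "/")))
  invisible(x)
}

#' Forward-model configuration for fitting
#'
#' Bundles the fixed (non-fitted) model configuration used by the fitting
#' routines: photoconversion parameters, reduced PIF3 parameters, and the
#' PIF3 engine. The same configuration drives simulation and fitting, so
#' fitted constants are directly comparable across the package.
#'
#' @param photo A [photo_params()] object.
#' @param pif A [pif_params()] object.
#' @param pif_source `"numeric"` (default) or `"closed_form"`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(photo = photo_params(), pif = pif_params(),
                         pif_source = c("numeric", "closed_form")) {
  structure(list(photo = photo, pif = pif,
                 pif_source = match.arg(pif_source)),
            class = "model_config")
}

# dense PIF trajectory for a config, spanning at least t_max
forward_pif_grid <- function(config, t_max, extra = NULL) {
  grid <- signalling_grid(max(t_max, 1e-3), extra = extra)
  if (config$pif_source == "numeric") {
    integrate_pif(config$pif, config$photo, grid)
  } else {
    data.frame(time = grid,
               pif = pif_closed_form(grid, config$pif, config$photo))
  }
}

series_weights <- function(series) {
  w <- rep(1, length(series$times))
  ok <- !is.na(series$se) & series$se > 0
  if (any(ok)) w[ok] <- 1 / series$se[ok]^2
  # points without a usable SE get the median weight of the rest
  if (any(ok) && any(!ok)) w[!ok] <- stats::median(w[ok])
  w
}

fit_result <- function(parameter, estimate, loss, converged, n_eval, bounds,
                       seed = NA_integer_, warning = NA_character_) {
  structure(list(parameter = parameter, estimate = estimate, loss = loss,
                 converged = converged, n_eval = n_eval, bounds = bounds,
                 seed = seed, warning = warning),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit of %s: estimate %.6g (loss %.4g, %d evaluations, bounds [%g, %g])\n",
              x$parameter, x$estimate, x$loss, x$n_eval, x$bounds[1], x$bounds[2]))
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

# shared 1-D bounded minimiser: 50-point log-grid pre-scan to bracket the
# optimum, then Brent refinement in the bracketing interval
minimise_1d <- function(loss, bounds, n_scan = 50L, tol = 1e-6) {
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_scan))
  lg <- vapply(grid, loss, numeric(1))
  i <- which.min(lg)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_scan, i + 1L)]
  opt <- optimize(loss, lower = lo, upper = hi, tol = tol * max(1, hi))
  n_eval <- n_scan + 30L  # optimize() does not report its count; Brent ~30
  best <- if (opt$objective <= lg[i]) list(par = opt$minimum, val = opt$objective)
          else list(par = grid[i], val = lg[i])
  list(par = best$par, value = best$val, n_eval = n_eval)
}

#' Fit the relative dissociation constant of a gene
#'
#' Estimates `K_PIF` by weighted least squares between the measured
#' fold-change means and the forward-model expression curve, with every
#' other model constant fixed by `config`. Weights are `1/SE^2` where a
#' standard error is available, else uniform. The loss is minimised over
#' `K_PIF` in `bounds` by a 50-point log-grid pre-scan followed by Brent
#' refinement. A series with essentially no light response drives the
#' estimate to the upper bound (`phi -> 1` as `K_PIF -> infinity`) and is
#' flagged with an identifiability warning.
#'
#' @param series An [expression_series()].
#' @param config A [model_config()].
#' @param bounds Search interval for `K_PIF`.
#' @param gamma Transcript decay rate, per day (fixed, not fitted).
#' @return A `fit_result` with fields `parameter`, `estimate`, `loss`,
#'   `converged`, `n_eval`, `bounds`, `warning`.
#' @export
fit_kpif <- function(series, config = model_config(), bounds = c(1e-4, 10),
                     gamma = 4 * log(2)) {
  stopifnot(inherits(series, "expression_series"),
            inherits(config, "model_config"))
  if (length(unique(series$times)) < 3L)
    stop("fitting requires at least 3 distinct time points", call. = FALSE)
  w <- series_weights(series)
  ptr <- forward_pif_grid(config, max(series$times), extra = series$times)
  tg <- ptr$time; pifv <- ptr$pif
  idx <- match(series$times, tg)
  loss <- function(K) {
    x <- expression_on_grid(K, gamma, tg, pifv)[idx]
    sum(w * (series$mean - x)^2)
  }
  m <- minimise_1d(loss, bounds)
  warn <- NA_character_
  span <- diff(range(series$mean)) / max(series$mean)
  if (m$par > 0.95 * bounds[2] || span < 0.05) {
    warn <- "estimate at or near the upper bound: series shows little light response, K_PIF weakly identified"
    warning(warn, call. = FALSE)
  }
  fit_result("K_PIF", m$par, m$value, converged = is.finite(m$value),
             n_eval = m$n_eval, bounds = bounds, warning = warn)
}

#' Fit the PhyB abundance scaling of a mutant series
#'
#' Estimates the abundance factor `q` (PhyB level relative to wild type)
#' from a mutant fold-change series, with the gene's `K_PIF` fixed (e.g.
#' from a wild-type fit). Lower `q` slows PIF3 removal, so the expression
#' response is pointwise weaker; the published *phyB* mutant data are
#' matched by `q` of about 1/4. The numeric PIF3 engine is used regardless
#' of `config$pif_source`, because the closed form is derived for `q = 1`.
#'
#' @param series An [expression_series()] of the mutant.
#' @param gene A [gene_params()] object with `K_PIF` fixed.
#' @param config A [model_config()].
#' @param bounds Search interval for `q` within `(0, 1]`.
#' @return A `fit_result`.
#' @export
fit_q <- function(series, gene, config = model_config(),
                  bounds = c(1e-3, 1)) {
  stopifnot(inherits(series, "expression_series"),
            inherits(config, "model_config"))
  gene <- as_gene_params(gene)
  if (length(unique(series$times)) < 3L)
    stop("fitting requires at least 3 distinct time points", call. = FALSE)
  w <- series_weights(series)
  grid <- signalling_grid(max(series$times), extra = series$times)
  idx <- match(series$times, grid)
  base <- config$photo
  loss <- function(q) {
    photo_q <- photo_params(K_Pfr = base$K_Pfr, Gamma_Pfr = base$Gamma_Pfr,
                            gamma_Pr = base$gamma_Pr, q = q)
    ptr <- integrate_pif(config$pif, photo_q, grid, rtol = 1e-8, atol = 1e-10)
    x <- expression_on_grid(gene$K_PIF, gene$gamma, grid, ptr$pif)[idx]
    sum(w * (series$mean - x)^2)
  }
  m <- minimise_1d(loss, bounds, n_scan = 30L)
  fit_result("q", m$par, m$value, converged = is.finite(m$value),
             n_eval = m$n_eval, bounds = bounds)
}

#' Fit an exponential decay with optional floor
#'
#' Least-squares fit of `value(t) = floor + (v0 - floor) * exp(-r * t)` to
#' a decay series, returning the rate and the implied half-life
#' `log(2) / r`. Used to calibrate the pooled PhyB decay rate from decay
#' data: exact samples of the PhyB closed form recover
#' `r = Q_Pfr * gamma_Pr` and `floor = 1 / Q_Pfr`. With `floor = "zero"`
#' the floor is fixed at 0; with exactly two points and a zero floor the
#' rate is computed in closed form.
#'
#' @param times Sampling times, days.
#' @param values Positive measurements decaying toward the floor.
#' @param floor `"fit"` to co-estimate the floor (requires >= 3 points),
#'   `"zero"` to fix it at 0, or a fixed numeric value.
#' @return List with `rate` (per day), `half_life` (days), `floor`, `v0`
#'   and the `nls` fit object (`NULL` for the two-point closed form).
#' @export
fit_exponential_halflife <- function(times, values, floor = c("fit", "zero")) {
  if (is.numeric(floor)) { fl_fixed <- floor; floor <- "fixed" }
  else { floor <- match.arg(floor); fl_fixed <- if (floor == "zero") 0 else NA }
  if (length(times) != length(values) || length(times) < 2L)
    stop("need at least two (time, value) pairs", call. = FALSE)
  if (any(values <= 0)) stop("`values` must be positive", call. = FALSE)
  o <- order(times); times <- times[o]; values <- values[o]
  if (values[length(values)] >= values[1])
    stop("series does not decay: cannot fit an exponential decay", call. = FALSE)

  if (floor != "fit" && length(times) == 2L) {
    # closed form for two exact points
    r <- log((values[1] - fl_fixed) / (values[2] - fl_fixed)) / diff(times)
    return(list(rate = r, half_life = log(2) / r, floor = fl_fixed,
                v0 = values[1], fit = NULL))
  }
  if (floor == "fit" && length(times) < 3L)
    stop("co-fitting the floor requires at least 3 points", call. = FALSE)

  fl0 <- if (floor == "fit") max(0, min(values) * 0.9) else fl_fixed
  pos <- values - fl0 > 0
  lmfit <- lm(log(values[pos] - fl0) ~ times[pos])
  r0 <- max(-coef(lmfit)[[2]], 1e-3)
  v00 <- values[1]
  df <- data.frame(t = times, v = values)
  fit <- if (floor == "fit") {
    minpack.lm::nlsLM(v ~ fl + (v0 - fl) * exp(-r * t), data = df,
                      start = list(fl = fl0, v0 = v00, r = r0),
                      lower = c(0, 0, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(v ~ fl_fixed + (v0 - fl_fixed) * exp(-r * t), data = df,
                      start = list(v0 = v00, r = r0), lower = c(0, 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- coef(fit)
  fl <- if (floor == "fit") cf[["fl"]] else fl_fixed
  list(rate = cf[["r"]], half_life = log(2) / cf[["r"]], floor = fl,
       v0 = cf[["v0"]], fit = fit)
}
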