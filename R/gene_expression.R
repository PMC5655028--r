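#' Parameters of a PIF3-repressed gene
#'
#' A gene `X` repressed by PIF3 binding (as a dimer) to its promoter. On the
#' relative-to-dark scale the only free parameters are the relative
#' dissociation constant `K_PIF` (smaller values mean stronger repression in
#' darkness and hence a larger relief upon light exposure) and the
#' transcript decay rate `gamma`. All six default genes share
#' `gamma = 4 log(2)` per day (a 6-hour transcript half-life, the mean
#' mRNA half-life in Arabidopsis).
#'
#' @param gene_id Gene label.
#' @param K_PIF Dimensionless relative dissociation constant (`> 0`).
#' @param gamma Transcript decay rate, per day (`> 0`).
#' @return An object of class `gene_params`.
#' @seealso [default_gene_params()]
#' @export
gene_params <- function(gene_id, K_PIF, gamma = 4 * log(2)) {
  if (!is.character(gene_id) || length(gene_id) != 1L)
    stop("`gene_id` must be a single string", call. = FALSE)
  if (!is.numeric(K_PIF) || length(K_PIF) != 1L || is.na(K_PIF) || K_PIF <= 0)
    stop("`K_PIF` must be a single positive number", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a single positive number (per day)", call. = FALSE)
  structure(list(gene_id = gene_id, K_PIF = K_PIF, gamma = gamma),
            class = "gene_params")
}

#' Default gene parameter table
#'
#' The six PEP-associated nuclear genes with their calibrated relative
#' dissociation constants: SIG2 (0.32), SIG6 (0.22), PAP1 (0.35),
#' PAP2 (0.12), PAP5 (0.48) and PRIN2 (0.09), all with a 6-hour transcript
#' half-life.
#'
#' @return A data.frame with columns `gene_id`, `K_PIF`, `gamma` (per day).
#' @export
default_gene_params <- function() {
  data.frame(
    gene_id = c("SIG2", "SIG6", "PAP1", "PAP2", "PAP5", "PRIN2"),
    K_PIF = c(0.32, 0.22, 0.35, 0.12, 0.48, 0.09),
    gamma = 4 * log(2),
    stringsAsFactors = FALSE
  )
}

as_gene_params <- function(gene) {
  if (inherits(gene, "gene_params")) return(gene)
  if (is.list(gene) && all(c("gene_id", "K_PIF") %in% names(gene)))
    return(gene_params(as.character(gene$gene_id), as.numeric(gene$K_PIF),
                       if (is.null(gene$gamma)) 4 * log(2) else as.numeric(gene$gamma)))
  stop("`gene` must be a gene_params object or a list/row with gene_id and K_PIF",
       call. = FALSE)
}

#' Relative synthesis rate of a PIF3-repressed gene
#'
#' The occupancy factor `phi = (K_PIF + 1) / (K_PIF + pif^2)`: the synthesis
#' rate of `X` relative to its dark value, for a promoter bound by PIF3
#' dimers. Equals 1 in darkness (`pif = 1`), increases monotonically as PIF3
#' is degraded, and saturates at the full-derepression value
#' `(K_PIF + 1) / K_PIF` when `pif = 0`.
#'
#' @param pif Relative PIF3 level(s) (`>= 0`).
#' @param K_PIF Relative dissociation constant (`> 0`).
#' @return Dimensionless synthesis rate(s).
#' @examples
#' phi(1, 0.32)  # 1 (dark)
#' phi(0, 0.32)  # 4.125 (maximal derepression)
#' @export
phi <- function(pif, K_PIF) {
  if (any(pif < 0)) stop("`pif` must be non-negative", call. = FALSE)
  if (!is.numeric(K_PIF) || any(K_PIF <= 0))
    stop("`K_PIF` must be positive", call. = FALSE)
  (K_PIF + 1) / (K_PIF + pif^2)
}

#' Absolute dark stationary transcript level
#'
#' `(V_max / gamma) * K_PIF / (K_PIF + 1)`: the dark steady state of the
#' absolute-scale transcription model, i.e. the maximal rate discounted by
#' the probability that the promoter is free of PIF3 in darkness. Documents
#' the rescaling that produces the relative-to-dark formulation (everything
#' downstream divides by this level).
#'
#' @param V_max Maximal transcription rate (concentration/day, `> 0`).
#' @param gamma Transcript decay rate (per day, `> 0`).
#' @param K_PIF_raw Dissociation constant on the dark-PIF concentration
#'   scale (`> 0`).
#' @return Stationary concentration.
#' @export
absolute_dark_stationary <- function(V_max, gamma, K_PIF_raw) {
  if (any(c(V_max, gamma, K_PIF_raw) <= 0))
    stop("all arguments must be positive", call. = FALSE)
  (V_max / gamma) * K_PIF_raw / (K_PIF_raw + 1)
}

#' Dense simulation grid for the signalling cascade
#'
#' A time grid refined near light onset, where PIF3 changes on the
#' 15-minute scale, and progressively coarser later. Used as the default
#' internal grid of the forward gene-expression model.
#'
#' @param t_max End of the grid, days.
#' @param extra Extra time points to merge into the grid (e.g. sampling
#'   times).
#' @return Strictly increasing numeric vector starting at 0.
#' @export
signalling_grid <- function(t_max = 7, extra = NULL) {
  stopifnot(t_max > 0)
  g <- c(seq(0, min(0.05, t_max), length.out = 400),
         if (t_max > 0.05) seq(0.05, min(0.5, t_max), length.out = 400),
         if (t_max > 0.5) seq(0.5, min(3, t_max), length.out = 500),
         if (t_max > 3) seq(3, t_max, length.out = 400))
  sort(unique(c(g, extra[extra >= 0 & extra <= t_max])))
}

#' Integrate the expression of a PIF3-repressed gene
#'
#' Solves the linear relative-expression equation
#' `d[X]/dt = gamma (phi(t) - [X])`, `[X](0) = 1`, driven by the PIF3
#' trajectory. The drive `phi(pif(t))` is interpolated linearly between the
#' trajectory grid points and the ODE is advanced with the exact
#' exponential-integrator step for a linear-in-time drive, so the scheme is
#' unconditionally stable and exact up to the interpolation of `phi`; on
#' the default dense grid it agrees with adaptive quadrature of the
#' convolution integral to better than 1e-4 relative. In darkness
#' (`pif` identically 1) the solution is identically 1.
#'
#' @param gene A [gene_params()] object (or a row of
#'   [default_gene_params()]).
#' @param pif_traj Data.frame with columns `time` and `pif`, e.g. from
#'   [integrate_pif()]; the grid should resolve the fast initial PIF3 decay
#'   (see [signalling_grid()]).
#' @param times Optional output times (must lie within the trajectory
#'   span); defaults to the trajectory grid.
#' @return Data.frame with columns `time` and `expression`.
#' @seealso [expression_by_quadrature()] for the independent quadrature
#'   oracle, [simulate_genes()] for the multi-gene front end.
#' @export
integrate_expression <- function(gene, pif_traj, times = NULL) {
  gene <- as_gene_params(gene)
  if (!is.data.frame(pif_traj) || !all(c("time", "pif") %in% names(pif_traj)))
    stop("`pif_traj` must be a data.frame with columns time and pif", call. = FALSE)
  tg <- pif_traj$time
  if (tg[1] != 0 || any(diff(tg) <= 0))
    stop("trajectory grid must start at 0 and be strictly increasing", call. = FALSE)
  x <- expression_on_grid(gene$K_PIF, gene$gamma, tg, pif_traj$pif)
  if (is.null(times)) return(data.frame(time = tg, expression = x))
  if (any(times < tg[1]) || any(times > tg[length(tg)]))
    stop("`times` outside the span of `pif_traj`", call. = FALSE)
  data.frame(time = times,
             expression = approx(tg, x, xout = times, ties = "ordered")$y)
}

# Exact exponential-integrator stepping for dX/dt = gamma*(phi - X) with
# phi piecewise linear on the grid. Particular solution for phi = a + b*s is
# X_p = phi(s) - b/gamma, so X_{i+1} = X_p(t_{i+1}) + (X_i - X_p(t_i)) e^{-g dt}.
expression_on_grid <- function(K_PIF, gamma, tg, pif) {
  ph <- (K_PIF + 1) / (K_PIF + pif^2)
  n <- length(tg)
  x <- numeric(n)
  x[1] <- 1
  dt <- diff(tg)
  b <- diff(ph) / dt
  decay <- exp(-gamma * dt)
  for (i in seq_len(n - 1L)) {
    x[i + 1L] <- (ph[i + 1L] - b[i] / gamma) +
      (x[i] - ph[i] + b[i] / gamma) * decay[i]
  }
  x
}

#' Expression by adaptive quadrature of the convolution integral
#'
#' Evaluates the integral solution of the linear expression equation,
#' `[X](t) = exp(-gamma t) + gamma * Int_0^t phi(s) exp(-gamma (t - s)) ds`:
#' the synthesis at each past time `s` discounted by the degradation between
#' `s` and `t`. The PIF3 trajectory is interpolated with a monotone spline
#' and the integral evaluated with adaptive quadrature; this is the
#' independent oracle for [integrate_expression()].
#'
#' @inheritParams integrate_expression
#' @param t Evaluation time(s), days, within the trajectory span.
#' @param rel.tol Quadrature relative tolerance.
#' @return Dimensionless expression value(s).
#' @export
expression_by_quadrature <- function(gene, pif_traj, t, rel.tol = 1e-9) {
  gene <- as_gene_params(gene)
  tg <- pif_traj$time
  if (any(t < tg[1]) || any(t > tg[length(tg)]))
    stop("`t` outside the span of `pif_traj`", call. = FALSE)
  pif_fn <- splinefun(tg, pif_traj$pif, method = "monoH.FC")
  g <- gene$gamma; K <- gene$K_PIF
  vapply(t, function(ti) {
    if (ti == 0) return(1)
    int <- integrate(function(s) phi(pmax(pif_fn(s), 0), K) * exp(-g * (ti - s)),
                     lower = 0, upper = ti, rel.tol = rel.tol,
                     subdivisions = 2000L)$value
    exp(-g * ti) + g * int
  }, numeric(1))
}

#' Short-time expression approximation
#'
#' For times shorter than `1 / sqrt(gamma_Pfr * gamma)` the PIF3 level has
#' already collapsed while PhyB is still near 1, and the expression rise is
#' approximated by
#' `[X](t) = (1 + ((K_PIF + 1) / K_PIF) (gamma t + (gamma t)^2 / 2)) exp(-gamma t)`.
#' A warning is issued for times beyond the validity bound (about 0.39 days,
#' 9.4 h, at the default calibration).
#'
#' @param t Time(s), days (`>= 0`).
#' @param gene A [gene_params()] object.
#' @param photo A [photo_params()] object (supplies `gamma_Pfr` for the
#'   validity bound).
#' @return Dimensionless expression value(s); equals 1 at `t = 0`.
#' @export
expression_short_time <- function(t, gene, photo = photo_params()) {
  gene <- as_gene_params(gene)
  stopifnot(inherits(photo, "photo_params"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  bound <- 1 / sqrt(photo$gamma_Pfr * gene$gamma)
  if (any(t > bound))
    warning(sprintf(
      "short-time approximation requested beyond its validity bound t < %.4g days",
      bound))
  g <- gene$gamma
  (1 + ((gene$K_PIF + 1) / gene$K_PIF) * (g * t + (g * t)^2 / 2)) * exp(-g * t)
}

#' Validity bound of the short-time approximation
#'
#' `1 / sqrt(gamma_Pfr * gamma)`, in days.
#'
#' @inheritParams expression_short_time
#' @return A single time in days.
#' @export
short_time_bound <- function(gene, photo = photo_params()) {
  gene <- as_gene_params(gene)
  1 / sqrt(photo$gamma_Pfr * gene$gamma)
}

#' Stationary relative expression level
#'
#' The long-time expression level `phi(PIF_inf)` obtained by setting the
#' time derivative of the expression equation to zero at the stationary
#' PIF3 level. Two modes are provided:
#'
#' * `"limit"` (default): `PIF_inf` is the long-time limit of the combined
#'   closed-form PIF3 solution, `Q_Pfr (sqrt(R_PP) - Q_Pfr/2) / R_PP`
#'   (see [pif_closed_form_limit()]); this reproduces the observed
#'   several-fold stationary induction. A different stationary PIF3 level
#'   (e.g. the slow-manifold value matching a numeric simulation) may be
#'   supplied through `pif_inf`.
#' * `"as_printed"`: the typeset stationary formula with inner term
#'   `(Q_Pfr / sqrt(R_PP) + Q_Pfr^2 / 2)^2`, kept verbatim for comparison.
#'   At the default calibration its inner term is about 1.5e3, which drives
#'   the value far below 1 and is inconsistent with the long-time levels of
#'   the forward model; it is retained only for reference.
#'
#' @param gene A [gene_params()] object.
#' @param pif_params A [pif_params()] object.
#' @param photo A [photo_params()] object.
#' @param mode `"limit"` or `"as_printed"`.
#' @param pif_inf Optional stationary PIF3 level overriding the closed-form
#'   limit (only used in `"limit"` mode).
#' @return A single dimensionless expression level (1 in darkness,
#'   `R_PP = 0`).
#' @export
expression_stationary <- function(gene, pif_params = phypif::pif_params(),
                                  photo = photo_params(),
                                  mode = c("limit", "as_printed"),
                                  pif_inf = NULL) {
  gene <- as_gene_params(gene)
  stopifnot(inherits(pif_params, "pif_params"), inherits(photo, "photo_params"))
  mode <- match.arg(mode)
  if (mode == "limit") {
    if (is.null(pif_inf))
      pif_inf <- pif_closed_form_limit(pif_params, photo)
    return(phi(pif_inf, gene$K_PIF))
  }
  if (pif_params$R_PP == 0) return(1)
  inner <- photo$Q_Pfr / sqrt(pif_params$R_PP) + photo$Q_Pfr^2 / 2
  (gene$K_PIF + 1) / (gene$K_PIF + inner^2)
}

#' Peak time and height of an expression trajectory
#'
#' Grid argmax and maximum of a gene's expression column; ties are broken
#' by the earliest time. The model predicts each PIF3-repressed gene peaks
#' within the first two days of light exposure.
#'
#' @param traj Data.frame with a `time` column and the gene's expression
#'   column.
#' @param gene_id Name of the expression column (default `"expression"`).
#' @return Named list with `t_peak` (days) and `fold_peak`.
#' @export
peak_metrics <- function(traj, gene_id = "expression") {
  if (!is.data.frame(traj) || nrow(traj) == 0L)
    stop("`traj` must be a non-empty data.frame", call. = FALSE)
  if (!gene_id %in% names(traj))
    stop(sprintf("no column `%s` in trajectory", gene_id), call. = FALSE)
  v <- traj[[gene_id]]
  i <- which.max(v)  # which.max returns the first (earliest) maximum
  list(t_peak = traj$time[i], fold_peak = v[i])
}

#' Simulate the full cascade for a set of genes
#'
#' Runs PhyB -> PIF3 -> expression for every gene in `genes` on a dense
#' internal grid and returns the trajectories at `times`. The PIF3 input is
#' either the numeric reduced-equation solution (default, as used for the
#' published model curves) or the combined closed-form approximation
#' (`pif_source = "closed_form"`).
#'
#' @param genes Data.frame with columns `gene_id`, `K_PIF` and optionally
#'   `gamma` (defaults to [default_gene_params()]).
#' @param pif A [pif_params()] object.
#' @param photo A [photo_params()] object.
#' @param times Output times, days, starting at 0.
#' @param pif_source `"numeric"` or `"closed_form"`.
#' @return Data.frame with columns `time`, `phyb`, `pfr`, `pif` and one
#'   expression column per gene; attribute `params` records the
#'   configuration.
#' @export
simulate_genes <- function(genes = default_gene_params(),
                           pif = pif_params(), photo = photo_params(),
                           times = seq(0, 7, by = 0.05),
                           pif_source = c("numeric", "closed_form")) {
  pif_source <- match.arg(pif_source)
  check_time_grid(times)
  grid <- signalling_grid(max(times), extra = times)
  ptr <- if (pif_source == "numeric") {
    integrate_pif(pif, photo, grid)
  } else {
    data.frame(time = grid, pif = pif_closed_form(grid, pif, photo))
  }
  out <- data.frame(time = times,
                    phyb = phyb_closed_form(times, photo),
                    pfr = pfr_level(times, photo),
                    pif = approx(grid, ptr$pif, xout = times, ties = "ordered")$y)
  for (i in seq_len(nrow(genes))) {
    g <- as_gene_params(as.list(genes[i, ]))
    out[[g$gene_id]] <- integrate_expression(g, ptr, times = times)$expression
  }
  attr(out, "params") <- list(genes = genes, pif = pif, photo = photo,
                              pif_source = pif_source)
  out
}
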