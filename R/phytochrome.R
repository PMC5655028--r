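#' Phytochrome B photoconversion and decay parameters
#'
#' Builds the parameter set of the two-state (Pr/Pfr) phytochrome B model.
#' Light drives the inactive Pr form to the active Pfr form; the ratio at the
#' fast photoequilibrium is `K_Pfr`, the light sensor of the model. The two
#' derived composites are
#' `Q_Pfr = (1 + Gamma_Pfr * K_Pfr) / (1 + K_Pfr)`, which sets the decay rate
#' of the total PhyB pool in light, and `R_Pfr = K_Pfr / (1 + K_Pfr)`, the Pfr
#' fraction of total PhyB.
#'
#' Defaults follow the red-light calibration of the model: `K_Pfr = 7`
#' (about 13% Pr remaining in red light, so `R_Pfr = 0.875`), `Q_Pfr = 8.75`
#' (hence `Gamma_Pfr = 69/7`), and a pooled decay rate
#' `Q_Pfr * gamma_Pr = 3 * log(2)` per day, i.e. an 8-hour PhyB half-life in
#' red light. Only the product `Q_Pfr * gamma_Pr` is constrained by data;
#' `gamma_Pr` alone is defined as that product divided by `Q_Pfr`.
#'
#' @param K_Pfr Dimensionless Pfr:Pr photoequilibrium constant in light
#'   (`>= 0`; 0 means darkness).
#' @param Gamma_Pfr Dimensionless ratio `gamma_Pfr / gamma_Pr` of the decay
#'   rates of the short-lived Pfr and long-lived Pr forms (`> 0`).
#' @param gamma_Pr Pr decay rate, per day (`> 0`).
#' @param q Dimensionless PhyB-abundance scaling for mutants with reduced
#'   phytochrome levels (`0 < q <= 1`). The scaling multiplies the PhyB (and
#'   hence Pfr) trajectory; `q = 1` is wild type.
#' @param k_Pr,k_Pfr_plus,k_Pfr_minus,k_dark Optional absolute-scale rate
#'   constants for the unreduced two-state system: Pr synthesis
#'   (concentration/day), Pr->Pfr photoconversion, Pfr->Pr back-conversion in
#'   light, and thermal dark reversion (all per day, `>= 0`). When all four
#'   are supplied they must satisfy
#'   `K_Pfr = k_Pfr_plus / (k_Pfr_minus + k_dark)` to relative tolerance 1e-9.
#'
#' @return An object of class `photo_params`: the inputs plus derived
#'   `Q_Pfr`, `R_Pfr` and `gamma_Pfr = Gamma_Pfr * gamma_Pr`.
#' @seealso [derive_photo_composites()], [phyb_closed_form()],
#'   [integrate_phyb()], [mutant_photo_params()]
#' @examples
#' p <- photo_params()
#' c(p$Q_Pfr, p$R_Pfr)  # 8.75, 0.875
#' @export
photo_params <- function(K_Pfr = 7,
                         Gamma_Pfr = 69 / 7,
                         gamma_Pr = 3 * log(2) / 8.75,
                         q = 1,
                         k_Pr = NULL,
                         k_Pfr_plus = NULL,
                         k_Pfr_minus = NULL,
                         k_dark = NULL) {
  if (!is.numeric(K_Pfr) || length(K_Pfr) != 1L || is.na(K_Pfr) || K_Pfr < 0)
    stop("`K_Pfr` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(Gamma_Pfr) || length(Gamma_Pfr) != 1L || Gamma_Pfr <= 0)
    stop("`Gamma_Pfr` must be a single positive number", call. = FALSE)
  if (!is.numeric(gamma_Pr) || length(gamma_Pr) != 1L || gamma_Pr <= 0)
    stop("`gamma_Pr` must be a single positive number (per day)", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q > 1)
    stop("`q` must satisfy 0 < q <= 1", call. = FALSE)

  abs_given <- !vapply(list(k_Pr, k_Pfr_plus, k_Pfr_minus, k_dark), is.null,
                       logical(1))
  if (any(abs_given) && !all(abs_given))
    stop("supply all of k_Pr, k_Pfr_plus, k_Pfr_minus, k_dark or none",
         call. = FALSE)
  if (all(abs_given)) {
    if (any(c(k_Pr, k_Pfr_plus, k_Pfr_minus, k_dark) < 0))
      stop("absolute rate constants must be non-negative", call. = FALSE)
    K_implied <- k_Pfr_plus / (k_Pfr_minus + k_dark)
    if (abs(K_implied - K_Pfr) > 1e-9 * max(1, abs(K_Pfr)))
      stop(sprintf(
        "K_Pfr (%.10g) inconsistent with k_Pfr_plus/(k_Pfr_minus + k_dark) = %.10g",
        K_Pfr, K_implied), call. = FALSE)
  }

  structure(list(
    K_Pfr = K_Pfr,
    Gamma_Pfr = Gamma_Pfr,
    gamma_Pr = gamma_Pr,
    gamma_Pfr = Gamma_Pfr * gamma_Pr,
    Q_Pfr = (1 + Gamma_Pfr * K_Pfr) / (1 + K_Pfr),
    R_Pfr = K_Pfr / (1 + K_Pfr),
    q = q,
    k_Pr = k_Pr,
    k_Pfr_plus = k_Pfr_plus,
    k_Pfr_minus = k_Pfr_minus,
    k_dark = k_dark
  ), class = "photo_params")
}

#' @export
print.photo_params <- function(x, ...) {
  cat("Phytochrome B photoconversion parameters\n")
  cat(sprintf("  K_Pfr = %g, Gamma_Pfr = %g, gamma_Pr = %g /day, q = %g\n",
              x$K_Pfr, x$Gamma_Pfr, x$gamma_Pr, x$q))
  cat(sprintf("  derived: Q_Pfr = %g, R_Pfr = %g, gamma_Pfr = %g /day\n",
              x$Q_Pfr, x$R_Pfr, x$gamma_Pfr))
  if (!is.null(x$k_Pr))
    cat(sprintf("  absolute: k_Pr = %g, k_Pfr+ = %g, k_Pfr- = %g, k_dark = %g\n",
                x$k_Pr, x$k_Pfr_plus, x$k_Pfr_minus, x$k_dark))
  invisible(x)
}

#' Preset for phyB-deficient mutants
#'
#' Wild-type photoconversion parameters with the PhyB abundance scaled by
#' `q`; `q = 1/4` reproduces the reduced SIG2/SIG6 light response of the
#' *phyB* mutant.
#'
#' @param q PhyB abundance relative to wild type (`0 < q <= 1`).
#' @param ... Passed on to [photo_params()].
#' @return A `photo_params` object.
#' @export
mutant_photo_params <- function(q = 0.25, ...) photo_params(q = q, ...)

#' Absolute-scale two-state parameter fixture
#'
#' A fast-equilibrating absolute parameterisation of the two-state system,
#' used as an independent oracle for the scaled one-variable reduction. The
#' photoconversion rates (7000, 990 and 10 per day) equilibrate Pr and Pfr on
#' a ~10 s timescale, far faster than the decay rates, and imply
#' `K_Pfr = 7000 / (990 + 10) = 7`. `k_Pr = gamma_Pr` makes the dark
#' stationary total equal 1 on the absolute scale. These magnitudes are an
#' illustrative fixture consistent with the composite calibration, not
#' measured constants.
#'
#' @param ... Overrides passed to [photo_params()].
#' @return A `photo_params` object with absolute constants set.
#' @export
two_state_photo_params <- function(...) {
  gamma_Pr <- 3 * log(2) / 8.75
  photo_params(k_Pr = gamma_Pr, k_Pfr_plus = 7000, k_Pfr_minus = 990,
               k_dark = 10, gamma_Pr = gamma_Pr, ...)
}

#' Composite photoequilibrium quantities
#'
#' Returns `Q_Pfr = (1 + Gamma_Pfr * K_Pfr) / (1 + K_Pfr)`, the pooled-decay
#' composite, and `R_Pfr = K_Pfr / (1 + K_Pfr)`, the Pfr fraction of total
#' phytochrome. In darkness (`K_Pfr = 0`) these reduce to `Q_Pfr = 1` and
#' `R_Pfr = 0`.
#'
#' @param params A [photo_params()] object.
#' @return Named list with elements `Q_Pfr` and `R_Pfr`.
#' @examples
#' derive_photo_composites(photo_params(K_Pfr = 7, Gamma_Pfr = 69/7))
#' @export
derive_photo_composites <- function(params) {
  stopifnot(inherits(params, "photo_params"))
  list(Q_Pfr = params$Q_Pfr, R_Pfr = params$R_Pfr)
}

#' Convert a half-life into a first-order rate constant
#'
#' `log(2) / half_life`, expressed per day. Used to calibrate the pooled
#' PhyB decay rate `Q_Pfr * gamma_Pr` from the observed 8-hour half-life of
#' PhyB in red light (`3 * log(2)` per day) and the fast PIF3 scale
#' `gamma_PIF * R_PP` from the 15-minute PIF3 half-life (96 per day).
#'
#' @param half_life Half-life, `> 0`.
#' @param unit Unit of `half_life`: `"days"`, `"hours"` or `"minutes"`.
#' @return Rate constant, per day.
#' @examples
#' rate_from_halflife(8, "hours")    # 3 log(2) = 2.079 per day
#' rate_from_halflife(15, "minutes") # 96 log(2) = 66.54 per day
#' @export
rate_from_halflife <- function(half_life, unit = c("days", "hours", "minutes")) {
  unit <- match.arg(unit)
  if (!is.numeric(half_life) || length(half_life) != 1L || is.na(half_life) ||
      half_life <= 0)
    stop("`half_life` must be a single positive number", call. = FALSE)
  per_day <- c(days = 1, hours = 24, minutes = 1440)[[unit]]
  log(2) / half_life * per_day
}

#' Closed-form total PhyB level after the dark-to-light switch
#'
#' The scaled total phytochrome concentration (relative to the dark
#' stationary level) after light induction at `t = 0`:
#' `[PhyB](t) = 1/Q_Pfr + (1 - 1/Q_Pfr) * exp(-Q_Pfr * gamma_Pr * t)`,
#' multiplied by the mutant abundance scaling `q`. Monotone non-increasing
#' for `Q_Pfr > 1`, decaying from `q` to the stationary level `q / Q_Pfr`.
#'
#' @param t Time since light onset, days (`>= 0`); vectorised.
#' @param params A [photo_params()] object.
#' @return Dimensionless PhyB level(s), same length as `t`.
#' @examples
#' phyb_closed_form(c(0, 1), photo_params())  # 1, 0.225
#' @export
phyb_closed_form <- function(t, params = photo_params()) {
  stopifnot(inherits(params, "photo_params"))
  if (any(t < 0)) stop("`t` must be non-negative (days)", call. = FALSE)
  Q <- params$Q_Pfr
  params$q * (1 / Q + (1 - 1 / Q) * exp(-Q * params$gamma_Pr * t))
}

#' Active Pfr level after the dark-to-light switch
#'
#' Under fast photoequilibration the active form is a constant fraction of
#' the total pool: `[Pfr](t) = R_Pfr * [PhyB](t)`. In darkness
#' (`K_Pfr = 0`) this is identically zero.
#'
#' @inheritParams phyb_closed_form
#' @return Dimensionless Pfr level(s) on the scale of the dark total PhyB.
#' @examples
#' pfr_level(0, photo_params())  # 0.875
#' @export
pfr_level <- function(t, params = photo_params()) {
  stopifnot(inherits(params, "photo_params"))
  params$R_Pfr * phyb_closed_form(t, params)
}

#' Numerically integrate the phytochrome model
#'
#' Integrates either the scaled one-variable reduction
#' `d[PhyB]/dt = gamma_Pr (1 - Q_Pfr [PhyB])`, `[PhyB](0) = 1`
#' (`form = "scaled"`, the oracle for [phyb_closed_form()]), or the
#' absolute-scale two-variable Pr/Pfr system (`form = "two_state"`, which
#' requires the absolute rate constants). The two-state integration starts
#' from the dark stationary state (all phytochrome as Pr, total 1 on the
#' relative scale) with light switched on at `t = 0`; setting
#' `light = FALSE` keeps `k_Pfr_plus = 0` (continued darkness).
#'
#' @param params A [photo_params()] object (with absolute constants for
#'   `form = "two_state"`).
#' @param times Strictly increasing time grid in days starting at 0.
#' @param form `"scaled"` or `"two_state"`.
#' @param light Logical; only used by the two-state form.
#' @param rtol,atol Solver tolerances (lsoda).
#' @return A data.frame with column `time` plus `phyb` and `pfr` (and for the
#'   two-state form also `pr`), all relative to the dark stationary total.
#' @examples
#' tr <- integrate_phyb(photo_params(), seq(0, 2, by = 0.5))
#' tr$phyb[tr$time == 1]  # 0.225
#' @export
integrate_phyb <- function(params = photo_params(), times,
                           form = c("scaled", "two_state"),
                           light = TRUE, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "photo_params"))
  form <- match.arg(form)
  check_time_grid(times)

  if (form == "scaled") {
    Q <- params$Q_Pfr; g <- params$gamma_Pr
    sol <- deSolve::ode(
      y = c(phyb = 1), times = times,
      func = function(t, y, p) list(g * (1 - Q * y[[1]])),
      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
    check_ode(sol, length(times), "scaled phytochrome")
    phyb <- params$q * sol[, "phyb"]
    out <- data.frame(time = times, phyb = phyb, pfr = params$R_Pfr * phyb)
  } else {
    if (is.null(params$k_Pr))
      stop("two-state form requires the absolute rate constants; see two_state_photo_params()",
           call. = FALSE)
    kp <- if (light) params$k_Pfr_plus else 0
    km <- params$k_Pfr_minus + params$k_dark
    dark_total <- params$k_Pr / params$gamma_Pr
    rhs <- function(t, y, p) {
      list(c(
        params$k_Pr + km * y[[2]] - (kp + params$gamma_Pr) * y[[1]],
        kp * y[[1]] - (km + params$gamma_Pfr) * y[[2]]
      ))
    }
    sol <- deSolve::ode(y = c(pr = dark_total, pfr = 0), times = times,
                        func = rhs, parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    check_ode(sol, length(times), "two-state phytochrome")
    pr <- params$q * sol[, "pr"] / dark_total
    pfr <- params$q * sol[, "pfr"] / dark_total
    out <- data.frame(time = times, pr = pr, pfr = pfr, phyb = pr + pfr)
  }
  attr(out, "photo") <- params
  out
}

# internal validators ---------------------------------------------------------

check_time_grid <- function(times) {
  if (!is.numeric(times) || length(times) < 2L)
    stop("`times` must be a numeric grid with at least two points", call. = FALSE)
  if (times[1] != 0)
    stop("`times` must start at 0 (light onset)", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  invisible(times)
}

check_ode <- function(sol, n_expected, what) {
  if (nrow(sol) != n_expected || anyNA(sol))
    stop(sprintf("ODE integration of the %s system failed (istate diagnostics: %s)",
                 what, paste(attr(sol, "istate"), collapse = " ")),
         call. = FALSE)
  invisible(sol)
}
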