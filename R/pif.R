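#' Reduced PIF3 dynamics parameters
#'
#' Parameters of the one-variable, relative-to-dark PIF3 equation
#' `d[PIF]/dt = gamma_PIF (1 - [PIF] - R_PP [PhyB]^2 [PIF]^2)`.
#' `R_PP` lumps the phosphorylation rate, the PIF and Pfr dimerisation
#' equilibria, the Pfr fraction and the dark PIF level into a single
#' dimensionless PhyB-PIF3 interaction strength; `R_PP = 0` leaves PIF at
#' its dark fixed point 1. Defaults are the red-light calibration
#' `R_PP = 350` with `gamma_PIF * R_PP = 96` per day, i.e. a 15-minute
#' PIF3 half-life immediately after light onset.
#'
#' @param R_PP Dimensionless PhyB-PIF3 interaction strength (`>= 0`).
#' @param gamma_PIF Basal PIF3 decay rate, per day (`> 0`).
#' @return An object of class `pif_params`.
#' @export
pif_params <- function(R_PP = 350, gamma_PIF = 96 / 350) {
  if (!is.numeric(R_PP) || length(R_PP) != 1L || is.na(R_PP) || R_PP < 0)
    stop("`R_PP` must be a single non-negative number", call. = FALSE)
  if (!is.numeric(gamma_PIF) || length(gamma_PIF) != 1L || gamma_PIF <= 0)
    stop("`gamma_PIF` must be a single positive number (per day)", call. = FALSE)
  structure(list(R_PP = R_PP, gamma_PIF = gamma_PIF), class = "pif_params")
}

#' @export
print.pif_params <- function(x, ...) {
  cat(sprintf("PIF3 reduced dynamics: R_PP = %g, gamma_PIF = %g /day (fast scale %g /day)\n",
              x$R_PP, x$gamma_PIF, x$R_PP * x$gamma_PIF))
  invisible(x)
}

#' Full three-variable PIF3 system parameters
#'
#' Rate constants of the unreduced PIF3 model with explicit monomer
#' (`PIF`), unphosphorylated dimer (`PIF2`) and phosphorylated dimer
#' (`PIF2*`) pools: constitutive synthesis, monomer decay, dimer on/off
#' exchange, Pfr-dimer-mediated phosphorylation, un-phosphorylation,
#' proteasomal decay of the phosphorylated dimer, and decay of the
#' unphosphorylated dimer.
#'
#' The individual constants of this system are not experimentally
#' constrained; the defaults are an illustrative fixture chosen to satisfy
#' the reduction regime (fast dimer exchange, `epsilon` small compared with
#' `k_PR * [Pfr]^2` and `gamma_star`, `gamma_2PIF` small compared with
#' `gamma_PIF`) while reproducing the lumped interaction strength
#' `R_PP = k_PR * K_dim_PIF * K_dim_Pfr * R_Pfr^2 * PIF_dark / gamma_PIF = 350`
#' at the default photoequilibrium (`R_Pfr = 0.875`). They are a consistency
#' fixture for testing the model reduction, not measured values.
#'
#' @param k_PIF Constitutive PIF synthesis rate (concentration/day). `NULL`
#'   (default) solves for the value that puts the dark monomer steady state
#'   at `PIF_dark`.
#' @param gamma_PIF Monomer decay rate, per day.
#' @param k_PIF2_plus,k_PIF2_minus Dimerisation on/off rates; their ratio is
#'   the PIF dimer equilibrium constant `K_dim_PIF`.
#' @param k_PR Phosphorylation rate constant of PIF dimers by Pfr dimers.
#' @param K_dim_Pfr Effective Pfr dimer equilibrium constant.
#' @param epsilon Un-phosphorylation rate, per day.
#' @param gamma_star Proteasomal decay rate of the phosphorylated dimer,
#'   per day.
#' @param gamma_2PIF Decay rate of the unphosphorylated dimer, per day.
#' @param PIF_dark Dark reference monomer concentration.
#' @return An object of class `pif_full_params`, including the derived
#'   `K_dim_PIF` and the dark steady state (`pif_dark`, `pif2_dark`).
#' @seealso [integrate_full_pif()]
#' @export
pif_full_params <- function(k_PIF = NULL,
                            gamma_PIF = 96 / 350,
                            k_PIF2_plus = 5000,
                            k_PIF2_minus = 1e6,
                            k_PR = 96 / (0.005 * (7 / 8)^2),
                            K_dim_Pfr = 1,
                            epsilon = 0.1,
                            gamma_star = 1000,
                            gamma_2PIF = 1e-3 * 96 / 350,
                            PIF_dark = 1) {
  vals <- c(gamma_PIF = gamma_PIF, k_PIF2_plus = k_PIF2_plus,
            k_PIF2_minus = k_PIF2_minus, k_PR = k_PR, K_dim_Pfr = K_dim_Pfr,
            epsilon = epsilon, gamma_star = gamma_star,
            gamma_2PIF = gamma_2PIF, PIF_dark = PIF_dark)
  if (any(vals < 0) || gamma_PIF <= 0 || k_PIF2_minus <= 0 || PIF_dark <= 0)
    stop("pif_full_params: rates must be non-negative, gamma_PIF, k_PIF2_minus and PIF_dark positive",
         call. = FALSE)
  K_dim_PIF <- k_PIF2_plus / k_PIF2_minus
  # dark steady state: dimers in quasi-equilibrium with slow decay gamma_2PIF
  dimer_of <- function(p) k_PIF2_plus * p^2 / (k_PIF2_minus + gamma_2PIF)
  if (is.null(k_PIF)) {
    k_PIF <- gamma_PIF * PIF_dark + gamma_2PIF * dimer_of(PIF_dark)
    pif_dark <- PIF_dark
  } else {
    f <- function(p) k_PIF - gamma_PIF * p - gamma_2PIF * dimer_of(p)
    pif_dark <- uniroot(f, c(0, 10 * k_PIF / gamma_PIF + 1), tol = 1e-12)$root
  }
  structure(list(
    k_PIF = k_PIF, gamma_PIF = gamma_PIF,
    k_PIF2_plus = k_PIF2_plus, k_PIF2_minus = k_PIF2_minus,
    K_dim_PIF = K_dim_PIF, k_PR = k_PR, K_dim_Pfr = K_dim_Pfr,
    epsilon = epsilon, gamma_star = gamma_star, gamma_2PIF = gamma_2PIF,
    PIF_dark = PIF_dark,
    pif_dark = pif_dark, pif2_dark = dimer_of(pif_dark)
  ), class = "pif_full_params")
}

#' Lumped interaction strength implied by full-system parameters
#'
#' `R_PP = k_PR * K_dim_PIF * K_dim_Pfr * R_Pfr^2 * PIF_dark / gamma_PIF`,
#' the interaction strength the reduced model inherits from a full
#' parameterisation at a given photoequilibrium.
#'
#' @param full A [pif_full_params()] object.
#' @param photo A [photo_params()] object supplying `R_Pfr`.
#' @return A [pif_params()] object with the implied `R_PP`.
#' @export
reduced_pif_params <- function(full, photo = photo_params()) {
  stopifnot(inherits(full, "pif_full_params"), inherits(photo, "photo_params"))
  R_PP <- full$k_PR * full$K_dim_PIF * full$K_dim_Pfr * photo$R_Pfr^2 *
    full$PIF_dark / full$gamma_PIF
  pif_params(R_PP = R_PP, gamma_PIF = full$gamma_PIF)
}

#' Right-hand side of the reduced PIF3 equation
#'
#' `gamma_PIF * (1 - pif - R_PP * phyb^2 * pif^2)`, the rate of change of
#' the relative PIF3 level. Zero at the dark fixed point (`pif = 1`,
#' `phyb = 0`) and on the slow manifold [pif_slow()].
#'
#' @param pif Relative PIF3 level (`>= 0`); vectorised.
#' @param phyb Relative total PhyB level (`>= 0`); vectorised.
#' @param params A [pif_params()] object.
#' @return Rate(s) of change, per day.
#' @export
pif_reduced_rhs <- function(pif, phyb, params = pif_params()) {
  stopifnot(inherits(params, "pif_params"))
  if (any(pif < 0) || any(phyb < 0))
    stop("`pif` and `phyb` must be non-negative", call. = FALSE)
  params$gamma_PIF * (1 - pif - params$R_PP * phyb^2 * pif^2)
}

#' Integrate the reduced PIF3 equation driven by the PhyB closed form
#'
#' Solves `d[PIF]/dt = gamma_PIF (1 - [PIF] - R_PP [PhyB](t)^2 [PIF]^2)`
#' with `[PIF](0) = 1` and `[PhyB](t)` from [phyb_closed_form()] (including
#' any mutant scaling `q`). With the default calibration the solution drops
#' rapidly on the 15-minute scale, reaches its minimum well before one day,
#' and then recovers slowly as Pfr decays.
#'
#' @param params A [pif_params()] object.
#' @param photo A [photo_params()] object.
#' @param times Time grid in days starting at 0.
#' @param rtol,atol Solver tolerances (lsoda).
#' @return Data.frame with columns `time`, `pif` (and `phyb`, `pfr` for
#'   convenience); attribute `params` records the parameter objects.
#' @export
integrate_pif <- function(params = pif_params(), photo = photo_params(),
                          times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "pif_params"), inherits(photo, "photo_params"))
  check_time_grid(times)
  rhs <- function(t, y, p) {
    b <- phyb_closed_form(t, photo)
    list(params$gamma_PIF * (1 - y[[1]] - params$R_PP * b^2 * y[[1]]^2))
  }
  sol <- deSolve::ode(y = c(pif = 1), times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  check_ode(sol, length(times), "reduced PIF3")
  out <- data.frame(time = times, pif = pmax(sol[, "pif"], 0),
                    phyb = phyb_closed_form(times, photo),
                    pfr = pfr_level(times, photo))
  attr(out, "params") <- list(pif = params, photo = photo)
  out
}

#' Integrate the full three-variable PIF3 system
#'
#' Solves the explicit monomer/dimer/phosphorylated-dimer system
#' driven by an arbitrary Pfr time course:
#' \deqn{d[PIF]/dt = k_{PIF} - \gamma_{PIF}[PIF] - k^+[PIF]^2 + k^-[PIF_2]}
#' \deqn{d[PIF_2]/dt = k^+[PIF]^2 - k^-[PIF_2] - k_{PR} K^{Pfr}_{dim} [Pfr]^2 [PIF_2] - \gamma_{2PIF}[PIF_2] + \epsilon[PIF_2^*]}
#' \deqn{d[PIF_2^*]/dt = k_{PR} K^{Pfr}_{dim}[Pfr]^2 [PIF_2] - \epsilon[PIF_2^*] - \gamma^*[PIF_2^*]}
#' starting from the dark steady state. In the reduction regime (fast dimer
#' exchange, small `epsilon` and `gamma_2PIF`) the monomer-equivalent total,
#' relative to its dark value, tracks the reduced solution of
#' [integrate_pif()].
#'
#' @param params A [pif_full_params()] object.
#' @param pfr_fn Function of time (days) returning the absolute Pfr level
#'   driving phosphorylation, e.g. `function(t) pfr_level(t, photo)`.
#' @param times Time grid in days starting at 0.
#' @param rtol,atol Solver tolerances (lsoda; the dimer exchange makes the
#'   system stiff).
#' @return Data.frame with columns `time`, `pif`, `pif2`, `pif2_star`,
#'   `total` (monomer equivalents, `pif + 2 pif2 + 2 pif2_star`) and
#'   `total_rel` (total relative to its dark value).
#' @export
integrate_full_pif <- function(params, pfr_fn, times,
                               rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(params, "pif_full_params"), is.function(pfr_fn))
  check_time_grid(times)
  p <- params
  rhs <- function(t, y, parms) {
    pfr2 <- p$K_dim_Pfr * pfr_fn(t)^2
    list(c(
      p$k_PIF - p$gamma_PIF * y[[1]] - p$k_PIF2_plus * y[[1]]^2 +
        p$k_PIF2_minus * y[[2]],
      p$k_PIF2_plus * y[[1]]^2 - p$k_PIF2_minus * y[[2]] -
        p$k_PR * pfr2 * y[[2]] - p$gamma_2PIF * y[[2]] + p$epsilon * y[[3]],
      p$k_PR * pfr2 * y[[2]] - (p$epsilon + p$gamma_star) * y[[3]]
    ))
  }
  y0 <- c(pif = p$pif_dark, pif2 = p$pif2_dark, pif2_star = 0)
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  check_ode(sol, length(times), "full PIF3")
  total <- sol[, "pif"] + 2 * sol[, "pif2"] + 2 * sol[, "pif2_star"]
  dark_total <- p$pif_dark + 2 * p$pif2_dark
  out <- data.frame(time = times, pif = sol[, "pif"], pif2 = sol[, "pif2"],
                    pif2_star = sol[, "pif2_star"], total = total,
                    total_rel = total / dark_total)
  attr(out, "params") <- params
  out
}

#' Fast-limit PIF3 solution
#'
#' Immediately after light onset PhyB is still near 1 and the quadratic
#' degradation term dominates, giving the hyperbolic decay
#' `[PIF]_fast(t) = 1 / (1 + gamma_PIF * R_PP * t)` (the integration
#' constant is fixed to 1 by `[PIF](0) = 1`). The half-value time is exactly
#' `1 / (gamma_PIF * R_PP)`, 15 minutes at the default calibration.
#'
#' @param t Time in days (`>= 0`); vectorised.
#' @param params A [pif_params()] object.
#' @return Dimensionless PIF3 level(s).
#' @examples
#' pif_fast(1 / 96, pif_params())  # 0.5 at t = 15 min
#' @export
pif_fast <- function(t, params = pif_params()) {
  stopifnot(inherits(params, "pif_params"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  1 / (1 + params$gamma_PIF * params$R_PP * t)
}

#' Slow-manifold (quasi-steady-state) PIF3 level
#'
#' The positive root of `1 - p - R_PP * phyb^2 * p^2 = 0`, the PIF3 level
#' in quasi-equilibrium with a slowly varying PhyB level:
#' `[PIF]_slow = (sqrt(1 + 4 R_PP phyb^2) - 1) / (2 R_PP phyb^2)`,
#' evaluated in the cancellation-free form `2 / (1 + sqrt(1 + 4 a))` with
#' `a = R_PP * phyb^2`, which handles the `phyb -> 0` and `R_PP -> 0`
#' limits (value 1) exactly.
#'
#' @param phyb Relative total PhyB level (`>= 0`); vectorised.
#' @param params A [pif_params()] object.
#' @return Dimensionless level(s) in `(0, 1]`.
#' @export
pif_slow <- function(phyb, params = pif_params()) {
  stopifnot(inherits(params, "pif_params"))
  if (any(phyb < 0)) stop("`phyb` must be non-negative", call. = FALSE)
  a <- params$R_PP * phyb^2
  2 / (1 + sqrt(1 + 4 * a))
}

#' Combined closed-form PIF3 solution
#'
#' The explicit approximation obtained by matching the fast hyperbolic decay
#' onto the slow quasi-steady-state response of the decaying PhyB level
#' (assuming `4 R_PP / Q_Pfr >> 1` and freezing the slowly varying square
#' root):
#' \deqn{[PIF](t) \approx \frac{1}{1 + \gamma_{PIF} R_{PP} t} +
#'   \frac{Q_{Pfr}(\sqrt{R_{PP}} - Q_{Pfr}/2)}
#'        {R_{PP}(1 + (Q_{Pfr} - 1) e^{-Q_{Pfr}\gamma_{Pr} t})^2}}
#' The `t = 0` value is 1 to within about 0.5% and the `t -> infinity`
#' limit is `Q_Pfr (sqrt(R_PP) - Q_Pfr/2) / R_PP` (0.35833 at defaults,
#' about 3.4% below the exact slow-manifold stationary value 0.37095).
#' The formula is derived for wild-type abundance; a `photo` object with
#' `q != 1` triggers a warning and `q` is ignored (use [integrate_pif()]
#' for mutants). With `R_PP = 0` the dark value 1 is returned.
#'
#' @param t Time in days (`>= 0`); vectorised.
#' @param params A [pif_params()] object.
#' @param photo A [photo_params()] object.
#' @return Dimensionless PIF3 level(s).
#' @export
pif_closed_form <- function(t, params = pif_params(), photo = photo_params()) {
  stopifnot(inherits(params, "pif_params"), inherits(photo, "photo_params"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (params$R_PP == 0) return(rep(1, length(t)))
  if (photo$q != 1)
    warning("pif_closed_form() is derived for wild-type abundance; q is ignored (use integrate_pif() for mutants)")
  Q <- photo$Q_Pfr; R <- params$R_PP
  if (4 * R / Q < 10)
    warning(sprintf("closed form assumes 4*R_PP/Q_Pfr >> 1; here it is %.3g",
                    4 * R / Q))
  fast <- 1 / (1 + params$gamma_PIF * R * t)
  slow <- Q * (sqrt(R) - Q / 2) /
    (R * (1 + (Q - 1) * exp(-Q * photo$gamma_Pr * t))^2)
  fast + slow
}

#' Long-time limit of the closed-form PIF3 solution
#'
#' `Q_Pfr * (sqrt(R_PP) - Q_Pfr / 2) / R_PP`, the stationary PIF3 level
#' implied by the combined closed form; used as the default PIF input of the
#' stationary gene-expression level.
#'
#' @inheritParams pif_closed_form
#' @return A single dimensionless value (1 when `R_PP = 0`).
#' @export
pif_closed_form_limit <- function(params = pif_params(), photo = photo_params()) {
  stopifnot(inherits(params, "pif_params"), inherits(photo, "photo_params"))
  if (params$R_PP == 0) return(1)
  photo$Q_Pfr * (sqrt(params$R_PP) - photo$Q_Pfr / 2) / params$R_PP
}
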