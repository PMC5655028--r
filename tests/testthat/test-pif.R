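test_that("reduced PIF3 rate vanishes at the dark fixed point and on the slow manifold", {
  pp <- default_pif
  expect_equal(pif_reduced_rhs(1, 0, pp), 0)
  # dark-cancellation leaves the pure quadratic sink: gamma_PIF * (-R_PP) = -96
  expect_equal(pif_reduced_rhs(1, 1, pp), -96)
  for (b in c(0, 0.1, 1 / 8.75, 0.5, 1))
    expect_equal(pif_reduced_rhs(pif_slow(b, pp), b, pp), 0, tolerance = 1e-12)
  expect_error(pif_reduced_rhs(-0.1, 1, pp), "non-negative")
})

test_that("fast-limit solution halves at 1/(gamma_PIF R_PP) and decays hyperbolically", {
  pp <- default_pif
  expect_equal(pif_fast(0, pp), 1)
  expect_equal(pif_fast(1 / 96, pp), 0.5)       # 15 minutes
  expect_equal(pif_fast(45 / 1440, pp), 0.25)   # 45 minutes: 1/(1+3)
})

test_that("slow manifold takes its frozen values and limits", {
  pp <- default_pif
  expect_equal(pif_slow(1, pp), (sqrt(1401) - 1) / 700)
  expect_equal(pif_slow(1, pp), 0.0520428, tolerance = 1e-6)
  expect_equal(pif_slow(1 / 8.75, pp), 0.3709508, tolerance = 1e-6)
  expect_equal(pif_slow(0, pp), 1)
  expect_equal(pif_slow(1, pif_params(R_PP = 0)), 1)
  expect_true(all(pif_slow(seq(0, 2, by = 0.1), pp) <= 1))
})

test_that("combined closed form matches frozen values and its long-time limit", {
  pp <- default_pif; p <- default_photo
  expect_equal(pif_closed_form(0, pp, p), 1.0046803, tolerance = 1e-6)
  expect_equal(pif_closed_form(1, pp, p), 0.1027588, tolerance = 1e-6)
  expect_equal(pif_closed_form_limit(pp, p),
               8.75 * (sqrt(350) - 4.375) / 350)
  expect_equal(pif_closed_form_limit(pp, p), 0.3583322, tolerance = 1e-6)
  expect_equal(pif_closed_form(0.5, pif_params(R_PP = 0), p), 1)
  expect_warning(pif_closed_form(1, pif_params(R_PP = 10), p), "4\\*R_PP")
  expect_warning(pif_closed_form(1, pp, photo_params(q = 0.5)), "wild-type")
})

test_that("fast term dominates the closed form for the first ten minutes", {
  tt <- seq(0, 10 / 1440, length.out = 20)
  expect_lt(max(rel_err(pif_closed_form(tt, default_pif, default_photo),
                        pif_fast(tt, default_pif))), 0.01)
})

test_that("numeric PIF3 solution decays fast, dips below 0.1, then recovers to the slow manifold", {
  ptr <- pif_traj7
  i <- which.min(ptr$pif)
  expect_gt(ptr$pif[i], 0)
  expect_lt(ptr$pif[i], 0.1)
  expect_lt(ptr$time[i], 1)
  # quasi-steady state at the end of the week
  expect_lt(rel_err(ptr$pif[nrow(ptr)],
                    pif_slow(phyb_closed_form(7, default_photo), default_pif)),
            0.05)
  # no interaction, no response
  null <- integrate_pif(pif_params(R_PP = 0), default_photo, seq(0, 7, by = 0.5))
  expect_equal(null$pif, rep(1, nrow(null)), tolerance = 1e-9)
})

test_that("stronger PhyB-PIF3 interaction never raises the PIF3 level", {
  tt <- seq(0, 7, by = 0.25)
  prev <- NULL
  for (R in c(50, 150, 350, 700)) {
    cur <- integrate_pif(pif_params(R_PP = R, gamma_PIF = 96 / 350),
                         default_photo, tt)$pif
    if (!is.null(prev)) expect_true(all(cur <= prev + 1e-9))
    prev <- cur
  }
})

test_that("full three-variable system holds its dark state and ignores light when k_PR = 0", {
  fp <- pif_full_params()
  tt <- seq(0, 2, by = 0.1)
  dark <- integrate_full_pif(fp, function(t) rep(0, length(t)), tt)
  expect_equal(dark$pif, rep(fp$pif_dark, length(tt)), tolerance = 1e-7)
  expect_equal(dark$total_rel, rep(1, length(tt)), tolerance = 1e-7)

  nolight <- integrate_full_pif(pif_full_params(k_PR = 0),
                                function(t) pfr_level(t, default_photo), tt)
  expect_equal(nolight$total_rel, rep(1, length(tt)), tolerance = 1e-7)
})

test_that("full system tracks the reduced equation in the stated regime", {
  fp <- pif_full_params()
  implied <- reduced_pif_params(fp, default_photo)
  expect_equal(implied$R_PP, 350, tolerance = 1e-12)
  full <- integrate_full_pif(fp, function(t) pfr_level(t, default_photo), grid7)
  sel <- grid7 >= 0.05
  expect_lt(max(rel_err(full$total_rel[sel], pif_traj7$pif[sel])), 0.05)
})
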