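test_that("generator configuration is validated", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(1, sampling_times = c(0.5, 1)), "start at 0")
  expect_error(synthetic_config(1, n_replicates = 0), "n_replicates")
  expect_error(synthetic_config(1, noise_cv = -0.1), "noise_cv")
})

test_that("zero-noise series equal the forward model exactly", {
  sc <- synthetic_config(seed = 1, noise_cv = 0)
  g <- gene_params("SIG6", 0.22)
  s <- gen_expression_series(sc, g)
  ptr <- integrate_pif(default_pif, default_photo,
                       signalling_grid(7, extra = sc$sampling_times))
  x <- integrate_expression(g, ptr, times = sc$sampling_times)$expression
  expect_equal(as.vector(s$replicates), rep(x, sc$n_replicates),
               tolerance = 1e-12)
  expect_equal(s$mean[1], 1)  # fold change is 1 at light onset
})

test_that("replicate summaries follow their definitions", {
  sc <- synthetic_config(seed = 3)
  s <- gen_expression_series(sc, gene_params("SIG2", 0.32))
  expect_equal(s$n, rep(9L, length(s$times)))
  expect_equal(s$se, apply(s$replicates, 1, sd) / sqrt(9))
  expect_true(all(s$replicates > 0))
})

test_that("lognormal noise is unbiased: sample means stay within 3 SE of the model", {
  sc <- synthetic_config(seed = 1, n_replicates = 9, noise_cv = 0.15)
  g <- gene_params("PAP1", 0.35)
  s <- gen_expression_series(sc, g)
  ptr <- integrate_pif(default_pif, default_photo,
                       signalling_grid(7, extra = sc$sampling_times))
  x <- integrate_expression(g, ptr, times = sc$sampling_times)$expression
  z <- abs(s$mean - x) / s$se
  expect_true(all(z < 3))
})

test_that("empirical replicate noise matches the configured CV across many seeds", {
  # pool replicate CVs at each sampling time over 200 seeded series
  cvs <- sapply(1:200, function(seed) {
    sc <- synthetic_config(seed = seed, noise_cv = 0.15)
    s <- gen_expression_series(sc, gene_params("SIG2", 0.32))
    apply(s$replicates, 1, function(r) sd(r) / mean(r))
  })
  per_point <- rowMeans(cvs)
  expect_true(all(abs(per_point - 0.15) / 0.15 < 0.20))
})

test_that("same seed and configuration give bit-identical files", {
  sc <- synthetic_config(seed = 77)
  s1 <- gen_expression_series(sc, gene_params("PRIN2", 0.09))
  s2 <- gen_expression_series(sc, gene_params("PRIN2", 0.09))
  expect_identical(s1, s2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_expression_long(list(s1), f1); write_expression_long(list(s2), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  p1 <- gen_promoters(sc); p2 <- gen_promoters(sc)
  expect_identical(p1, p2)
  g1 <- tempfile(fileext = ".fa"); g2 <- tempfile(fileext = ".fa")
  write_promoters_fasta(p1, g1); write_promoters_fasta(p2, g2)
  expect_identical(readBin(g1, "raw", file.size(g1)),
                   readBin(g2, "raw", file.size(g2)))
  unlink(c(f1, f2, g1, g2))
})

test_that("decay series sample the forward model and support rate recovery", {
  sc0 <- synthetic_config(seed = 2, decay_sd = 0)
  phyb <- gen_decay_series(sc0, "phyb")
  expect_equal(phyb$value[phyb$time == 1], 0.225, tolerance = 1e-9)
  pifd <- gen_decay_series(sc0, "pif")
  expect_equal(pifd$value[abs(pifd$time - 1 / 96) < 1e-9], 0.5,
               tolerance = 0.02)
  fit <- fit_exponential_halflife(phyb$time, phyb$value)
  expect_lt(rel_err(fit$rate, 3 * log(2)), 1e-6)
  # noise is seeded and additive
  scn <- synthetic_config(seed = 2, decay_sd = 0.02)
  n1 <- gen_decay_series(scn, "phyb"); n2 <- gen_decay_series(scn, "phyb")
  expect_identical(n1, n2)
  expect_false(all(n1$value == phyb$value))
})

test_that("planted promoters are recovered exactly by the scanner", {
  sc <- synthetic_config(seed = 13)
  pr <- gen_promoters(sc)
  expect_equal(length(pr), 13)
  expect_true(all(nchar(pr) == 3000))
  hits <- scan_motifs(pr)
  plan <- attr(pr, "plants")
  for (sid in names(plan)) {
    for (k in seq_len(nrow(plan[[sid]]))) {
      sel <- hits$seq_id == sid & hits$motif == plan[[sid]]$motif[k] &
        hits$offset == plan[[sid]]$offset[k]
      # palindromic motifs hit both strands at the planted offset
      expected_n <- if (plan[[sid]]$motif[k] == "G-box") 2L else 1L
      expect_equal(sum(sel), expected_n)
    }
  }
  # and nothing else: every hit corresponds to a plant
  n_planted <- sum(vapply(plan, function(p)
    sum(ifelse(p$motif == "G-box", 2L, 1L)), integer(1)))
  expect_equal(nrow(hits), n_planted)
  # presence pattern mirrors the plan
  tab <- presence_table(hits, seq_ids = names(pr))
  expect_true(all(tab$`PBE-box`))
  expect_equal(tab$seq_id[tab$`G-box`],
               c("SIG4", "SIG5", "PAP1", "PAP11", "PRIN2"))
  # PBE plants cluster in three regions
  m <- histogram_modes(position_histogram(hits[hits$motif == "PBE-box", ]))
  expect_equal(nrow(m), 3)
})

test_that("promoter edge cases: no plants and overlapping plants", {
  sc <- synthetic_config(seed = 4)
  none <- gen_promoters(sc, plants = list(p1 = data.frame(
    motif = character(), offset = numeric())))
  expect_equal(nrow(scan_motifs(none)), 0)
  expect_error(
    gen_promoters(sc, plants = list(p1 = data.frame(
      motif = c("PBE-box", "G-box"), offset = c(-100, -103)))),
    "overlap")
  expect_error(
    gen_promoters(sc, plants = list(p1 = data.frame(
      motif = "G-box", offset = -3))),
    "offsets")
})
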