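#' Configuration of the synthetic data generator
#'
#' Defines the study conditions emulated by the generator: sampling grid
#' over the 0-7 day greening time course, 9 independent replicates per
#' point with multiplicative lognormal noise, the six default genes, an
#' optional PhyB-abundance scaling for mutant series, and promoter
#' construction (3 kb windows at Arabidopsis-like 36% GC with planted
#' motifs). Identical seed and configuration give bit-identical output.
#'
#' @param seed Integer seed; every generator call derives its stream from
#'   it deterministically.
#' @param sampling_times Sampling times, days, sorted, starting at 0.
#' @param n_replicates Replicates per time point (`>= 1`).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (`>= 0`).
#' @param genes Gene table as in [default_gene_params()].
#' @param q PhyB abundance scaling for the generated series (1 = wild
#'   type).
#' @param decay_sd Additive Gaussian noise sd for decay-curve series.
#' @param promoter_length Promoter window length, bp.
#' @param gc Background GC fraction.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             sampling_times = c(0, 0.125, 0.25, 0.5, 1, 2, 3, 5, 7),
                             n_replicates = 9,
                             noise_cv = 0.15,
                             genes = default_gene_params(),
                             q = 1,
                             decay_sd = 0.02,
                             promoter_length = 3000,
                             gc = 0.36) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("`seed` is required (single integer)", call. = FALSE)
  if (is.unsorted(sampling_times, strictly = TRUE) || sampling_times[1] != 0)
    stop("`sampling_times` must be strictly increasing and start at 0", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("`gc` must be in (0, 1)", call. = FALSE)
  structure(list(seed = as.integer(seed), sampling_times = sampling_times,
                 n_replicates = as.integer(n_replicates), noise_cv = noise_cv,
                 genes = genes, q = q, decay_sd = decay_sd,
                 promoter_length = as.integer(promoter_length), gc = gc),
            class = "synthetic_config")
}

# deterministic sub-seed per generator call, kept below 2^31 (double
# arithmetic: large user seeds must not overflow R's 32-bit integers)
sub_seed <- function(config, tag) {
  as.integer((as.numeric(config$seed) * 1009 + sum(utf8ToInt(tag)) * 31) %%
               2147483647)
}

#' Generate a noisy fold-change expression series
#'
#' Samples the forward model at the configured times and multiplies each
#' replicate by lognormal noise with unit mean (`sdlog` chosen from
#' `noise_cv`, `meanlog = -sdlog^2/2` so the replicate mean is unbiased).
#' The day-zero point is the model value 1 with the same noise applied,
#' emulating fold-change measurements that are themselves noisy at the
#' reference point.
#'
#' @param config A [synthetic_config()].
#' @param gene A [gene_params()] object or row of the gene table.
#' @param model A [model_config()]; the generated series inherits
#'   `config$q` through its photoconversion block.
#' @return An [expression_series()] with replicates, mean, SE and n.
#' @export
gen_expression_series <- function(config, gene, model = model_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  gene <- as_gene_params(gene)
  base <- model$photo
  photo_q <- photo_params(K_Pfr = base$K_Pfr, Gamma_Pfr = base$Gamma_Pfr,
                          gamma_Pr = base$gamma_Pr, q = config$q)
  cfg <- model_config(photo = photo_q, pif = model$pif,
                      pif_source = model$pif_source)
  ptr <- forward_pif_grid(cfg, max(config$sampling_times),
                          extra = config$sampling_times)
  x <- integrate_expression(gene, ptr, times = config$sampling_times)$expression
  nt <- length(config$sampling_times); nr <- config$n_replicates
  set.seed(sub_seed(config, paste0("expr:", gene$gene_id)))
  if (config$noise_cv > 0) {
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- matrix(rlnorm(nt * nr, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = nt)
  } else {
    noise <- matrix(1, nrow = nt, ncol = nr)
  }
  expression_series(gene$gene_id, config$sampling_times,
                    replicates = x * noise)
}

#' Generate a noisy decay series
#'
#' Samples the PhyB closed form or the numeric reduced PIF3 solution on a
#' grid resolving the relevant half-life (8 h for PhyB, 15 min for PIF3)
#' and adds Gaussian noise of sd `decay_sd`. Mirrors published protein
#' decay measurements after light onset.
#'
#' @param config A [synthetic_config()].
#' @param which `"phyb"` or `"pif"`.
#' @param times Optional sampling grid (days).
#' @param model A [model_config()].
#' @return Data.frame with columns `time` and `value`.
#' @export
gen_decay_series <- function(config, which = c("phyb", "pif"), times = NULL,
                             model = model_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  which <- match.arg(which)
  if (is.null(times)) {
    times <- if (which == "phyb") sort(unique(c(seq(0, 2, by = 1 / 12), 1)))
             else sort(unique(c(0, (1:12) / 96, 0.25, 0.5, 1, 2)))
  }
  clean <- if (which == "phyb") {
    phyb_closed_form(times, model$photo)
  } else {
    grid <- signalling_grid(max(times), extra = times)
    ptr <- integrate_pif(model$pif, model$photo, grid)
    approx(grid, ptr$pif, xout = times, ties = "ordered")$y
  }
  set.seed(sub_seed(config, paste0("decay:", which)))
  noise <- if (config$decay_sd > 0) rnorm(length(times), 0, config$decay_sd) else 0
  data.frame(time = times, value = clean + noise)
}

#' Generate promoter sequences with planted motifs
#'
#' Builds i.i.d. background sequences at the configured GC fraction,
#' rewrites every spontaneous occurrence of the target motifs (on either
#' strand) so the background is clean, then plants motifs at exact
#' ATG-relative offsets. [scan_motifs()] on the output recovers exactly
#' the planted set. The default plant plan mirrors the qualitative
#' finding for the PEP-associated genes: a PBE-box in every promoter,
#' rotating through three upstream regions (around -2900, -1500 and
#' -200 bp), and a G-box in the subset where one was identified.
#'
#' @param config A [synthetic_config()].
#' @param plants Named list: for each sequence id, a data.frame with
#'   columns `motif` (name in `motifs`) and `offset` (negative,
#'   in `[-length, -motif_length]`); plants must not overlap. `NULL` uses
#'   the default plan.
#' @param motifs Named motif set (default [pif3_motifs()]).
#' @return Named character vector of sequences (writable with
#'   [write_promoters_fasta()]), with the plant plan as attribute
#'   `plants`.
#' @export
gen_promoters <- function(config, plants = NULL, motifs = pif3_motifs()) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- config$promoter_length
  if (is.null(plants)) plants <- default_plant_plan()
  set.seed(sub_seed(config, "promoters"))
  probs <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
             G = config$gc / 2, T = (1 - config$gc) / 2)
  # forbid motifs and their reverse complements anywhere in the background
  forbidden <- unique(c(toupper(motifs), reverse_complement(motifs)))
  out <- character(0)
  for (sid in names(plants)) {
    plan <- plants[[sid]]
    if (nrow(plan)) {
      widths <- nchar(motifs[plan$motif])
      if (any(plan$offset < -L) || any(plan$offset > -widths))
        stop(sprintf("'%s': plant offsets outside [-%d, -motif_length]", sid, L),
             call. = FALSE)
      starts <- L + plan$offset + 1L
      ends <- starts + widths - 1L
      o <- order(starts)
      if (any(starts[o][-1] <= ends[o][-length(o)]))
        stop(sprintf("'%s': overlapping plant positions", sid), call. = FALSE)
    }
    s <- paste(sample(names(probs), L, replace = TRUE, prob = probs),
               collapse = "")
    s <- scrub_motifs(s, forbidden, probs)
    if (nrow(plan)) {
      for (k in seq_len(nrow(plan))) {
        mo <- toupper(motifs[[plan$motif[k]]])
        st <- L + plan$offset[k] + 1L
        substr(s, st, st + nchar(mo) - 1L) <- mo
      }
      # planting can create spurious occurrences across plant boundaries;
      # rewrite flanking bases (never planted ones) until only plants remain
      planted_pos <- unlist(lapply(seq_len(nrow(plan)), function(k) {
        st <- L + plan$offset[k] + 1L
        st:(st + nchar(motifs[[plan$motif[k]]]) - 1L)
      }))
      s <- scrub_motifs(s, forbidden, probs, protect = planted_pos)
    }
    out[sid] <- s
  }
  attr(out, "plants") <- plants
  out
}

# rewrite bases until no forbidden k-mer remains; positions in `protect`
# are never modified (occurrences lying entirely inside them are kept)
scrub_motifs <- function(s, forbidden, probs, protect = integer(0)) {
  for (iter in 1:200) {
    dirty <- FALSE
    for (f in forbidden) {
      m <- gregexpr(f, s, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      for (st in as.integer(m)) {
        pos <- st:(st + nchar(f) - 1L)
        free <- setdiff(pos, protect)
        if (!length(free)) next  # a planted occurrence
        p <- free[sample.int(length(free), 1L)]
        substr(s, p, p) <- sample(names(probs), 1L, prob = probs)
        dirty <- TRUE
      }
    }
    if (!dirty) return(s)
  }
  stop("failed to scrub spontaneous motif occurrences", call. = FALSE)
}

#' Default promoter plant plan
#'
#' Thirteen PEP-associated promoters (SIG1-6, PAP1, PAP3, PAP5, PAP6,
#' PAP11, FLN2, PRIN2) each receive a PBE-box in one of three upstream
#' regions (-2900, -1500, -200 bp, rotating); those in which a G-box was
#' also identified (SIG4, SIG5, PAP1, PAP11, PRIN2) additionally receive a
#' G-box at -800 bp. A synthetic stand-in for real upstream sequences,
#' mirroring the qualitative presence pattern and the three positional
#' clusters.
#'
#' @return Named list of plant data.frames (`motif`, `offset`).
#' @export
default_plant_plan <- function() {
  ids <- c("SIG1", "SIG2", "SIG3", "SIG4", "SIG5", "SIG6",
           "PAP1", "PAP3", "PAP5", "PAP6", "PAP11", "FLN2", "PRIN2")
  regions <- c(-2900, -1500, -200)
  gbox_ids <- c("SIG4", "SIG5", "PAP1", "PAP11", "PRIN2")
  plan <- lapply(seq_along(ids), function(i) {
    df <- data.frame(motif = "PBE-box",
                     offset = regions[(i - 1L) %% 3L + 1L],
                     stringsAsFactors = FALSE)
    if (ids[i] %in% gbox_ids)
      df <- rbind(df, data.frame(motif = "G-box", offset = -800))
    df
  })
  names(plan) <- ids
  plan
}
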