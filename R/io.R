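#' Read a long-format expression CSV
#'
#' Long format: columns `gene_id`, `time_days`, `replicate`, `value`
#' (fold change relative to dark). Returns one [expression_series()] per
#' gene.
#'
#' @param path CSV path.
#' @return Named list of `expression_series`.
#' @export
read_expression_long <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "time_days", "replicate", "value")
  if (!all(need %in% names(df)))
    stop(sprintf("expression CSV must have columns %s (missing: %s)",
                 paste(need, collapse = ", "),
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  out <- lapply(split(df, df$gene_id), function(g) {
    times <- sort(unique(g$time_days))
    reps <- sort(unique(g$replicate))
    m <- matrix(NA_real_, nrow = length(times), ncol = length(reps))
    m[cbind(match(g$time_days, times), match(g$replicate, reps))] <- g$value
    if (anyNA(m))
      stop(sprintf("gene %s: incomplete replicate grid", g$gene_id[1]),
           call. = FALSE)
    expression_series(g$gene_id[1], times, replicates = m)
  })
  out[unique(df$gene_id)]
}

#' Read a summary-format expression CSV
#'
#' Summary format: columns `gene_id`, `time_days`, `mean`, `se`, `n`.
#'
#' @param path CSV path.
#' @return Named list of [expression_series()].
#' @export
read_expression_summary <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "time_days", "mean", "se", "n")
  if (!all(need %in% names(df)))
    stop(sprintf("summary CSV must have columns %s (missing: %s)",
                 paste(need, collapse = ", "),
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  out <- lapply(split(df, df$gene_id), function(g) {
    o <- order(g$time_days)
    expression_series(g$gene_id[1], g$time_days[o], mean = g$mean[o],
                      se = g$se[o], n = g$n[o])
  })
  out[unique(df$gene_id)]
}

#' Write expression series to a long-format CSV
#'
#' @param series_list List of [expression_series()] with replicate
#'   matrices.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_long <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    if (is.null(s$replicates))
      stop(sprintf("series %s has no replicates; use the summary writer", s$gene_id),
           call. = FALSE)
    nr <- ncol(s$replicates)
    data.frame(gene_id = s$gene_id,
               time_days = rep(s$times, times = nr),
               replicate = rep(seq_len(nr), each = length(s$times)),
               value = as.vector(s$replicates))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write expression series to a summary CSV
#'
#' @param series_list List of [expression_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_summary <- function(series_list, path) {
  rows <- lapply(series_list, function(s)
    data.frame(gene_id = s$gene_id, time_days = s$times, mean = s$mean,
               se = s$se, n = s$n))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to long-format CSV
#'
#' Columns `time_days`, `species`, `value`, one row per grid point and
#' species.
#'
#' @param traj Wide trajectory data.frame (column `time` plus one column
#'   per species), e.g. from [simulate_genes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  sp <- setdiff(names(traj), "time")
  long <- do.call(rbind, lapply(sp, function(s)
    data.frame(time_days = traj$time, species = s, value = traj[[s]])))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory to JSON with its parameter block
#'
#' Serialises the trajectory plus the resolved parameter configuration
#' (from the `params` attribute) for provenance.
#'
#' @inheritParams write_trajectory_csv
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(traj, path) {
  params <- attr(traj, "params")
  payload <- list(
    parameters = unclass_all(params),
    trajectory = as.list(as.data.frame(traj))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

unclass_all <- function(x) {
  if (is.list(x)) lapply(x, unclass_all) else x
}

#' Write motif hits to TSV
#'
#' @param hits Data.frame from [scan_motifs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write promoter sequences to FASTA
#'
#' @param sequences Named character vector, e.g. from [gen_promoters()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a fit result to JSON
#'
#' @param fits A `fit_result` or list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  jsonlite::write_json(lapply(fits, unclass), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
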