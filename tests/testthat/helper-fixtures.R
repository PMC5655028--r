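# shared fixtures: default parameter objects and a dense 7-day grid
default_photo <- photo_params()
default_pif <- pif_params()
grid7 <- signalling_grid(7)
pif_traj7 <- integrate_pif(default_pif, default_photo, grid7)

# brute-force O(n*m) substring scan used as the independent oracle for
# scan_motifs(): returns plus-strand starts of `pattern` in `s`
naive_starts <- function(s, pattern) {
  s <- toupper(s); pattern <- toupper(pattern)
  n <- nchar(s); m <- nchar(pattern)
  if (m > n) return(integer(0))
  which(vapply(seq_len(n - m + 1L),
               function(i) substr(s, i, i + m - 1L) == pattern, logical(1)))
}

# naive hit table in scan_motifs() layout for one sequence
naive_scan <- function(s, motifs = pif3_motifs(), window = 3000) {
  L <- nchar(s)
  sub <- if (L > window) substr(s, L - window + 1L, L) else s
  Ls <- nchar(sub)
  rows <- list()
  for (mn in names(motifs)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") motifs[[mn]] else reverse_complement(motifs[[mn]])
      st <- naive_starts(sub, pat)
      if (length(st))
        rows[[length(rows) + 1L]] <- data.frame(
          motif = mn, strand = strand, offset = st - Ls - 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(motif = character(), strand = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$offset, match(out$strand, c("+", "-")), out$motif), ,
      drop = FALSE]
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
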