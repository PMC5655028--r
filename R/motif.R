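#' PIF3 binding motifs
#'
#' The two hexamer cis-elements bound by PIF3: the palindromic G-box
#' (CACGTG) and the PBE-box (CACATG).
#'
#' @return Named character vector of motif sequences.
#' @export
pif3_motifs <- function() c("G-box" = "CACGTG", "PBE-box" = "CACATG")

#' Reverse complement of a nucleotide sequence
#'
#' Standard Watson-Crick reversal over the alphabet A/C/G/T/N
#' (case-insensitive; N maps to N). Applying it twice returns the input.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Character vector of reverse complements (upper case).
#' @examples
#' reverse_complement("CACATG")  # "CATGTG"
#' reverse_complement("CACGTG")  # its own reverse complement
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    su <- toupper(s)
    bad <- regexpr("[^ACGTN]", su)
    if (bad > 0)
      stop(sprintf("illegal character '%s' at position %d", substr(s, bad, bad), bad),
           call. = FALSE)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(su)))
  }, character(1), USE.NAMES = FALSE)
}

#' Scan promoter sequences for exact motif occurrences on both strands
#'
#' Finds every exact, case-insensitive occurrence of each motif on the plus
#' strand, and of its reverse complement (reported as a minus-strand hit),
#' within a window upstream of the translation start. The 3' end of each
#' sequence is taken to be adjacent to the A of the ATG start codon, so
#' offsets are negative ATG-relative positions of the motif's 5'-most base
#' on the plus-strand coordinate (-1 is the base immediately upstream).
#' With this FIMO-like convention, plus- and minus-strand hits of a
#' palindromic motif such as the G-box coincide. Overlapping occurrences
#' are all reported; matches containing N never count. Sequences longer
#' than `window` are scanned over their 3'-most `window` bases; shorter
#' sequences are scanned in full.
#'
#' @param sequences Named character vector of upstream sequences (names are
#'   gene/sequence ids), or a [Biostrings::DNAStringSet].
#' @param motifs Named character vector of exact motifs (defaults to
#'   [pif3_motifs()]).
#' @param window Scan window in bp upstream of ATG (default 3000).
#' @return Data.frame with columns `seq_id`, `motif`, `strand` (`+`/`-`),
#'   `offset` (negative, ATG-relative) and `match` (the plus-strand text:
#'   the motif for `+` hits, its reverse complement for `-` hits), ordered
#'   by input sequence, then offset, then strand (`+` first), then motif
#'   name.
#' @examples
#' s <- paste0(strrep("A", 100), "CACGTG", strrep("A", 50))
#' scan_motifs(c(g1 = s))  # palindromic G-box: one hit per strand at -56
#' @export
scan_motifs <- function(sequences, motifs = pif3_motifs(), window = 3000) {
  if (inherits(sequences, "DNAStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  if (!is.character(sequences) || length(sequences) == 0L)
    stop("`sequences` must be a non-empty named character vector or DNAStringSet",
         call. = FALSE)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("`sequences` must be named (sequence ids)", call. = FALSE)
  if (length(motifs) == 0L || any(!nzchar(motifs)))
    stop("`motifs` must be non-empty motif strings", call. = FALSE)
  if (is.null(names(motifs))) names(motifs) <- motifs
  if (!is.numeric(window) || window <= 0)
    stop("`window` must be positive", call. = FALSE)

  rows <- list()
  for (sid in names(sequences)) {
    s <- toupper(sequences[[sid]])
    bad <- regexpr("[^ACGTN]", s)
    if (bad > 0)
      stop(sprintf("sequence '%s': illegal character at position %d", sid, bad),
           call. = FALSE)
    L <- nchar(s)
    sub <- if (L > window) substr(s, L - window + 1L, L) else s
    Ls <- nchar(sub)
    subj <- Biostrings::DNAString(sub)
    for (mn in names(motifs)) {
      mo <- toupper(motifs[[mn]])
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") mo else reverse_complement(mo)
        hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                         fixed = TRUE)
        st <- Biostrings::start(hits)
        if (length(st))
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = sid, motif = mn, strand = strand,
            offset = st - Ls - 1L,
            match = pat,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(), motif = character(),
                      strand = character(), offset = integer(),
                      match = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  ord <- order(match(out$seq_id, names(sequences)), out$offset,
               match(out$strand, c("+", "-")), out$motif)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a promoter FASTA file
#'
#' Reads a multi-record FASTA of upstream sequences (3' ends adjacent to
#' ATG) and runs [scan_motifs()].
#'
#' @param fasta Path to a FASTA file.
#' @inheritParams scan_motifs
#' @return As [scan_motifs()].
#' @export
scan_promoter_fasta <- function(fasta, motifs = pif3_motifs(), window = 3000) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) {
    warning("empty FASTA: no sequences to scan")
    return(scan_motifs(c(placeholder = "A"), motifs, window)[0, ])
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  scan_motifs(seqs, motifs, window)
}

#' Positional histogram of motif hits
#'
#' Bins hit offsets over `[-window, 0)` into bins of width `bin_bp`
#' (which must divide `window`). The total count equals the number of
#' hits.
#'
#' @param hits Data.frame from [scan_motifs()] (possibly filtered).
#' @param bin_bp Bin width in bp (default 100).
#' @param window Window in bp (default 3000).
#' @return Data.frame with columns `bin_start`, `bin_end` (ATG-relative,
#'   `bin_start < bin_end <= 0`) and `count`.
#' @export
position_histogram <- function(hits, bin_bp = 100, window = 3000) {
  if (!is.numeric(bin_bp) || bin_bp <= 0)
    stop("`bin_bp` must be positive", call. = FALSE)
  if (window %% bin_bp != 0)
    stop("`bin_bp` must divide `window`", call. = FALSE)
  nb <- window / bin_bp
  starts <- seq(-window, -bin_bp, by = bin_bp)
  counts <- integer(nb)
  if (nrow(hits)) {
    if (any(hits$offset < -window | hits$offset > -1))
      stop("hit offsets outside [-window, -1]", call. = FALSE)
    idx <- floor((hits$offset + window) / bin_bp) + 1L
    tab <- table(factor(idx, levels = seq_len(nb)))
    counts <- as.integer(tab)
  }
  data.frame(bin_start = starts, bin_end = starts + bin_bp, count = counts)
}

#' Local maxima (clusters) of a positional histogram
#'
#' Identifies distinct positional clusters as local maxima of the binned
#' histogram: a candidate is a non-empty bin not exceeded by its
#' neighbours (plateaus collapse to their first bin), and two candidates
#' count as distinct clusters only when separated by at least two bins
#' that are empty or strictly lower than both; otherwise they are merged
#' (the higher is kept). This is the operational version of "motifs
#' clustered to distinct regions" - a descriptive summary, not a
#' statistical test.
#'
#' @param histogram Data.frame from [position_histogram()].
#' @return The rows of `histogram` that are cluster maxima.
#' @export
histogram_modes <- function(histogram) {
  cnt <- histogram$count
  nb <- length(cnt)
  if (nb == 0L || all(cnt == 0)) return(histogram[0, ])
  left <- c(-Inf, cnt[-nb]); right <- c(cnt[-1], -Inf)
  cand <- which(cnt > 0 & cnt >= left & cnt >= right)
  # collapse plateaus: keep first bin of each run of equal-count candidates
  if (length(cand) > 1L)
    cand <- cand[c(TRUE, !(diff(cand) == 1L &
                           cnt[cand[-1]] == cnt[cand[-length(cand)]]))]
  keep <- cand[1]
  for (j in cand[-1]) {
    i <- keep[length(keep)]
    between <- if (j - i > 1L) cnt[(i + 1L):(j - 1L)] else integer(0)
    sep <- sum(between == 0 | between < min(cnt[i], cnt[j]))
    if (sep >= 2L) keep <- c(keep, j)
    else if (cnt[j] > cnt[i]) keep[length(keep)] <- j
  }
  histogram[keep, , drop = FALSE]
}

#' Gene-by-motif presence table
#'
#' Summarises a scan into presence/absence of each motif per sequence,
#' plus per-sequence hit counts. Row order follows `seq_ids` (or the order
#' of first appearance in `hits`).
#'
#' @param hits Data.frame from [scan_motifs()].
#' @param seq_ids Optional character vector of all sequence ids (so that
#'   sequences without hits appear as all-FALSE rows).
#' @param motifs Optional character vector of motif names (defaults to
#'   those present in `hits`).
#' @return Data.frame with column `seq_id`, one logical column per motif,
#'   and `n_hits`.
#' @export
presence_table <- function(hits, seq_ids = NULL, motifs = NULL) {
  if (is.null(seq_ids)) seq_ids <- unique(hits$seq_id)
  if (is.null(motifs)) motifs <- sort(unique(hits$motif))
  if (length(seq_ids) == 0L) {
    out <- data.frame(seq_id = character(), stringsAsFactors = FALSE)
    for (m in motifs) out[[m]] <- logical(0)
    out$n_hits <- integer(0)
    return(out)
  }
  out <- data.frame(seq_id = seq_ids, stringsAsFactors = FALSE)
  for (m in motifs)
    out[[m]] <- vapply(seq_ids, function(s)
      any(hits$seq_id == s & hits$motif == m), logical(1), USE.NAMES = FALSE)
  out$n_hits <- vapply(seq_ids, function(s) sum(hits$seq_id == s),
                       integer(1), USE.NAMES = FALSE)
  out
}
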