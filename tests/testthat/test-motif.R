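test_that("reverse complement is the Watson-Crick involution over ACGTN", {
  expect_equal(reverse_complement("CACATG"), "CATGTG")
  expect_equal(reverse_complement("CACGTG"), "CACGTG")  # palindromic G-box
  expect_equal(reverse_complement("ACGTN"), "NACGT")
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE),
               collapse = "")
    expect_equal(reverse_complement(reverse_complement(s)), s)
  }
  expect_error(reverse_complement("ACGXT"), "position 4")
})

test_that("palindromic plants give coincident hits on both strands", {
  s <- paste0(strrep("T", 2494), "CACGTG", strrep("T", 500))
  h <- scan_motifs(c(g1 = s))
  expect_equal(nrow(h), 2)
  expect_equal(h$offset, c(-506, -506))
  expect_equal(h$strand, c("+", "-"))
  expect_equal(unique(h$match), "CACGTG")
})

test_that("PBE-box hits report the strand carrying the motif", {
  s <- strrep("A", 3000)
  substr(s, 3000 - 1200 + 1, 3000 - 1200 + 6) <- "CACATG"  # + strand
  substr(s, 3000 - 300 + 1, 3000 - 300 + 6) <- "CATGTG"    # - strand
  h <- scan_motifs(c(g = s))
  pbe <- h[h$motif == "PBE-box", ]
  expect_equal(pbe$offset, c(-1200, -300))
  expect_equal(pbe$strand, c("+", "-"))
  expect_equal(pbe$match, c("CACATG", "CATGTG"))
})

test_that("scanning handles empty, overlapping and N-containing cases", {
  expect_equal(nrow(scan_motifs(c(g = strrep("A", 3000)))), 0)
  # overlapping occurrences are all reported
  h <- scan_motifs(c(g = "AAAA"), motifs = c(m = "AA"), window = 10)
  expect_equal(sum(h$strand == "+"), 3)
  # N breaks an exact match
  expect_equal(nrow(scan_motifs(c(g = paste0("CACNTG", strrep("A", 20))))), 0)
  # lower case input is scanned case-insensitively
  expect_equal(nrow(scan_motifs(c(g = paste0(strrep("a", 20), "cacgtg")))), 2)
  expect_error(scan_motifs(c(g = "ACGT"), motifs = ""), "motif")
  expect_error(scan_motifs(c(g = "ACGQ")), "illegal character")
})

test_that("sequences longer than the window are scanned over their 3'-most bases", {
  # motif 3500 bp upstream lies outside the 3-kb window
  far <- paste0("CACATG", strrep("A", 3494))
  expect_equal(nrow(scan_motifs(c(g = far))), 0)
  # short sequences are scanned in full
  near <- paste0("CACATG", strrep("A", 100))
  h <- scan_motifs(c(g = near))
  expect_equal(h$offset[h$strand == "+"], -106)
})

test_that("scanner agrees with a naive substring oracle on random sequences", {
  set.seed(202)
  for (i in 1:100) {
    # short random sequences at high GC make motif hits frequent
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE,
                      prob = c(0.2, 0.3, 0.3, 0.2)), collapse = "")
    got <- scan_motifs(c(x = s))[, c("motif", "strand", "offset")]
    want <- naive_scan(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want[, c("motif", "strand", "offset")])
  }
})

test_that("positional histogram conserves counts and validates its bins", {
  hits <- data.frame(seq_id = "g", motif = "PBE-box", strand = "+",
                     offset = rep(-150, 10), match = "CACATG")
  h <- position_histogram(hits, bin_bp = 100, window = 3000)
  expect_equal(sum(h$count), 10)
  expect_equal(h$count[h$bin_start == -200], 10)
  expect_equal(sum(h$count > 0), 1)
  empty <- position_histogram(hits[0, ], bin_bp = 100)
  expect_equal(sum(empty$count), 0)
  expect_equal(nrow(empty), 30)
  expect_error(position_histogram(hits, bin_bp = 0), "positive")
  expect_error(position_histogram(hits, bin_bp = 7), "divide")
})

test_that("three separated planted blocks yield exactly three histogram maxima", {
  offs <- c(rep(-2900, 5), rep(-2850, 2), rep(-1500, 6), rep(-250, 3),
            rep(-150, 4))
  hits <- data.frame(seq_id = "g", motif = "PBE-box", strand = "+",
                     offset = offs, match = "CACATG")
  h <- position_histogram(hits)
  m <- histogram_modes(h)
  expect_equal(nrow(m), 3)
  expect_equal(sum(h$count), length(offs))
})

test_that("presence table marks genes with and without hits", {
  hits <- scan_motifs(c(
    g1 = paste0(strrep("A", 100), "CACGTG", strrep("A", 100)),
    g2 = strrep("A", 200)))
  tab <- presence_table(hits, seq_ids = c("g1", "g2"),
                        motifs = c("G-box", "PBE-box"))
  expect_equal(tab$`G-box`, c(TRUE, FALSE))
  expect_equal(tab$`PBE-box`, c(FALSE, FALSE))
  expect_equal(tab$n_hits, c(2L, 0L))
  empty <- presence_table(hits[0, ], seq_ids = character())
  expect_equal(nrow(empty), 0)
})
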