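test_that("MEME minimal parsing handles background, defaults and errors", {
  txt <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "MOTIF toy", "letter-probability matrix: alength= 4 w= 2",
           " 1.0 0.0 0.0 0.0", " 0.0 1.0 0.0 0.0")
  x <- load_meme_motif(paste(txt, collapse = "\n"))
  expect_equal(pwm_consensus(x), "AC")
  expect_equal(unname(x$background), rep(0.25, 4))  # uniform default

  with_bg <- c("MEME version 4", "", "Background letter frequencies",
               "A 0.3 C 0.2 G 0.2 T 0.3", "", "MOTIF toy",
               "letter-probability matrix: alength= 4 w= 1",
               " 0.25 0.25 0.25 0.25")
  y <- load_meme_motif(paste(with_bg, collapse = "\n"))
  expect_equal(unname(y$background), c(0.3, 0.2, 0.2, 0.3))

  bad <- sub(" 0.0 1.0 0.0 0.0", " 0.0 0.9 0.0 0.0", paste(txt, collapse = "\n"))
  expect_error(load_meme_motif(bad), "line 8")
})

test_that("MEME write/read round-trip preserves the matrix to 1e-12", {
  x <- random_pwm(12, seed = 44)
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme_motif(x, path)
  y <- load_meme_motif(path)
  expect_equal(y$matrix, x$matrix, tolerance = 1e-12)
  expect_equal(y$width, 12L)
})

test_that("log-odds scoring matches the direct formula and its bounds", {
  x <- random_pwm(6, seed = 3)
  sm <- pwm_score_matrix(x)
  # consensus achieves the column-wise maximum
  expect_equal(log_odds_score(x, pwm_consensus(x)), sum(apply(sm, 1, max)))
  set.seed(8)
  for (i in 1:20) {
    b <- sample(1:4, 6, replace = TRUE)
    word <- paste(c("A", "C", "G", "T")[b], collapse = "")
    manual <- sum(log2((x$matrix[cbind(1:6, b)] +
                          x$pseudocount * x$background[b]) /
                         ((1 + x$pseudocount) * x$background[b])))
    expect_equal(log_odds_score(x, word), manual, tolerance = 1e-12)
  }
  # zero-information column scores 0 bits
  flat <- pwm(matrix(0.25, nrow = 1, ncol = 4))
  expect_equal(log_odds_score(flat, "A"), 0)
  # ambiguous base never scores
  expect_equal(log_odds_score(x, "ACGTNN"), -Inf)
})

test_that("exact score p-values agree with 4^w enumeration for small widths", {
  set.seed(19)
  for (i in 1:100) {
    w <- sample(2:6, 1)
    x <- random_pwm(w)
    score <- log_odds_score(x, paste(sample(c("A", "C", "G", "T"), w,
                                            replace = TRUE), collapse = ""))
    expect_equal(score_pvalue(x, score), oracle_pwm_pvalue(x, score),
                 tolerance = 1e-6)
  }
})

test_that("score p-value is monotone with boundary behaviour at the extremes", {
  x <- random_pwm(5, seed = 55)
  sm <- pwm_score_matrix(x)
  smin <- sum(apply(sm, 1, min)); smax <- sum(apply(sm, 1, max))
  expect_equal(score_pvalue(x, smin - 1), 1)
  expect_equal(score_pvalue(x, smax + 1), 0)
  grid <- seq(smin, smax, length.out = 25)
  ps <- vapply(grid, function(s) score_pvalue(x, s), 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("scanning recovers planted consensus sites and strand symmetry", {
  x <- cre_like_pwm()
  genome <- random_genome(10000L, seed = 5)
  pl <- plant_motif_sites(genome, x, data.frame(chrom = "chr1", pos = 100L))
  hits <- scan_sequence(pl$genome[["chr1"]], x, 1e-4, seqname = "chr1")
  expect_true(100 %in% hits$offset)
  expect_true(all(hits$p_value <= 1e-4))
  expect_true(all(hits$offset + 12 <= 10000))

  # reverse complement of the sequence gives mirror-image hits
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pl$genome[["chr1"]])))
  hits_rc <- scan_sequence(rc, x, 1e-4)
  expect_equal(nrow(hits_rc), nrow(hits))
  expect_setequal(10000 - 12 - hits$offset, hits_rc$offset)

  # the consensus here is a perfect palindrome: coincident both-strand hits
  cons_hits <- hits[hits$offset == 100, ]
  expect_equal(nrow(cons_hits), 2L)
  expect_setequal(cons_hits$strand, c("+", "-"))
  expect_true(all(cons_hits$palindromic))
})

test_that("degenerate scan thresholds behave as documented", {
  x <- random_pwm(4, seed = 10)
  seq <- "ACGTACGTAC"
  all_hits <- scan_sequence(seq, x, p_threshold = 1)
  expect_equal(nrow(all_hits), 2 * (nchar(seq) - 4 + 1))
  expect_warning(scan_sequence("ACG", x, 1e-4), "shorter than")
})

test_that("peak-level motif counting requires a hit fully inside the peak", {
  x <- cre_like_pwm()
  genome <- random_genome(20000L, seed = 23)
  pl <- plant_motif_sites(genome, x,
                          data.frame(chrom = "chr1", pos = c(1000L, 5000L)))
  peaks <- data.frame(chrom = "chr1",
                      start = c(900L, 4900L, 8000L, 12000L),
                      end = c(1200L, 5100L, 8300L, 12300L))
  res <- count_peaks_with_motif(peaks, pl$genome, x, 1e-4)
  expect_equal(res$n_total, 4L)
  expect_equal(res$n_with_motif, 2L)
  expect_gt(nrow(res$hits[[1]]), 0)
  expect_equal(nrow(res$hits[[3]]), 0)
  # a hit straddling the peak edge does not count
  edge <- data.frame(chrom = "chr1", start = 1005L, end = 1100L)
  expect_equal(count_peaks_with_motif(edge, pl$genome, x, 1e-4)$n_with_motif, 0L)
  # degenerate inputs
  expect_equal(count_peaks_with_motif(peaks[0, ], pl$genome, x, 1e-4),
               list(n_with_motif = 0L, n_total = 0L, hits = list()))
  expect_equal(count_peaks_with_motif(peaks, pl$genome, x, 0)$n_with_motif, 0L)
  expect_error(count_peaks_with_motif(
    data.frame(chrom = "chr1", start = 19990L, end = 20100L),
    pl$genome, x, 1e-4), "outside genome")
})

test_that("reporter element construction and validation follow the 4 x 22 design", {
  x <- cre_like_pwm()
  seg <- function(core = "TGACGTCA") paste0("CTAGCTA", core, "TTCACCG")
  expect_equal(nchar(seg()), 22L)
  atre <- build_atre(rep(seg(), 4))
  expect_equal(nchar(atre), 88L)
  v <- validate_atre(atre, x)
  expect_true(all(v$core_match))
  expect_true(all(v$pwm_hit))

  # mutant: 3 substitutions inside the core abolish the core match
  matre <- build_atre(c(rep(seg(), 3), seg(core = "TGTACGCA")))
  vm <- validate_atre(matre, x)
  expect_equal(vm$core_match, c(TRUE, TRUE, TRUE, FALSE))

  # a reverse-complement core still matches (palindrome-insensitive rule)
  rc_core <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TGACGTCA")))
  expect_true(validate_atre(build_atre(rep(seg(rc_core), 4)), x)$core_match[1])

  expect_error(build_atre(rep(seg(), 3)), "exactly 4")
  expect_error(build_atre(c(rep(seg(), 3), "ACGT")), "22")
  expect_error(validate_atre("ACGT", x), "88 nt")
})
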