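DNA <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' A PWM is a `width x 4` column-stochastic description of a binding motif:
#' `matrix[i, b]` is the probability of base `b` (order A, C, G, T) at motif
#' position `i`. Scoring uses FIMO-style log-odds against a background model
#' with a pseudocount proportional to the background.
#'
#' @param matrix numeric `width x 4` matrix of per-position probabilities
#'   (rows sum to 1).
#' @param background length-4 background probabilities (sums to 1); default
#'   uniform.
#' @param pseudocount pseudocount fraction added as `pseudocount * bg`.
#' @param name motif name.
#' @return A list of class `pwm`.
#' @export
pwm <- function(matrix, background = rep(0.25, 4), pseudocount = 0.01,
                name = "motif") {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L) stop("pwm: matrix must have 4 columns (A,C,G,T)")
  if (nrow(matrix) < 1L) stop("pwm: width must be >= 1")
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > 1e-3))
    stop("pwm: row ", which(abs(rs - 1) > 1e-3)[1L],
         " does not sum to 1 (got ", rs[which(abs(rs - 1) > 1e-3)[1L]], ")")
  matrix <- matrix / rs
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6 ||
      any(background <= 0))
    stop("pwm: background must be 4 positive probabilities summing to 1")
  colnames(matrix) <- DNA
  structure(list(width = nrow(matrix), matrix = matrix,
                 background = stats::setNames(as.numeric(background), DNA),
                 pseudocount = pseudocount, name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm '", x$name, "' width ", x$width, ", consensus ",
      pwm_consensus(x), "\n", sep = "")
  invisible(x)
}

#' @describeIn pwm Consensus sequence (per-position argmax base).
#' @param x a `pwm`.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA[apply(x$matrix, 1L, which.max)], collapse = "")
}

#' @describeIn pwm The PWM of the reverse-complement motif.
#' @export
pwm_reverse_complement <- function(x) {
  stopifnot(inherits(x, "pwm"))
  m <- x$matrix[rev(seq_len(x$width)), rev(seq_len(4L)), drop = FALSE]
  pwm(m, background = x$background[c(4L, 3L, 2L, 1L)],
      pseudocount = x$pseudocount, name = paste0(x$name, "_rc"))
}

#' Log-odds score matrix of a PWM, in bits
#'
#' `S[i, b] = log2((p[i, b] + pc * bg[b]) / ((1 + pc) * bg[b]))`.
#'
#' @param x a `pwm`.
#' @return `width x 4` numeric matrix.
#' @export
pwm_score_matrix <- function(x) {
  stopifnot(inherits(x, "pwm"))
  bg <- matrix(x$background, nrow = x$width, ncol = 4L, byrow = TRUE)
  log2((x$matrix + x$pseudocount * bg) / ((1 + x$pseudocount) * bg))
}

#' Log-odds score of one word under a PWM
#'
#' @param x a `pwm`.
#' @param word character string of length `x$width` over A/C/G/T; any other
#'   base scores `-Inf`.
#' @return score in bits.
#' @export
log_odds_score <- function(x, word) {
  stopifnot(inherits(x, "pwm"))
  b <- match(strsplit(toupper(word), "")[[1L]], DNA)
  if (length(b) != x$width)
    stop("log_odds_score: word length ", length(b), " != PWM width ", x$width)
  if (anyNA(b)) return(-Inf)
  sm <- pwm_score_matrix(x)
  sum(sm[cbind(seq_len(x$width), b)])
}

# Exact distribution of the log-odds score of a random background word,
# on an integer lattice of `step` bits. Returns the lattice scores (bits)
# and upper-tail probabilities P(S >= s).
pwm_score_distribution <- function(x, step = 1e-3) {
  sm <- round(pwm_score_matrix(x) / step)
  probs <- x$background
  acc <- 1; acc_lo <- 0L  # acc[k] = P(partial sum == acc_lo + k - 1)
  for (i in seq_len(x$width)) {
    s <- sm[i, ]
    new_lo <- acc_lo + min(s)
    new_hi <- acc_lo + length(acc) - 1L + max(s)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- acc_lo + s[b] - new_lo
      idx <- seq_along(acc) + sh
      new[idx] <- new[idx] + acc * probs[b]
    }
    acc <- new; acc_lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(acc)))
  list(scores = (seq_along(acc) - 1L + acc_lo) * step, tail = tail_p,
       step = step, lattice_lo = acc_lo)
}

#' Exact p-value of a PWM score under the background model
#'
#' `P(score(W) >= score)` for a word `W` drawn i.i.d. from the PWM's
#' background. For motifs up to `exact_max_width` positions the dynamic
#' program carries the exact support of the score distribution, so the
#' p-value is exact to floating-point precision; wider motifs use a
#' discretized score lattice (default step 1e-3 bits, far below any decision
#' boundary at the usual scan thresholds).
#'
#' @param x a `pwm`.
#' @param score score in bits.
#' @param step lattice discretization in bits (wide motifs only).
#' @param exact_max_width largest width for which the exact-support dynamic
#'   program is used.
#' @return p-value in `[0, 1]`.
#' @export
score_pvalue <- function(x, score, step = 1e-3, exact_max_width = 10L) {
  stopifnot(inherits(x, "pwm"), is.finite(score))
  if (x$width <= exact_max_width) {
    sm <- pwm_score_matrix(x)
    sums <- sm[1L, ]
    probs <- x$background
    for (i in seq_len(x$width)[-1L]) {
      sums <- as.vector(outer(sums, sm[i, ], `+`))
      probs <- as.vector(outer(probs, x$background, `*`))
    }
    return(sum(probs[sums >= score - 1e-9]))
  }
  d <- pwm_score_distribution(x, step)
  k <- round(score / step) - d$lattice_lo + 1L
  if (k <= 1L) return(1)
  if (k > length(d$tail)) return(0)
  d$tail[k]
}

# Smallest score (bits, on the lattice) whose tail p-value is <= p_threshold;
# +Inf if unattainable.
pwm_score_threshold <- function(x, p_threshold, step = 1e-3) {
  d <- pwm_score_distribution(x, step)
  ok <- d$tail <= p_threshold
  if (!any(ok)) return(Inf)
  d$scores[which(ok)[1L]]
}

seq_to_codes <- function(seq) {
  if (inherits(seq, "DNAString") || inherits(seq, "XString"))
    seq <- as.character(seq)
  match(strsplit(toupper(seq), "")[[1L]], DNA)
}

scan_codes <- function(codes, sm_lattice) {
  w <- nrow(sm_lattice)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric())
  total <- numeric(n)
  na_hit <- logical(n)
  for (i in seq_len(w)) {
    b <- codes[i:(i + n - 1L)]
    bad <- is.na(b)
    na_hit <- na_hit | bad
    s <- sm_lattice[i, ]
    v <- s[ifelse(bad, 1L, b)]
    total <- total + v
  }
  total[na_hit] <- -Inf
  total
}

#' Scan a sequence for PWM matches at a p-value threshold
#'
#' Reports every offset whose forward- or reverse-complement-strand word has
#' an exact background p-value at or below the threshold. Matches whose word
#' equals its own reverse complement are reported on both strands and flagged
#' `palindromic`.
#'
#' @param seq a character string or `Biostrings::DNAString`.
#' @param x a `pwm`.
#' @param p_threshold p-value threshold in (0, 1].
#' @param both_strands scan the minus strand too.
#' @param seqname name recorded for the sequence.
#' @param step score-lattice step in bits.
#' @return data.frame with `seqname`, `offset` (0-based leftmost base of the
#'   match on the forward strand), `strand`, `score` (bits), `p_value`,
#'   `palindromic`.
#' @export
scan_sequence <- function(seq, x, p_threshold = 1e-4, both_strands = TRUE,
                          seqname = "seq", step = 1e-3) {
  stopifnot(inherits(x, "pwm"), p_threshold > 0, p_threshold <= 1)
  codes <- seq_to_codes(seq)
  empty <- data.frame(seqname = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      p_value = numeric(), palindromic = logical())
  if (length(codes) < x$width) {
    warning("scan_sequence: sequence '", seqname, "' shorter than PWM width")
    return(empty)
  }
  d <- pwm_score_distribution(x, step)
  sm <- round(pwm_score_matrix(x) / step)
  one_strand <- function(scorer, strand) {
    lattice <- scan_codes(codes, scorer)
    scores <- lattice * step
    k <- lattice - d$lattice_lo + 1L
    p <- ifelse(k <= 0L, 1,
                ifelse(k > length(d$tail), 0, d$tail[pmax(k, 1L)]))
    p[!is.finite(scores)] <- 1
    hit <- p <= p_threshold
    if (!any(hit)) return(empty)
    data.frame(seqname = seqname, offset = which(hit) - 1L, strand = strand,
               score = scores[hit], p_value = p[hit], palindromic = FALSE)
  }
  res <- one_strand(sm, "+")
  if (both_strands) {
    sm_rc <- round(pwm_score_matrix(pwm_reverse_complement(x)) / step)
    res <- rbind(res, one_strand(sm_rc, "-"))
  }
  if (nrow(res)) {
    res$palindromic <- vapply(res$offset, function(o) {
      word <- DNA[codes[(o + 1L):(o + x$width)]]
      identical(word, rev(chartr_complement(word)))
    }, TRUE)
    res <- res[order(res$offset, res$strand), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

chartr_complement <- function(bases)
  unname(c(A = "T", C = "G", G = "C", T = "A")[bases])

#' Scan every sequence of a genome for PWM matches
#'
#' @param genome named character vector or `Biostrings::DNAStringSet`.
#' @inheritParams scan_sequence
#' @return row-bound [scan_sequence()] results with `seqname` per chromosome.
#' @export
scan_genome <- function(genome, x, p_threshold = 1e-4, both_strands = TRUE) {
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  out <- lapply(names(genome), function(chrom)
    scan_sequence(genome[[chrom]], x, p_threshold, both_strands,
                  seqname = chrom))
  do.call(rbind, out)
}

#' Count peaks containing at least one motif hit
#'
#' A peak counts as motif-containing iff at least one scan hit lies fully
#' inside the peak interval.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genome named character vector or `DNAStringSet`.
#' @param x a `pwm`.
#' @param p_threshold scan p-value threshold.
#' @return list with `n_with_motif`, `n_total`, and `hits`, a list (one
#'   element per peak) of per-peak hit data.frames.
#' @export
count_peaks_with_motif <- function(peaks, genome, x, p_threshold = 1e-4) {
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  if (!nrow(peaks))
    return(list(n_with_motif = 0L, n_total = 0L, hits = list()))
  lens <- vapply(genome, nchar, 1L)
  if (any(!peaks$chrom %in% names(genome)) ||
      any(peaks$start < 0) || any(peaks$end > lens[peaks$chrom]))
    stop("count_peaks_with_motif: peak outside genome bounds")
  if (p_threshold <= 0)
    return(list(n_with_motif = 0L, n_total = nrow(peaks), hits = list()))
  all_hits <- scan_genome(genome, x, p_threshold)
  hits <- lapply(seq_len(nrow(peaks)), function(i) {
    h <- all_hits[all_hits$seqname == peaks$chrom[i] &
                    all_hits$offset >= peaks$start[i] &
                    all_hits$offset + x$width <= peaks$end[i], , drop = FALSE]
    rownames(h) <- NULL
    h
  })
  n_with <- sum(vapply(hits, nrow, 1L) > 0L)
  list(n_with_motif = n_with, n_total = nrow(peaks), hits = hits)
}

#' Build a concatenated reporter element from motif-bearing segments
#'
#' Concatenates four 22-bp genomic segments, each expected to carry one
#' binding site, into the 88-bp synthetic response element used for reporter
#' constructs.
#'
#' @param site_segments character vector of exactly 4 sequences, 22 nt each.
#' @return The 88-nt reporter sequence.
#' @export
build_atre <- function(site_segments) {
  if (length(site_segments) != 4L)
    stop("build_atre: need exactly 4 segments, got ", length(site_segments))
  n <- nchar(site_segments)
  if (any(n != 22L))
    stop("build_atre: segment ", which(n != 22L)[1L], " is ",
         n[n != 22L][1L], " nt, expected 22")
  paste(toupper(site_segments), collapse = "")
}

#' Validate a reporter element against the binding-site core and PWM
#'
#' Splits the 88-nt reporter back into its four 22-nt segments and reports,
#' per segment, whether the 8-mer recognition core (or its reverse
#' complement) occurs and whether a PWM hit at the p-value threshold exists.
#' Three or more substitutions inside the core (the mutant-reporter design)
#' abolish the core match.
#'
#' @param seq an 88-nt reporter sequence.
#' @param x a `pwm`.
#' @param core recognition-core 8-mer; default the CRE-like `TGACGTCA`.
#' @param p_threshold PWM-hit p-value threshold per segment.
#' @return data.frame with one row per segment: `segment`, `core_match`,
#'   `pwm_hit`.
#' @export
validate_atre <- function(seq, x, core = "TGACGTCA", p_threshold = 1e-4) {
  seq <- toupper(seq)
  if (nchar(seq) != 88L)
    stop("validate_atre: reporter must be 88 nt (4 x 22), got ", nchar(seq))
  core_rc <- paste(rev(chartr_complement(strsplit(core, "")[[1L]])),
                   collapse = "")
  segs <- substring(seq, seq(1L, 67L, by = 22L), seq(22L, 88L, by = 22L))
  core_match <- grepl(core, segs, fixed = TRUE) |
    grepl(core_rc, segs, fixed = TRUE)
  pwm_hit <- vapply(segs, function(s)
    nrow(scan_sequence(s, x, p_threshold)) > 0L, TRUE, USE.NAMES = FALSE)
  data.frame(segment = 1:4, core_match = core_match, pwm_hit = pwm_hit)
}
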