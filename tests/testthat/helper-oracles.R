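# Independent oracles and fixture builders shared across tests.

# Brute-force per-base interval stabbing: coverage of extended fragments.
oracle_coverage <- function(alignments, chrom_len, extension_bp) {
  cov <- numeric(chrom_len)
  for (i in seq_len(nrow(alignments))) {
    s <- if (alignments$strand[i] == "+") alignments$start[i] else
      alignments$end[i] - extension_bp
    e <- if (alignments$strand[i] == "+") alignments$start[i] + extension_bp else
      alignments$end[i]
    s <- max(s, 0L); e <- min(e, chrom_len)
    for (b in seq(s + 1L, e)) cov[b] <- cov[b] + 1
  }
  cov
}

# Full C(m+n, m) enumeration of the two-sample two-sided KS null: every
# assignment of the pooled values to the two groups, p = P(D >= observed).
oracle_ks_enum <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  pts <- sort(unique(pooled))
  d_of <- function(a, b) {
    fa <- vapply(pts, function(t) mean(a <= t), 0)
    fb <- vapply(pts, function(t) mean(b <= t), 0)
    max(abs(fa - fb))
  }
  D_obs <- d_of(x, y)
  splits <- utils::combn(m + n, m)
  ds <- apply(splits, 2L, function(idx) d_of(pooled[idx], pooled[-idx]))
  list(D = D_obs, p = mean(ds >= D_obs - 1e-12))
}

# Reference BH step-up: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Hypergeometric upper-tail by PMF summation.
oracle_hyper_tail <- function(k, size_a, size_b, universe) {
  kk <- k:min(size_a, size_b)
  sum(choose(size_a, kk) * choose(universe - size_a, size_b - kk)) /
    choose(universe, size_b)
}

# Brute-force PWM score p-value: enumerate all 4^width words.
oracle_pwm_pvalue <- function(x, score) {
  w <- x$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sm <- pwm_score_matrix(x)
  scores <- rowSums(matrix(sm[cbind(rep(seq_len(w), each = nrow(words)),
                                    as.vector(words))],
                           nrow = nrow(words)))
  probs <- apply(words, 1L, function(b) prod(x$background[b]))
  sum(probs[scores >= score - 1e-12])
}

random_pwm <- function(width, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rgamma(width * 4, 1), nrow = width)
  pwm(m / rowSums(m))
}

random_alignments <- function(n, chrom_len, read_len = 50L, chrom = "chr1",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(chrom_len - read_len, n, replace = TRUE) - 1L
  data.frame(chrom = chrom, start = start, end = start + read_len,
             strand = sample(c("+", "-"), n, replace = TRUE))
}

# A raw profile wrapped directly from a value vector (bypassing reads), used
# to test the later pipeline states in isolation.
profile_from_values <- function(values, state = "unit_scaled",
                                total_reads = 100L) {
  structure(list(values = values, state = state, sample_label = "fix",
                 total_reads = total_reads),
            class = "coverage_profile")
}

disc_from_values <- function(values, grid, n_rep = 1L) {
  structure(list(grid = grid, values = values,
                 n_replicates_combined = n_rep),
            class = "discretized_profile")
}

# Width-12 high-information PWM whose consensus carries the CRE-like core.
cre_like_pwm <- function(p_major = 0.97) {
  cons <- c("A", "A", "T", "G", "A", "C", "G", "T", "C", "A", "T", "T")
  m <- matrix((1 - p_major) / 3, nrow = 12, ncol = 4)
  for (i in seq_len(12)) m[i, match(cons[i], c("A", "C", "G", "T"))] <- p_major
  pwm(m, name = "cre_like")
}

random_genome <- function(len, seed, chrom = "chr1") {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), chrom)
}

run_sim_pipeline <- function(seed, spikes = NULL, reads = 100000L,
                             config = pipeline_config()) {
  conf <- sim_config(seed = seed, spike_regions = spikes,
                     reads_per_chip_replicate = reads,
                     reads_per_input = reads)
  gen <- simulate_genome(conf)
  exp <- simulate_chip_experiment(conf, gen)
  res <- call_differential_regions(
    exp$samples[paste0("case_chip_", seq_len(conf$n_chip_replicates))],
    exp$samples$case_input,
    exp$samples[paste0("control_chip_", seq_len(conf$n_chip_replicates))],
    exp$samples$control_input,
    gen$chrom_sizes, config)
  list(conf = conf, gen = gen, exp = exp, res = res)
}
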