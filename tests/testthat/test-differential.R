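grid4 <- window_grid(c(chr1 = 100L), 50L, 25L)

test_that("difference profile is the signed case-minus-control window values", {
  case <- disc_from_values(list(chr1 = c(1.0, 0.5, 0.2, 0.0)), grid4)
  ctrl <- disc_from_values(list(chr1 = c(0.0, 0.5, 0.4, 0.0)), grid4)
  d <- difference_profile(case, ctrl)
  expect_equal(d$values$chr1, c(1.0, 0.0, -0.2, 0.0))
  expect_equal(d$global_mean, mean(c(1, 0, -0.2, 0)))
  expect_equal(d$global_sd, sd(c(1, 0, -0.2, 0)))
  # self-difference is all zero with sd 0
  d0 <- difference_profile(case, case)
  expect_equal(d0$values$chr1, rep(0, 4))
  expect_equal(d0$global_sd, 0)
  # bounded by construction when inputs are unit scaled
  set.seed(4)
  a <- disc_from_values(list(chr1 = runif(4)), grid4)
  b <- disc_from_values(list(chr1 = runif(4)), grid4)
  expect_true(all(abs(difference_profile(a, b)$values$chr1) <= 1))
})

test_that("noise filter keeps only values outside the mean +/- k*SD band", {
  # 1000 zeros and a single 1.0: only the outlier survives at 4 SD
  vals <- c(rep(0, 1000), 1)
  g <- window_grid(c(chr1 = as.integer(length(vals) * 25)), 50L, 25L)
  vals <- vals[seq_len(g$n_windows)]
  case <- disc_from_values(list(chr1 = vals), g)
  ctrl <- disc_from_values(list(chr1 = numeric(length(vals))), g)
  d <- difference_profile(case, ctrl)
  kept <- filter_noise(d, 4)
  expect_equal(kept$window, which(vals == 1))
  expect_equal(kept$sign, 1L)
  expect_true(abs(1 - d$global_mean) >= 4 * d$global_sd)
  # constant profile (sd = 0) retains nothing
  expect_equal(nrow(filter_noise(difference_profile(ctrl, ctrl), 4)), 0L)
})

test_that("values exactly inside the band are removed, at/beyond it retained", {
  # construct values at mu +/- c*sigma: sub-threshold multiplier keeps nothing
  set.seed(9)
  v <- rnorm(500)
  g <- window_grid(c(chr1 = as.integer(500 * 25)), 50L, 25L)
  v <- v[seq_len(g$n_windows)]
  case <- disc_from_values(list(chr1 = (v - min(v)) / diff(range(v))), g)
  ctrl <- disc_from_values(list(chr1 = numeric(length(v))), g)
  d <- difference_profile(case, ctrl)
  kept <- filter_noise(d, 3.9)
  ora <- which(abs(d$values$chr1 - d$global_mean) >= 3.9 * d$global_sd)
  expect_equal(kept$window, ora)
  # boundary inclusion: a value at exactly k*sd from the mean is retained
  d2 <- d; d2$global_mean <- 0; d2$global_sd <- 0.25
  d2$values$chr1[1] <- 1.0
  expect_true(1L %in% filter_noise(d2, 4)$window)
})

test_that("same-sign adjacent windows merge; gaps and sign changes split", {
  g <- window_grid(c(chr1 = 1000L), 50L, 25L)
  ret <- data.frame(chrom = "chr1", window = c(1L, 2L),
                    start = c(0L, 25L), end = c(50L, 75L),
                    value = c(0.5, 0.4), sign = c(1L, 1L))
  m <- merge_regions(ret, g)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 75L))

  gap <- data.frame(chrom = "chr1", window = c(1L, 5L),
                    start = c(0L, 100L), end = c(50L, 150L),
                    value = c(0.5, 0.4), sign = c(1L, 1L))
  expect_equal(nrow(merge_regions(gap, g)), 2L)

  signs <- data.frame(chrom = "chr1", window = c(1L, 2L),
                      start = c(0L, 25L), end = c(50L, 75L),
                      value = c(0.5, -0.4), sign = c(1L, -1L))
  m2 <- merge_regions(signs, g)
  expect_equal(nrow(m2), 2L)
  expect_setequal(m2$sign, c(1L, -1L))
})

test_that("regions shorter than the window size are discarded", {
  g <- window_grid(c(chr1 = 110L), 50L, 25L)
  # trailing clipped window [100, 110) alone spans only 10 bp
  ret <- data.frame(chrom = "chr1", window = 5L, start = 100L, end = 110L,
                    value = 0.9, sign = 1L)
  expect_equal(nrow(merge_regions(ret, g)), 0L)
})

test_that("KS statistic and exact p match full enumeration for small samples", {
  expect_equal(ks_test2(c(0, 0, 0), c(1, 1, 1)),
               list(D = 1, p_value = 0.1, exact = TRUE))
  # degenerate 1 vs 1: D = 1 but p = 1
  k11 <- ks_test2(0.3, 0.7)
  expect_equal(k11$D, 1)
  expect_equal(k11$p_value, 1)
  # identical samples
  k0 <- ks_test2(c(1, 2, 3), c(1, 2, 3))
  expect_equal(k0$D, 0)
  expect_equal(k0$p_value, 1)

  # all sample splits with m + n <= 8, continuous and tied values
  set.seed(21)
  for (rep in 1:20) {
    m <- sample(1:4, 1); n <- sample(1:4, 1)
    vals <- if (rep %% 2 == 0) sample(1:4, m + n, replace = TRUE) else
      rnorm(m + n)
    x <- vals[seq_len(m)]; y <- vals[m + seq_len(n)]
    got <- ks_test2(x, y)
    ora <- oracle_ks_enum(x, y)
    expect_equal(got$D, ora$D, tolerance = 1e-12)
    expect_equal(got$p_value, ora$p, tolerance = 1e-9)
  }
})

test_that("asymptotic KS p is used above the exact-size bound and is sane", {
  set.seed(2)
  x <- rnorm(150); y <- rnorm(150)
  k <- ks_test2(x, y)
  expect_false(k$exact)
  expect_equal(k$p_value,
               suppressWarnings(stats::ks.test(x, y, exact = FALSE)$p.value),
               tolerance = 1e-6)
})

test_that("region testing pools the window values overlapping the span", {
  g <- window_grid(c(chr1 = 200L), 50L, 25L)
  case <- disc_from_values(list(chr1 = c(0.9, 0.8, 0.7, 0.1, 0.1, 0.1, 0.1, 0.1)), g)
  ctrl <- disc_from_values(list(chr1 = rep(0.1, 8)), g)
  r <- list(chrom = "chr1", start = 0L, end = 75L)  # windows 1-3 overlap
  t1 <- test_region(r, case, ctrl)
  expect_equal(t1$n_case, 3L)
  ora <- oracle_ks_enum(c(0.9, 0.8, 0.7), rep(0.1, 3))
  expect_equal(t1$ks_D, ora$D)
  expect_equal(t1$p_value, ora$p, tolerance = 1e-9)
  # per-replicate pooling triples the sample size
  t2 <- test_region(r, list(case, case, case), list(ctrl, ctrl, ctrl))
  expect_equal(t2$n_case, 9L)
})

test_that("BH q-values equal the reference step-up on random vectors", {
  expect_equal(bh_correct(0.03), 0.03)
  expect_equal(bh_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(77)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    q <- bh_correct(p)
    expect_equal(q, oracle_bh(p))
    # q preserves the order of p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("blacklisted regions are dropped unless whitelisted via a gene", {
  regions <- data.frame(chrom = "chr1", start = c(100L, 5000L),
                        end = c(400L, 5400L), name = c("peak_1", "peak_2"))
  bl <- data.frame(chrom = "chr1", start = 0L, end = 1000L)
  expect_equal(apply_blacklist(regions, bl)$name, "peak_2")
  # exemption by whitelisted gene assignment
  assoc <- data.frame(peak = "peak_1", gene_id = "atf3", relation = "body")
  kept <- apply_blacklist(regions, bl, assoc, whitelist_genes = "atf3")
  expect_setequal(kept$name, c("peak_1", "peak_2"))
  # empty blacklist is the identity
  expect_equal(apply_blacklist(regions, NULL), regions)
  expect_equal(apply_blacklist(regions, bl[0, ]), regions)
})
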