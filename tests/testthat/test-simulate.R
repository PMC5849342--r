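test_that("config validation names the offending field", {
  expect_error(sim_config(genome_length_bp = 100L), "genome_length_bp")
  expect_error(sim_config(gc_fraction = 1.2), "gc_fraction")
  expect_error(sim_config(fragment_length_bp = 40L, read_length_bp = 50L),
               "fragment_length_bp")
  expect_error(sim_config(spike_regions = data.frame(
    chrom = "chr1", start = 10L, end = 500L, fold = 0.5)), "fold")
})

test_that("genome simulation is deterministic and honours the config", {
  conf <- sim_config(seed = 7L, genome_length_bp = 10000L, n_genes = 0L)
  g1 <- simulate_genome(conf)
  g2 <- simulate_genome(conf)
  expect_identical(g1, g2)
  expect_equal(nchar(g1$genome[["chr1"]]), 10000L)
  expect_equal(nrow(g1$genes), 0L)
  expect_true(all(strsplit(g1$genome[["chr1"]], "")[[1]] %in%
                    c("A", "C", "G", "T")))
})

test_that("observed GC fraction is within 3 SD of the binomial expectation", {
  n <- 100000L
  conf <- sim_config(seed = 1L, genome_length_bp = n, gc_fraction = 0.5,
                     n_genes = 0L)
  g <- simulate_genome(conf)
  gc <- sum(strsplit(g$genome[["chr1"]], "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(n * 0.5 * 0.5)
  expect_lt(abs(gc - n * 0.5), sd3)
})

test_that("gene models are non-degenerate, stranded and within bounds", {
  conf <- sim_config(seed = 3L, n_genes = 12L, n_chromosomes = 2L)
  g <- simulate_genome(conf)
  expect_equal(nrow(g$genes), 12L)
  expect_true(all(g$genes$start < g$genes$end))
  expect_true(all(g$genes$strand %in% c("+", "-")))
  expect_true(all(g$genes$end <= g$chrom_sizes[g$genes$chrom]))
  expect_true(all(g$genes$tss == ifelse(g$genes$strand == "+",
                                        g$genes$start, g$genes$end - 1L)))
})

test_that("experiment simulation is deterministic and spike-aware", {
  spikes <- data.frame(chrom = "chr1", start = 40000L, end = 40500L, fold = 8)
  conf <- sim_config(seed = 42L, spike_regions = spikes,
                     reads_per_chip_replicate = 100000L)
  gen <- simulate_genome(conf)
  e1 <- simulate_chip_experiment(conf, gen)
  e2 <- simulate_chip_experiment(conf, gen)
  expect_identical(e1, e2)
  expect_equal(e1$truth$spiked, spikes)
  expect_length(e1$samples, 8L)

  # coverage oracle: mean case ChIP coverage inside the spike exceeds 4x the
  # genome-wide background mean (expected ratio ~ fold = 8)
  cov <- build_coverage(e1$samples$case_chip_1, gen$chrom_sizes, 200L)
  inside <- mean(cov$values$chr1[40001:40500])
  background <- mean(cov$values$chr1[-(40001:40500)])
  expect_gt(inside, 4 * background)

  # control replicates carry no spikes: ratio near 1
  covc <- build_coverage(e1$samples$control_chip_1, gen$chrom_sizes, 200L)
  ratio_c <- mean(covc$values$chr1[40001:40500]) /
    mean(covc$values$chr1[-(40001:40500)])
  expect_lt(abs(ratio_c - 1), 0.25)
})

test_that("background coverage matches the Poisson depth expectation", {
  conf <- sim_config(seed = 5L, reads_per_chip_replicate = 50000L,
                     reads_per_input = 50000L)
  gen <- simulate_genome(conf)
  e <- simulate_chip_experiment(conf, gen)
  cov <- build_coverage(e$samples$case_input, gen$chrom_sizes, 200L)
  expected <- 50000 * 200 / 100000
  # mean of ~1e5 Poisson(100) bases: allow 3 SD of the mean of the profile
  obs <- mean(cov$values$chr1)
  expect_lt(abs(obs - expected), 3 * sqrt(expected * 200 / 100000))
})

test_that("fold-1 spikes are listed in truth but indistinguishable from background", {
  spikes <- data.frame(chrom = "chr1", start = 20000L, end = 20500L, fold = 1)
  conf <- sim_config(seed = 9L, spike_regions = spikes)
  gen <- simulate_genome(conf)
  e <- simulate_chip_experiment(conf, gen)
  expect_equal(e$truth$spiked$fold, 1)
  cov <- build_coverage(e$samples$case_chip_1, gen$chrom_sizes, 200L)
  ratio <- mean(cov$values$chr1[20001:20500]) /
    mean(cov$values$chr1[-(20001:20500)])
  expect_lt(abs(ratio - 1), 0.25)
})

test_that("spike regions outside the genome are a configuration error", {
  spikes <- data.frame(chrom = "chr1", start = 99900L, end = 100500L, fold = 4)
  conf <- sim_config(seed = 2L, spike_regions = spikes)
  gen <- simulate_genome(conf)
  expect_error(simulate_chip_experiment(conf, gen), "outside genome")
})

test_that("motif planting writes the consensus and rejects collisions", {
  x <- cre_like_pwm()
  genome <- random_genome(1000L, seed = 15)
  before <- genome[["chr1"]]
  pl <- plant_motif_sites(genome, x, data.frame(chrom = "chr1", pos = 100L))
  after <- pl$genome[["chr1"]]
  expect_equal(substring(after, 101, 112), pwm_consensus(x))
  expect_equal(substring(after, 1, 100), substring(before, 1, 100))
  expect_equal(substring(after, 113), substring(before, 113))
  # empty plant list is the identity
  pl0 <- plant_motif_sites(genome, x,
                           data.frame(chrom = character(), pos = integer()))
  expect_identical(pl0$genome, genome)
  # overlapping positions are an error listing the collision
  expect_error(plant_motif_sites(genome, x,
                                 data.frame(chrom = "chr1", pos = c(100L, 105L))),
               "overlapping")
  # position past the end does not fit
  expect_error(plant_motif_sites(genome, x,
                                 data.frame(chrom = "chr1", pos = 995L)),
               "fit")
})
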