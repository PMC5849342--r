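#' Configuration for the ChIP-seq spike-in simulator
#'
#' Describes a desk-scale two-condition ChIP experiment: per condition,
#' `n_chip_replicates` ChIP replicates plus one input sample of single-end
#' reads (default 50 bp) from fragments of fixed length (default 200 bp),
#' with background fragments uniform over a small genome and, in the case
#' condition only, `spike_regions` sampled at `fold` times the background
#' density. The defaults mirror the 3-replicate + 1-input, 50 bp single-end,
#' 200 bp-fragment design the pipeline targets; sequencing depth is a free
#' parameter (default 100,000 reads per sample).
#'
#' @param seed integer random seed; fixed seed implies byte-identical output.
#' @param genome_length_bp total genome length (split evenly over
#'   chromosomes).
#' @param n_chromosomes number of chromosomes.
#' @param gc_fraction expected G+C fraction of the simulated genome.
#' @param n_genes number of non-overlapping gene models to draw.
#' @param read_length_bp,fragment_length_bp read and fragment lengths.
#' @param n_chip_replicates ChIP replicates per condition.
#' @param reads_per_chip_replicate,reads_per_input reads per sample.
#' @param spike_regions data.frame with `chrom`, `start`, `end`, `fold`
#'   (0-based half-open, `fold >= 1`), enriched in the case condition.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length_bp = 100000L,
                       n_chromosomes = 1L,
                       gc_fraction = 0.42,
                       n_genes = 6L,
                       read_length_bp = 50L,
                       fragment_length_bp = 200L,
                       n_chip_replicates = 3L,
                       reads_per_chip_replicate = 100000L,
                       reads_per_input = 100000L,
                       spike_regions = NULL) {
  if (is.null(spike_regions))
    spike_regions <- data.frame(chrom = character(), start = integer(),
                                end = integer(), fold = numeric())
  conf <- list(seed = as.integer(seed),
               genome_length_bp = as.integer(genome_length_bp),
               n_chromosomes = as.integer(n_chromosomes),
               gc_fraction = gc_fraction,
               n_genes = as.integer(n_genes),
               read_length_bp = as.integer(read_length_bp),
               fragment_length_bp = as.integer(fragment_length_bp),
               n_chip_replicates = as.integer(n_chip_replicates),
               reads_per_chip_replicate = as.integer(reads_per_chip_replicate),
               reads_per_input = as.integer(reads_per_input),
               spike_regions = spike_regions,
               conditions = c("case", "control"))
  for (nm in c("genome_length_bp", "n_chromosomes", "read_length_bp",
               "fragment_length_bp", "n_chip_replicates",
               "reads_per_chip_replicate", "reads_per_input"))
    if (is.na(conf[[nm]]) || conf[[nm]] < 1L)
      stop("sim_config: field '", nm, "' must be a positive integer")
  if (conf$n_genes < 0L) stop("sim_config: field 'n_genes' must be >= 0")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("sim_config: field 'gc_fraction' must lie in [0, 1]")
  if (conf$fragment_length_bp < conf$read_length_bp)
    stop("sim_config: field 'fragment_length_bp' must be >= read_length_bp")
  if (conf$genome_length_bp < 10L * conf$fragment_length_bp)
    stop("sim_config: field 'genome_length_bp' must be >= 10 x fragment length")
  if (nrow(spike_regions)) {
    if (any(spike_regions$fold < 1))
      stop("sim_config: spike region fold must be >= 1")
    if (any(spike_regions$start < 0 | spike_regions$end <= spike_regions$start))
      stop("sim_config: spike regions must be non-empty 0-based half-open intervals")
  }
  structure(conf, class = "sim_config")
}

sim_chrom_sizes <- function(config) {
  per <- config$genome_length_bp %/% config$n_chromosomes
  sizes <- rep(per, config$n_chromosomes)
  sizes[config$n_chromosomes] <- sizes[config$n_chromosomes] +
    config$genome_length_bp %% config$n_chromosomes
  stats::setNames(as.integer(sizes), paste0("chr", seq_len(config$n_chromosomes)))
}

# Deterministic per-sample sub-seed: samples are generated from independent
# streams in a fixed role order, so adding samples never perturbs earlier ones.
sample_seed <- function(seed, k) as.integer((seed + 7919 * k) %% .Machine$integer.max)

#' Simulate a random genome and gene models
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_fraction / 2`. Gene models
#' are non-overlapping intervals (500-2000 bp) with uniform random strand.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector), `genes` (gene-model
#'   data.frame), and `chrom_sizes`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- sim_chrom_sizes(config)
  set.seed(sample_seed(config$seed, 1L))
  p <- c(A = (1 - config$gc_fraction) / 2, C = config$gc_fraction / 2,
         G = config$gc_fraction / 2, T = (1 - config$gc_fraction) / 2)
  genome <- vapply(sizes, function(len)
    paste(sample(DNA, len, replace = TRUE, prob = p), collapse = ""), "")

  genes <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character())
  if (config$n_genes > 0L) {
    set.seed(sample_seed(config$seed, 2L))
    per_chrom <- table(sample(names(sizes), config$n_genes, replace = TRUE))
    rows <- list()
    for (chrom in names(per_chrom)) {
      len <- sizes[[chrom]]
      n <- per_chrom[[chrom]]
      # lay genes on a jittered lattice so they never overlap
      slot <- len %/% n
      g_len <- pmin(sample(500:2000, n, replace = TRUE), slot - 2L)
      offset <- vapply(slot - g_len - 1L, function(m) sample.int(m, 1L), 1L)
      start <- (seq_len(n) - 1L) * slot + offset
      rows[[chrom]] <- data.frame(
        gene_id = character(n), chrom = chrom, start = start,
        end = start + g_len,
        strand = sample(c("+", "-"), n, replace = TRUE))
    }
    genes <- do.call(rbind, rows)
    genes <- genes[order(genes$chrom, genes$start), ]
    genes$gene_id <- sprintf("gene_%03d", seq_len(nrow(genes)))
    rownames(genes) <- NULL
    genes <- gene_models(genes)
  }
  list(genome = genome, genes = genes, chrom_sizes = sizes)
}

sample_fragments <- function(n_reads, sizes, spikes, read_len, frag_len) {
  chrom_p <- sizes / sum(sizes)
  n_per <- as.integer(stats::rmultinom(1L, n_reads, chrom_p))
  rows <- vector("list", length(sizes))
  for (ci in seq_along(sizes)) {
    chrom <- names(sizes)[ci]
    len <- sizes[[ci]]
    n <- n_per[ci]
    if (n == 0L) next
    sp <- spikes[spikes$chrom == chrom, , drop = FALSE]
    if (nrow(sp)) {
      w <- rep(1, len)
      for (j in seq_len(nrow(sp)))
        w[(sp$start[j] + 1L):sp$end[j]] <- sp$fold[j]
      frag_start <- sample.int(len, n, replace = TRUE, prob = w) - 1L
    } else {
      frag_start <- sample.int(len, n, replace = TRUE) - 1L
    }
    frag_end <- pmin(frag_start + frag_len, len)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    read_start <- ifelse(strand == "+", frag_start,
                         pmax(frag_end - read_len, frag_start))
    read_end <- ifelse(strand == "+", pmin(frag_start + read_len, frag_end),
                       frag_end)
    rows[[ci]] <- data.frame(chrom = chrom, start = read_start,
                             end = read_end, strand = strand)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character())
  rownames(out) <- NULL
  out
}

#' Simulate a two-condition ChIP experiment with spike-in truth
#'
#' Fragment start positions are uniform over the genome for input samples,
#' background ChIP reads, and all control-condition samples; inside a spiked
#' region of fold `f`, the case-condition ChIP sampling density is `f` times
#' background. Each alignment is the `read_length_bp` 5'-end of its fragment,
#' with strand uniform per fragment; fragments overhanging a chromosome end
#' are truncated there.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()] (used for chromosome bounds).
#' @return list with `samples` (named list of alignment data.frames:
#'   `case_chip_1..n`, `case_input`, `control_chip_1..n`, `control_input`),
#'   `truth` (list with `spiked`), and `chrom_sizes`.
#' @export
simulate_chip_experiment <- function(config, genome) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- genome$chrom_sizes
  spikes <- config$spike_regions
  if (nrow(spikes)) {
    bad <- !spikes$chrom %in% names(sizes) | spikes$end > sizes[spikes$chrom]
    if (any(bad))
      stop("simulate_chip_experiment: spike region outside genome: ",
           paste0(spikes$chrom[bad], ":", spikes$start[bad], "-",
                  spikes$end[bad], collapse = ", "))
  }
  no_spikes <- spikes[0, , drop = FALSE]
  samples <- list()
  k <- 10L  # sub-seed role offset; roles 1-2 are genome and genes
  for (cond in config$conditions) {
    cond_spikes <- if (cond == "case") spikes else no_spikes
    for (r in seq_len(config$n_chip_replicates)) {
      set.seed(sample_seed(config$seed, k)); k <- k + 1L
      samples[[paste0(cond, "_chip_", r)]] <- sample_fragments(
        config$reads_per_chip_replicate, sizes, cond_spikes,
        config$read_length_bp, config$fragment_length_bp)
    }
    set.seed(sample_seed(config$seed, k)); k <- k + 1L
    samples[[paste0(cond, "_input")]] <- sample_fragments(
      config$reads_per_input, sizes, no_spikes,
      config$read_length_bp, config$fragment_length_bp)
  }
  list(samples = samples,
       truth = list(spiked = spikes),
       chrom_sizes = sizes)
}

#' Plant motif consensus sites into a genome
#'
#' Writes the PWM consensus on the forward strand at each requested position;
#' all other bases are unchanged. Overlapping plant positions are an error.
#'
#' @param genome named character vector of sequences (or the list returned by
#'   [simulate_genome()], whose `genome` element is used).
#' @param x a [pwm()].
#' @param positions data.frame with `chrom` and 0-based `pos` columns.
#' @return list with `genome` (modified sequences) and `planted_motifs`
#'   (data.frame `chrom`, `pos`, `strand`).
#' @export
plant_motif_sites <- function(genome, x, positions) {
  stopifnot(inherits(x, "pwm"))
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  cons <- pwm_consensus(x)
  w <- x$width
  if (nrow(positions)) {
    if (any(!positions$chrom %in% names(genome)))
      stop("plant_motif_sites: unknown chromosome")
    lens <- nchar(genome)[positions$chrom]
    if (any(positions$pos < 0 | positions$pos + w > lens))
      stop("plant_motif_sites: position does not fit inside chromosome")
    for (chrom in unique(positions$chrom)) {
      p <- sort(positions$pos[positions$chrom == chrom])
      coll <- which(diff(p) < w)
      if (length(coll))
        stop("plant_motif_sites: overlapping plant positions on ", chrom,
             ": ", paste(p[coll], p[coll + 1L], sep = "/", collapse = ", "))
    }
    for (i in seq_len(nrow(positions))) {
      chrom <- positions$chrom[i]; pos <- positions$pos[i]
      substr(genome[[chrom]], pos + 1L, pos + w) <- cons
    }
  }
  list(genome = genome,
       planted_motifs = data.frame(chrom = positions$chrom,
                                   pos = positions$pos,
                                   strand = rep("+", nrow(positions))))
}
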