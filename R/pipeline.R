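process_replicate <- function(chip_aln, input_norm, chrom_sizes, grid, config,
                              label) {
  prof <- build_coverage(chip_aln, chrom_sizes,
                         extension_bp = config$fragment_extension_bp,
                         sample_label = label)
  prof <- normalize_per_million(prof)
  prof <- subtract_input(prof, input_norm)
  prof <- scale_unit(prof)
  discretize(prof, grid)
}

as_alignments <- function(x) {
  if (is.character(x)) read_alignments(x) else validate_alignments(x)
}

#' Call differentially enriched regions between two ChIP-seq conditions
#'
#' Runs the full coverage-profile workflow: per replicate, read extension,
#' per-million normalization, subtraction of the condition's normalized input
#' and min-max unit scaling; sliding-window discretization and replicate
#' combination per condition; the signed case-minus-control difference
#' profile; removal of windows within `sd_multiplier` SD of the global mean;
#' merging of adjacent same-sign windows with a minimal-span filter; a
#' two-sided two-sample KS test of the case vs control window values of each
#' candidate region; Benjamini-Hochberg correction; optional blacklist
#' filtering. Accepted peaks are case-enriched candidates with
#' `q < q_threshold`.
#'
#' @param case_chip,control_chip lists of alignment data.frames (or BED/BAM
#'   paths), one per ChIP replicate.
#' @param case_input,control_input alignment data.frame (or path) of the
#'   condition's input sample.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param config a [pipeline_config()].
#' @param blacklist optional data.frame of intervals to discard peaks in.
#' @param assignments,whitelist_genes see [apply_blacklist()].
#' @param keep_control_enriched if `TRUE`, control-enriched accepted regions
#'   are returned too (in `peaks`, distinguished by `sign`).
#' @return list with `peaks` (accepted regions), `candidates` (full tested
#'   table with `ks_D`, `p_value`, `q_value`), `difference`
#'   (the `difference_profile`), and `grid`.
#' @export
call_differential_regions <- function(case_chip, case_input,
                                      control_chip, control_input,
                                      chrom_sizes,
                                      config = pipeline_config(),
                                      blacklist = NULL,
                                      assignments = NULL,
                                      whitelist_genes = character(),
                                      keep_control_enriched = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(case_chip) || !length(control_chip))
    stop("call_differential_regions: need at least one ChIP replicate per condition")
  case_chip <- lapply(case_chip, as_alignments)
  control_chip <- lapply(control_chip, as_alignments)
  grid <- window_grid(chrom_sizes, config$window_bp, config$shift_bp)

  inputs <- lapply(list(case = case_input, control = control_input),
                   function(a) {
    prof <- build_coverage(as_alignments(a), chrom_sizes,
                           extension_bp = config$fragment_extension_bp,
                           sample_label = "input")
    normalize_per_million(prof)
  })

  disc <- list(
    case = lapply(seq_along(case_chip), function(i)
      process_replicate(case_chip[[i]], inputs$case, chrom_sizes, grid,
                        config, paste0("case_", i))),
    control = lapply(seq_along(control_chip), function(i)
      process_replicate(control_chip[[i]], inputs$control, chrom_sizes, grid,
                        config, paste0("control_", i))))
  combined <- lapply(disc, combine_replicates)

  diff <- difference_profile(combined$case, combined$control)
  retained <- filter_noise(diff, config$sd_multiplier)
  regions <- merge_regions(retained, grid, config$min_region_bp)

  if (nrow(regions)) {
    case_src <- if (config$ks_per_replicate) disc$case else combined$case
    ctrl_src <- if (config$ks_per_replicate) disc$control else combined$control
    tests <- lapply(seq_len(nrow(regions)), function(i)
      test_region(regions[i, ], case_src, ctrl_src))
    regions$ks_D <- vapply(tests, `[[`, 0, "ks_D")
    regions$p_value <- vapply(tests, `[[`, 0, "p_value")
    regions$q_value <- NA_real_
    fam <- if (config$bh_family == "case_only") regions$sign == 1L else
      rep(TRUE, nrow(regions))
    regions$q_value[fam] <- bh_correct(regions$p_value[fam])
    regions$name <- paste0("peak_", seq_len(nrow(regions)))
  } else {
    regions$ks_D <- numeric()
    regions$p_value <- numeric()
    regions$q_value <- numeric()
    regions$name <- character()
  }

  accepted <- regions[!is.na(regions$q_value) &
                        regions$q_value < config$q_threshold, , drop = FALSE]
  if (!keep_control_enriched)
    accepted <- accepted[accepted$sign == 1L, , drop = FALSE]
  accepted <- apply_blacklist(accepted, blacklist, assignments,
                              whitelist_genes)
  rownames(accepted) <- NULL
  list(peaks = accepted, candidates = regions, difference = diff, grid = grid)
}
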