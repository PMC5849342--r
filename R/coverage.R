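#' @importFrom IRanges IRanges coverage
#' @importFrom methods as
NULL

new_coverage_profile <- function(values, state, sample_label, total_reads) {
  structure(list(values = values, state = state,
                 sample_label = sample_label,
                 total_reads = as.integer(total_reads)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile [", x$state, "] sample=", x$sample_label,
      " reads=", x$total_reads, "\n", sep = "")
  for (chrom in names(x$values))
    cat("  ", chrom, ": ", length(x$values[[chrom]]), " bp\n", sep = "")
  invisible(x)
}

chrom_lengths <- function(profile) vapply(profile$values, length, 1L)

assert_state <- function(profile, state, op) {
  if (!inherits(profile, "coverage_profile"))
    stop(op, ": expected a coverage_profile")
  if (profile$state != state)
    stop(op, ": profile must be in state '", state, "', got '",
         profile$state, "'")
}

validate_alignments <- function(alignments) {
  need <- c("chrom", "start", "end", "strand")
  if (!is.data.frame(alignments) || !all(need %in% names(alignments)))
    stop("alignments must be a data.frame with columns ",
         paste(need, collapse = ", "))
  alignments
}

#' Build a raw base-resolution coverage profile from aligned reads
#'
#' Each read is extended to the original fragment length: a plus-strand read
#' starting at `s` covers `[s, s + extension_bp)`, a minus-strand read ending
#' at `e` covers `[e - extension_bp, e)`. Fragments are clamped to the
#' chromosome. Coordinates are 0-based half-open throughout.
#'
#' @param alignments data.frame with columns `chrom`, `start`, `end`,
#'   `strand` (0-based half-open), as returned by [read_alignments()].
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param extension_bp fragment length to extend each read to.
#' @param sample_label label stored on the profile.
#' @return A `coverage_profile` in state `"raw"`.
#' @export
build_coverage <- function(alignments, chrom_sizes, extension_bp = 200L,
                           sample_label = "sample") {
  validate_alignments(alignments)
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  unknown <- setdiff(unique(alignments$chrom), names(chrom_sizes))
  if (length(unknown))
    stop("alignment on unknown chromosome: ", paste(unknown, collapse = ", "))
  if (any(alignments$start < 0))
    stop("alignment with negative start coordinate")
  if (any(alignments$end > chrom_sizes[alignments$chrom]))
    stop("alignment extends past chromosome end")
  if (extension_bp < 1L) stop("extension_bp must be positive")
  read_len <- alignments$end - alignments$start
  if (nrow(alignments) && extension_bp < max(read_len))
    stop("extension_bp (", extension_bp, ") is shorter than the longest read (",
         max(read_len), ")")

  frag_start <- ifelse(alignments$strand == "+",
                       alignments$start,
                       alignments$end - extension_bp)
  frag_end <- ifelse(alignments$strand == "+",
                     alignments$start + extension_bp,
                     alignments$end)
  frag_start <- pmax(frag_start, 0L)
  frag_end <- pmin(frag_end, chrom_sizes[alignments$chrom])

  values <- lapply(names(chrom_sizes), function(chrom) {
    len <- chrom_sizes[[chrom]]
    on_chrom <- alignments$chrom == chrom
    if (!any(on_chrom)) return(numeric(len))
    cov <- IRanges::coverage(
      IRanges::IRanges(start = frag_start[on_chrom] + 1L,
                       end = frag_end[on_chrom]),
      width = len)
    as.numeric(cov)
  })
  names(values) <- names(chrom_sizes)
  new_coverage_profile(values, "raw", sample_label, nrow(alignments))
}

#' Normalize a raw coverage profile to reads per million
#'
#' Divides every base value by the sample's total read count and multiplies
#' by one million, making profiles of differing sequencing depth comparable.
#'
#' @param profile a `coverage_profile` in state `"raw"`.
#' @return The profile in state `"normalized"`.
#' @export
normalize_per_million <- function(profile) {
  assert_state(profile, "raw", "normalize_per_million")
  if (profile$total_reads == 0L)
    stop("normalize_per_million: empty sample (total_reads = 0)")
  scale <- 1e6 / profile$total_reads
  profile$values <- lapply(profile$values, function(v) v * scale)
  profile$state <- "normalized"
  profile
}

#' Subtract a normalized input profile from a normalized ChIP profile
#'
#' Elementwise `chip - input`. Negative values (input excess) are retained;
#' the subsequent unit scaling absorbs the offset.
#'
#' @param chip,input `coverage_profile`s in state `"normalized"` over the
#'   same chromosomes.
#' @return The ChIP profile in state `"subtracted"`.
#' @export
subtract_input <- function(chip, input) {
  assert_state(chip, "normalized", "subtract_input")
  assert_state(input, "normalized", "subtract_input")
  if (!identical(names(chip$values), names(input$values)) ||
      !identical(unname(chrom_lengths(chip)), unname(chrom_lengths(input))))
    stop("subtract_input: chromosome sets/lengths differ between chip (",
         paste(names(chip$values), collapse = ","), ") and input (",
         paste(names(input$values), collapse = ","), ")")
  chip$values <- Map(`-`, chip$values, input$values)
  chip$state <- "subtracted"
  chip
}

#' Min-max scale a subtracted profile into [0, 1]
#'
#' One transform per replicate over all bases of all chromosomes:
#' `v' = (v - min) / (max - min)`. A constant profile maps to all zeros.
#'
#' @param profile a `coverage_profile` in state `"subtracted"`.
#' @return The profile in state `"unit_scaled"`.
#' @export
scale_unit <- function(profile) {
  assert_state(profile, "subtracted", "scale_unit")
  if (!length(profile$values)) stop("scale_unit: empty profile")
  rng <- range(unlist(lapply(profile$values, range), use.names = FALSE))
  span <- rng[2L] - rng[1L]
  profile$values <- lapply(profile$values, function(v) {
    if (span == 0) numeric(length(v)) else (v - rng[1L]) / span
  })
  profile$state <- "unit_scaled"
  profile
}
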