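#' Pipeline configuration
#'
#' Bundles the tunable constants of the differential enrichment workflow and
#' its downstream annotation/scanning steps. Defaults are the workflow's
#' standard operating point for 50 bp single-end transcription-factor
#' ChIP-seq: reads extended to the 200 bp fragment, 50 bp windows shifted by
#' half a window, a 4 standard-deviation noise cut, and acceptance at
#' q < 0.05.
#'
#' @param fragment_extension_bp fragment length each read is extended to (bp).
#' @param window_bp sliding-window size for discretization (bp).
#' @param shift_bp window shift; defaults to half the window size.
#' @param sd_multiplier difference values within `sd_multiplier` standard
#'   deviations of the global mean are discarded as noise.
#' @param q_threshold Benjamini-Hochberg q-value acceptance threshold.
#' @param min_region_bp minimal merged-region span; defaults to `window_bp`.
#' @param upstream_assign_bp upstream reach of peak-to-gene assignment (bp).
#' @param scan_p_threshold motif-scan p-value threshold.
#' @param annotate_upstream_bp,annotate_downstream_bp gene-window limits used
#'   when annotating motif hits to genes (bp).
#' @param fc_threshold fold-change cutoff for differential-expression lists.
#' @param ks_per_replicate if `TRUE`, the KS test pools per-replicate window
#'   values instead of the replicate-combined values.
#' @param bh_family `"all"` corrects over candidates of both signs,
#'   `"case_only"` over case-enriched candidates only.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fragment_extension_bp = 200L,
                            window_bp = 50L,
                            shift_bp = NULL,
                            sd_multiplier = 4,
                            q_threshold = 0.05,
                            min_region_bp = NULL,
                            upstream_assign_bp = 1000L,
                            scan_p_threshold = 1e-4,
                            annotate_upstream_bp = 5000L,
                            annotate_downstream_bp = 1000L,
                            fc_threshold = 1.5,
                            ks_per_replicate = FALSE,
                            bh_family = c("all", "case_only")) {
  if (is.null(shift_bp)) shift_bp <- window_bp %/% 2L
  if (is.null(min_region_bp)) min_region_bp <- window_bp
  bh_family <- match.arg(bh_family)
  num_fields <- list(fragment_extension_bp = fragment_extension_bp,
                     window_bp = window_bp, shift_bp = shift_bp,
                     sd_multiplier = sd_multiplier, q_threshold = q_threshold,
                     min_region_bp = min_region_bp,
                     upstream_assign_bp = upstream_assign_bp,
                     scan_p_threshold = scan_p_threshold,
                     annotate_upstream_bp = annotate_upstream_bp,
                     annotate_downstream_bp = annotate_downstream_bp,
                     fc_threshold = fc_threshold)
  for (nm in names(num_fields)) {
    v <- num_fields[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("pipeline_config: field '", nm, "' must be a single positive number")
  }
  if (window_bp %% shift_bp != 0L && shift_bp * 2L != window_bp)
    stop("pipeline_config: shift_bp must divide window_bp (or be window_bp/2)")
  structure(list(fragment_extension_bp = as.integer(fragment_extension_bp),
                 window_bp = as.integer(window_bp),
                 shift_bp = as.integer(shift_bp),
                 sd_multiplier = sd_multiplier,
                 q_threshold = q_threshold,
                 min_region_bp = as.integer(min_region_bp),
                 upstream_assign_bp = as.integer(upstream_assign_bp),
                 scan_p_threshold = scan_p_threshold,
                 annotate_upstream_bp = as.integer(annotate_upstream_bp),
                 annotate_downstream_bp = as.integer(annotate_downstream_bp),
                 fc_threshold = fc_threshold,
                 ks_per_replicate = isTRUE(ks_per_replicate),
                 bh_family = bh_family),
            class = "pipeline_config")
}

#' Read or write a flat key: value configuration file
#'
#' One `key: value` pair per line; blank lines and `#` comments ignored.
#' Values are parsed as numbers or logicals where possible.
#'
#' @param path file path.
#' @return For `read_config`, a `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", lines))
  bad <- vapply(kv, length, 1L) != 3L
  if (any(bad)) stop("read_config: malformed line: ", lines[bad][1L])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- lapply(kv, function(m) {
    v <- m[3L]
    if (v %in% c("TRUE", "FALSE", "true", "false")) return(toupper(v) == "TRUE")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(vals) <- keys
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  fmt <- vapply(names(config), function(nm) {
    paste0(nm, ": ", format(config[[nm]], scientific = FALSE))
  }, "")
  writeLines(fmt, path)
  invisible(path)
}
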