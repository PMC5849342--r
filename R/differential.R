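#' Signed difference profile between case and control window profiles
#'
#' Per-window `case - control` on a shared grid. With unit-scaled inputs the
#' values lie in `[-1, 1]` and, absent true differences, are approximately
#' normal with mean near 0; the global mean and standard deviation over all
#' windows of all chromosomes are recorded for the noise filter.
#'
#' @param case,control replicate-combined `discretized_profile`s on
#'   identical grids.
#' @return A list of class `difference_profile` with fields `grid`, `values`,
#'   `global_mean`, `global_sd`.
#' @export
difference_profile <- function(case, control) {
  stopifnot(inherits(case, "discretized_profile"),
            inherits(control, "discretized_profile"))
  if (!same_grid(case$grid, control$grid))
    stop("difference_profile: case and control grids differ")
  values <- Map(`-`, case$values, control$values)
  all_v <- unlist(values, use.names = FALSE)
  structure(list(grid = case$grid, values = values,
                 global_mean = mean(all_v),
                 global_sd = if (length(all_v) > 1L) stats::sd(all_v) else 0),
            class = "difference_profile")
}

#' Noise-filter a difference profile at a standard-deviation cutoff
#'
#' Retains window `i` iff `|v_i - mean| >= sd_multiplier * sd`, with mean and
#' SD taken genome-wide over all windows. A zero-SD (constant) profile
#' retains nothing.
#'
#' @param diff a `difference_profile`.
#' @param sd_multiplier width of the discarded central band in SD units.
#' @return data.frame of retained windows: `chrom`, `window` (1-based index
#'   on the grid), `start`, `end`, `value`, `sign` (+1/-1).
#' @export
filter_noise <- function(diff, sd_multiplier = 4) {
  stopifnot(inherits(diff, "difference_profile"))
  out <- lapply(names(diff$values), function(chrom) {
    v <- diff$values[[chrom]]
    keep <- if (diff$global_sd == 0) rep(FALSE, length(v)) else
      abs(v - diff$global_mean) >= sd_multiplier * diff$global_sd
    if (!any(keep)) return(NULL)
    b <- window_bounds(diff$grid, chrom)
    data.frame(chrom = chrom, window = which(keep),
               start = b$start[keep], end = b$end[keep],
               value = v[keep], sign = ifelse(v[keep] >= 0, 1L, -1L))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), window = integer(),
                      start = integer(), end = integer(),
                      value = numeric(), sign = integer())
  out
}

#' Merge retained same-sign windows into candidate regions
#'
#' Windows whose genomic spans overlap or abut and that share the sign of
#' their difference value are merged (span = union). Regions shorter than
#' `min_region_bp` are discarded.
#'
#' @param retained data.frame from [filter_noise()].
#' @param grid the `window_grid` the windows live on.
#' @param min_region_bp minimal region span in bp.
#' @return data.frame of candidate regions sorted by (chrom, start):
#'   `chrom`, `start`, `end`, `sign`, `n_windows`.
#' @export
merge_regions <- function(retained, grid, min_region_bp = grid$window_bp) {
  if (!nrow(retained))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), sign = integer(),
                      n_windows = integer()))
  pieces <- lapply(split(retained, list(retained$chrom, retained$sign),
                         drop = TRUE), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(d$start[-1L] > cummax(d$end[-nrow(d)]))))
    agg <- lapply(split(seq_len(nrow(d)), grp), function(i)
      data.frame(chrom = d$chrom[1L], start = min(d$start[i]),
                 end = max(d$end[i]), sign = d$sign[1L],
                 n_windows = length(i)))
    do.call(rbind, agg)
  })
  regions <- do.call(rbind, pieces)
  regions <- regions[regions$end - regions$start >= min_region_bp, ,
                     drop = FALSE]
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  regions
}

#' Two-sample two-sided Kolmogorov-Smirnov test
#'
#' Computes `D`, the supremum of the absolute ECDF difference, and its
#' p-value: exact (tie-aware, conditional on the pooled sample) when
#' `length(x) * length(y) <= exact_max`, by the asymptotic Kolmogorov series
#' otherwise.
#'
#' @param x,y numeric sample vectors.
#' @param exact_max product-of-sizes bound below which the exact p is used.
#' @return list with elements `D`, `p_value`, `exact`.
#' @export
ks_test2 <- function(x, y, exact_max = 10000) {
  m <- length(x); n <- length(y)
  if (m < 1L || n < 1L) stop("ks_test2: both samples must be non-empty")
  pooled <- sort(unique(c(x, y)))
  fx <- vapply(pooled, function(t) mean(x <= t), 0)
  fy <- vapply(pooled, function(t) mean(y <= t), 0)
  D <- max(abs(fx - fy))
  exact <- m * n <= exact_max
  p <- if (exact) {
    stats::psmirnov(D, sizes = c(m, n), z = c(x, y),
                    two.sided = TRUE, exact = TRUE, lower.tail = FALSE)
  } else {
    t <- sqrt(m * n / (m + n)) * D
    k <- seq_len(100)
    min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
  }
  list(D = D, p_value = min(1, max(0, p)), exact = exact)
}

#' KS-test a candidate region on case vs control window values
#'
#' Tests the multisets of per-window values whose windows overlap the region
#' span, case against control, with the two-sided two-sample KS test.
#'
#' @param region one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param case,control `discretized_profile`s (replicate-combined by
#'   default); alternatively lists of per-replicate profiles, whose window
#'   values are pooled.
#' @return list with `ks_D`, `p_value`, `n_case`, `n_control`.
#' @export
test_region <- function(region, case, control) {
  pull <- function(p) {
    profs <- if (inherits(p, "discretized_profile")) list(p) else p
    unlist(lapply(profs, function(pr) {
      b <- window_bounds(pr$grid, region$chrom)
      hit <- b$start < region$end & b$end > region$start
      pr$values[[region$chrom]][hit]
    }), use.names = FALSE)
  }
  xv <- pull(case); yv <- pull(control)
  if (!length(xv) || !length(yv))
    stop("test_region: region spans no grid window")
  ks <- ks_test2(xv, yv)
  list(ks_D = ks$D, p_value = ks$p_value,
       n_case = length(xv), n_control = length(yv))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_correct <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("bh_correct: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Drop regions overlapping blacklist intervals, with gene exemptions
#'
#' A region overlapping any blacklist interval is discarded unless it is
#' assigned (via `assignments`) to a gene named in `whitelist_genes`.
#'
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); a `name` column is used to match assignments if present.
#' @param blacklist data.frame with `chrom`, `start`, `end`, or NULL/empty
#'   for a no-op.
#' @param assignments optional data.frame with `peak`, `gene_id` as returned
#'   by [assign_peaks_to_genes()].
#' @param whitelist_genes character vector of exempt gene identifiers.
#' @return The filtered regions data.frame.
#' @export
apply_blacklist <- function(regions, blacklist, assignments = NULL,
                            whitelist_genes = character()) {
  if (is.null(blacklist) || !nrow(blacklist) || !nrow(regions)) return(regions)
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end))
  bg <- GenomicRanges::GRanges(blacklist$chrom,
                               IRanges::IRanges(blacklist$start + 1L, blacklist$end))
  hit <- IRanges::overlapsAny(rg, bg)
  if (length(whitelist_genes) && !is.null(assignments) && nrow(assignments)) {
    nm <- if ("name" %in% names(regions)) regions$name else
      paste0(regions$chrom, ":", regions$start, "-", regions$end)
    exempt_peaks <- unique(assignments$peak[assignments$gene_id %in%
                                              whitelist_genes])
    hit <- hit & !(nm %in% exempt_peaks)
  }
  out <- regions[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
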