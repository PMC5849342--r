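#' Sliding-window grid over a chromosome set
#'
#' Windows are half-open intervals `[k*shift, k*shift + window)`, anchored at
#' coordinate 0 and clipped at the chromosome end; the trailing partial
#' window is kept. Consecutive windows overlap by `window - shift` bases.
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param window_bp window size in bp.
#' @param shift_bp window shift in bp; defaults to half the window.
#' @return A list of class `window_grid`.
#' @export
window_grid <- function(chrom_sizes, window_bp = 50L, shift_bp = NULL) {
  if (is.null(shift_bp)) shift_bp <- window_bp %/% 2L
  stopifnot(window_bp >= 1L, shift_bp >= 1L, shift_bp <= window_bp)
  n_windows <- vapply(chrom_sizes, function(len) {
    as.integer(ceiling(len / shift_bp))
  }, 1L)
  structure(list(window_bp = as.integer(window_bp),
                 shift_bp = as.integer(shift_bp),
                 chrom_sizes = chrom_sizes,
                 n_windows = n_windows),
            class = "window_grid")
}

#' Window boundaries for one chromosome of a grid
#'
#' @param grid a `window_grid`.
#' @param chrom chromosome name.
#' @return data.frame with 0-based half-open `start`, `end` per window.
#' @export
window_bounds <- function(grid, chrom) {
  len <- grid$chrom_sizes[[chrom]]
  if (is.null(len)) stop("window_bounds: unknown chromosome ", chrom)
  k <- seq_len(grid$n_windows[[chrom]]) - 1L
  start <- k * grid$shift_bp
  data.frame(start = start, end = pmin(start + grid$window_bp, len))
}

same_grid <- function(a, b) {
  identical(a$window_bp, b$window_bp) &&
    identical(a$shift_bp, b$shift_bp) &&
    identical(unname(a$chrom_sizes), unname(b$chrom_sizes)) &&
    identical(names(a$chrom_sizes), names(b$chrom_sizes))
}

new_discretized_profile <- function(grid, values, n_replicates_combined = 1L) {
  structure(list(grid = grid, values = values,
                 n_replicates_combined = as.integer(n_replicates_combined)),
            class = "discretized_profile")
}

#' @export
print.discretized_profile <- function(x, ...) {
  cat("discretized_profile: window=", x$grid$window_bp, " shift=",
      x$grid$shift_bp, " replicates=", x$n_replicates_combined, "\n", sep = "")
  invisible(x)
}

#' Discretize a unit-scaled coverage profile on a sliding-window grid
#'
#' Each window value is the arithmetic mean of the base values it spans;
#' clipped trailing windows average over their actual span.
#'
#' @param profile a `coverage_profile` in state `"unit_scaled"`.
#' @param grid a `window_grid` over the same chromosomes.
#' @return A `discretized_profile`.
#' @export
discretize <- function(profile, grid) {
  assert_state(profile, "unit_scaled", "discretize")
  if (!identical(names(profile$values), names(grid$chrom_sizes)) ||
      !identical(unname(chrom_lengths(profile)),
                 unname(as.integer(grid$chrom_sizes))))
    stop("discretize: profile chromosomes do not match the grid")
  values <- lapply(names(grid$chrom_sizes), function(chrom) {
    v <- profile$values[[chrom]]
    b <- window_bounds(grid, chrom)
    cs <- c(0, cumsum(v))
    (cs[b$end + 1L] - cs[b$start + 1L]) / (b$end - b$start)
  })
  names(values) <- names(grid$chrom_sizes)
  new_discretized_profile(grid, values, 1L)
}

#' Combine replicate discretized profiles by per-window mean
#'
#' @param profiles list of `discretized_profile`s on identical grids.
#' @return A `discretized_profile` with `n_replicates_combined` set.
#' @export
combine_replicates <- function(profiles) {
  if (!length(profiles)) stop("combine_replicates: need at least one profile")
  stopifnot(all(vapply(profiles, inherits, TRUE, "discretized_profile")))
  grid <- profiles[[1L]]$grid
  for (p in profiles[-1L])
    if (!same_grid(grid, p$grid))
      stop("combine_replicates: profiles are on different grids")
  values <- lapply(names(grid$chrom_sizes), function(chrom) {
    Reduce(`+`, lapply(profiles, function(p) p$values[[chrom]])) /
      length(profiles)
  })
  names(values) <- names(grid$chrom_sizes)
  new_discretized_profile(grid, values, length(profiles))
}
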