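#' Read a motif from MEME minimal format
#'
#' Parses the first `letter-probability matrix` block of a MEME minimal
#' motif file (alphabet ACGT). Per-position probabilities off unity by at
#' most 1e-3 are renormalized; a larger deviation is a parse error. The
#' `Background letter frequencies` line is honoured; absent one, the
#' background is uniform.
#'
#' @param text path to a MEME file, or its lines as a character vector.
#' @param pseudocount pseudocount stored on the returned PWM.
#' @return A [pwm()].
#' @export
load_meme_motif <- function(text, pseudocount = 0.01) {
  lines <- if (length(text) == 1L && file.exists(text))
    readLines(text, warn = FALSE) else
      unlist(strsplit(text, "\n", fixed = TRUE))
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    tok <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    if (length(tok) != 8L)
      stop("load_meme_motif: malformed background line at line ",
           bg_at[1L] + 1L)
    vals <- as.numeric(tok[c(2L, 4L, 6L, 8L)])
    names(vals) <- tok[c(1L, 3L, 5L, 7L)]
    bg <- as.numeric(vals[DNA])
  }
  motif_at <- grep("^MOTIF\\b", lines)
  if (!length(motif_at)) stop("load_meme_motif: no MOTIF block found")
  name <- sub("^MOTIF\\s+", "", lines[motif_at[1L]])
  name <- strsplit(trimws(name), "\\s+")[[1L]][1L]
  lpm_at <- grep("^letter-probability matrix", lines)
  lpm_at <- lpm_at[lpm_at > motif_at[1L]]
  if (!length(lpm_at))
    stop("load_meme_motif: no letter-probability matrix after line ",
         motif_at[1L])
  header <- lines[lpm_at[1L]]
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", header))
  if (is.na(w)) stop("load_meme_motif: cannot parse w= at line ", lpm_at[1L])
  rows <- lines[(lpm_at[1L] + 1L):(lpm_at[1L] + w)]
  mat <- matrix(NA_real_, nrow = w, ncol = 4L)
  for (i in seq_len(w)) {
    tok <- strsplit(trimws(rows[i]), "\\s+")[[1L]]
    v <- suppressWarnings(as.numeric(tok))
    if (length(v) != 4L || anyNA(v))
      stop("load_meme_motif: malformed matrix row at line ", lpm_at[1L] + i)
    if (abs(sum(v) - 1) > 1e-3)
      stop("load_meme_motif: row at line ", lpm_at[1L] + i,
           " sums to ", sum(v), " (> 1e-3 off unity)")
    mat[i, ] <- v / sum(v)
  }
  pwm(mat, background = bg, pseudocount = pseudocount, name = name)
}

#' Write a motif in MEME minimal format
#'
#' @param x a [pwm()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_meme_motif <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  lines <- c(
    "MEME version 4",
    "",
    "ALPHABET= ACGT",
    "",
    "strands: + -",
    "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", DNA, x$background), collapse = " "),
    "",
    paste("MOTIF", x$name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            x$width),
    apply(x$matrix, 1L, function(r) paste(sprintf("%.17g", r), collapse = "  ")))
  writeLines(lines, path)
  invisible(path)
}
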