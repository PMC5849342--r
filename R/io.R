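#' Read aligned reads from BED6 or BAM
#'
#' Returns 0-based half-open intervals. BED is passed through; BAM records
#' are converted (alignment width from the CIGAR); unmapped BAM records are
#' skipped with a counted warning.
#'
#' @param path path to a `.bed` or `.bam` file.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("read_alignments: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bam") return(read_alignments_bam(path))
  if (ext %in% c("bed", "txt", "tsv", "")) return(read_alignments_bed(path))
  stop("read_alignments: unknown format '.", ext,
       "'; accepted formats are BED6 and BAM")
}

read_alignments_bed <- function(path) {
  if (file.size(path) == 0L) {
    warning("read_alignments: empty file ", path)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "character", "character", "character"),
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"))
  if (any(!d$strand %in% c("+", "-")))
    stop("read_alignments: invalid strand in ", path)
  d[, c("chrom", "start", "end", "strand")]
}

read_alignments_bam <- function(path) {
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
  n_total <- Rsamtools::countBam(path)$records
  if (n_total > length(ga))
    warning("read_alignments: skipped ", n_total - length(ga),
            " unmapped records in ", path)
  data.frame(chrom = as.character(GenomicAlignments::seqnames(ga)),
             start = GenomicAlignments::start(ga) - 1L,
             end = GenomicAlignments::end(ga),
             strand = as.character(GenomicAlignments::strand(ga)))
}

#' Read chromosome sizes from two-column text
#'
#' @param path file with lines `name<TAB>length`.
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "integer"))
  stats::setNames(d$length, d$chrom)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes named integer vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes), chrom_sizes),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write alignments as 6-column BED
#'
#' Output is coordinate-sorted, 0-based half-open, with `name` `read_k` and
#' score 0.
#'
#' @param alignments data.frame with `chrom`, `start`, `end`, `strand`.
#' @param path output path.
#' @export
write_bed_alignments <- function(alignments, path) {
  validate_alignments(alignments)
  a <- alignments[order(alignments$chrom, alignments$start, alignments$end), ]
  d <- data.frame(a$chrom, a$start, a$end,
                  paste0("read_", seq_len(nrow(a))), 0L, a$strand)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write accepted peaks as BED6+4
#'
#' Columns: chrom, start, end, name, `score = round(-10*log10(q))` capped at
#' 1000, strand ".", then sign, KS D, p and q.
#'
#' @param peaks peaks data.frame from [call_differential_regions()].
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- if (nrow(peaks)) pmin(1000L, round(-10 * log10(pmax(
    peaks$q_value, 1e-100)))) else integer()
  d <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name, score,
                  ".", peaks$sign, signif(peaks$ks_D, 6),
                  signif(peaks$p_value, 6), signif(peaks$q_value, 6))
  d <- d[order(d[[1L]], d[[2L]]), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export a coverage or discretized profile as bedGraph
#'
#' Coverage profiles are run-length collapsed per base; discretized profiles
#' are written on window midpoints (inspection only).
#'
#' @param profile a `coverage_profile` or `discretized_profile`.
#' @param path output path.
#' @export
write_bedgraph <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(profile, "coverage_profile")) {
    for (chrom in names(profile$values)) {
      r <- rle(profile$values[[chrom]])
      end <- cumsum(r$lengths)
      start <- end - r$lengths
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, start, end, r$values), con)
    }
  } else if (inherits(profile, "discretized_profile")) {
    for (chrom in names(profile$values)) {
      b <- window_bounds(profile$grid, chrom)
      mid <- (b$start + b$end) %/% 2L
      writeLines(sprintf("%s\t%d\t%d\t%g", chrom, mid, mid + 1L,
                         profile$values[[chrom]]), con)
    }
  } else stop("write_bedgraph: unsupported object")
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome named character vector or `Biostrings::DNAStringSet`.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  stats::setNames(as.character(g), names(g))
}

#' Write gene models as GTF (gene features, 1-based closed)
#'
#' @param genes gene-model data.frame (see [gene_models()]).
#' @param path output path.
#' @export
write_gtf <- function(genes, path) {
  genes <- gene_models(genes)
  lines <- sprintf(
    "%s\tprofdiff\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    genes$chrom, genes$start + 1L, genes$end, genes$strand, genes$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF or BED6
#'
#' GTF gene features (or, absent those, the per-gene span of all features
#' sharing a `gene_id`) are converted to 0-based half-open gene models; BED6
#' is taken as one gene per line with the `name` column as `gene_id`.
#'
#' @param path `.gtf`/`.gff` or `.bed` path.
#' @return gene-model data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_genes <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff", "gff3")) {
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    if (!"gene_id" %in% names(S4Vectors::mcols(gr)))
      stop("read_genes: GTF lacks gene_id attributes")
    d <- data.frame(gene_id = gr$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)))
    if (anyDuplicated(d$gene_id)) {  # collapse transcripts to the gene span
      sp <- split(d, d$gene_id)
      d <- do.call(rbind, lapply(sp, function(g)
        data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
                   start = min(g$start), end = max(g$end),
                   strand = g$strand[1L])))
    }
    rownames(d) <- NULL
    return(gene_models(d))
  }
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "character", "character"))
  gene_models(data.frame(gene_id = d$name, chrom = d$chrom, start = d$start,
                         end = d$end, strand = d$strand))
}

#' Write a JSON run manifest
#'
#' Records the configuration snapshot, input checksums, per-stage record
#' counts, package version and seed of a pipeline run; re-running with an
#' identical manifest reproduces identical outputs.
#'
#' @param manifest named list.
#' @param path output `.json` path.
#' @export
write_manifest <- function(manifest, path) {
  manifest$tool_version <- as.character(utils::packageVersion("profdiff"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

file_checksum <- function(path) unname(tools::md5sum(path))
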