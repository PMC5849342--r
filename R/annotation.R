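#' Gene model table
#'
#' Validates a gene-model data.frame and derives the transcription start
#' site. Coordinates are 0-based half-open; the TSS of a plus-strand gene is
#' `start`, of a minus-strand gene `end - 1`.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @return The validated data.frame with a `tss` column.
#' @export
gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!is.data.frame(genes) || !all(need %in% names(genes)))
    stop("gene_models: need columns ", paste(need, collapse = ", "))
  if (any(genes$start >= genes$end))
    stop("gene_models: degenerate gene interval (start >= end)")
  if (any(!genes$strand %in% c("+", "-")))
    stop("gene_models: strand must be '+' or '-'")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes
}

genes_to_granges <- function(genes, flank_up = 0L, flank_down = 0L) {
  plus <- genes$strand == "+"
  start0 <- ifelse(plus, genes$start - flank_up, genes$start - flank_down)
  end0 <- ifelse(plus, genes$end + flank_down, genes$end + flank_up)
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(pmax(start0, 0L) + 1L,
                                          pmax(end0, pmax(start0, 0L))),
                         strand = genes$strand)
}

relation_to_gene <- function(q_start, q_end, gene) {
  if (q_start < gene$end && q_end > gene$start) return("body")
  upstream <- if (gene$strand == "+") q_end <= gene$start else
    q_start >= gene$end
  if (upstream) "upstream" else "downstream"
}

#' Assign peaks to genes by body overlap or an upstream window
#'
#' A peak is associated with a gene iff it overlaps the gene body or the
#' strand-aware window `upstream_bp` 5' of the TSS. A peak may map to several
#' genes (nested or dense gene regions); peaks matching no gene are listed
#' with `gene_id = NA`.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open);
#'   an optional `name` column labels the peaks.
#' @param genes gene-model data.frame (see [gene_models()]).
#' @param upstream_bp upstream reach from the TSS in bp.
#' @return data.frame with `peak`, `gene_id`, `relation` in
#'   \{body, upstream\}; unassigned peaks carry `NA` gene and relation.
#' @export
assign_peaks_to_genes <- function(peaks, genes, upstream_bp = 1000L) {
  genes <- gene_models(genes)
  nm <- if ("name" %in% names(peaks)) peaks$name else
    paste0(peaks$chrom, ":", peaks$start, "-", peaks$end)
  if (!nrow(peaks))
    return(data.frame(peak = character(), gene_id = character(),
                      relation = character()))
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end))
  gg <- genes_to_granges(genes, flank_up = upstream_bp)
  ov <- GenomicRanges::findOverlaps(pg, gg, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  rel <- vapply(seq_along(qi), function(k)
    relation_to_gene(peaks$start[qi[k]], peaks$end[qi[k]], genes[si[k], ]),
    "")
  out <- data.frame(peak = nm[qi], gene_id = genes$gene_id[si],
                    relation = rel)
  unassigned <- setdiff(nm, out$peak)
  if (length(unassigned))
    out <- rbind(out, data.frame(peak = unassigned, gene_id = NA_character_,
                                 relation = NA_character_))
  rownames(out) <- NULL
  out
}

#' Annotate genomic hits to strand-aware gene windows
#'
#' A hit is annotated to a gene iff it lies within the gene body, at most
#' `upstream_bp` 5' of the gene, or at most `downstream_bp` 3' of the gene
#' (strand-aware). Used to relate genome-wide motif occurrences to genes.
#'
#' @param hits data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genes gene-model data.frame (see [gene_models()]).
#' @param upstream_bp,downstream_bp window limits in bp.
#' @return list with `annotations` (data.frame `hit`, `gene_id`, `relation`)
#'   and `n_genes`, the number of distinct genes with at least one hit.
#' @export
annotate_hits_to_gene_windows <- function(hits, genes, upstream_bp = 5000L,
                                          downstream_bp = 1000L) {
  genes <- gene_models(genes)
  if (!nrow(hits))
    return(list(annotations = data.frame(hit = integer(),
                                         gene_id = character(),
                                         relation = character()),
                n_genes = 0L))
  hg <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L, hits$end))
  gg <- genes_to_granges(genes, flank_up = upstream_bp,
                         flank_down = downstream_bp)
  ov <- GenomicRanges::findOverlaps(hg, gg, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  rel <- vapply(seq_along(qi), function(k)
    relation_to_gene(hits$start[qi[k]], hits$end[qi[k]], genes[si[k], ]),
    "")
  ann <- data.frame(hit = qi, gene_id = genes$gene_id[si], relation = rel)
  list(annotations = ann, n_genes = length(unique(ann$gene_id)))
}
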