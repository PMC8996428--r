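# Gene-structure (intron) and chromosome-distribution summaries.

#' Intron counts and intronless percentage
#'
#' Intron count is computed on transcript exons (intron = exon count - 1),
#' the GSDS convention, not on CDS segments.
#'
#' @param genes List of [gene_model()] objects.
#' @return List with `per_gene` (data.frame gene_id, n_exons, n_introns),
#'   `n_intronless`, and `pct_intronless` (percent of the full family,
#'   rounded to 2 decimals).
#' @export
intron_counts <- function(genes) {
  nex <- vapply(genes, function(g) nrow(g$exons), integer(1))
  if (any(nex == 0L))
    stop("gene(s) with 0 exons: ",
         paste(vapply(genes[nex == 0L], `[[`, character(1), "gene_id"),
               collapse = ", "))
  per_gene <- data.frame(
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    n_exons = nex, n_introns = nex - 1L,
    row.names = NULL, stringsAsFactors = FALSE)
  n0 <- sum(per_gene$n_introns == 0L)
  list(per_gene = per_gene, n_intronless = n0,
       pct_intronless = round_half_up(100 * n0 / nrow(per_gene), 2L))
}

#' Per-chromosome gene counts
#'
#' @param genes List of [gene_model()] objects.
#' @param chromosomes Optional character vector of all chromosome names;
#'   chromosomes without genes are reported with count 0.
#' @return Named integer vector chromosome -> gene count.
#' @export
chromosome_distribution <- function(genes, chromosomes = NULL) {
  chr <- vapply(genes, `[[`, character(1), "chromosome")
  lev <- if (is.null(chromosomes)) sort(unique(chr)) else chromosomes
  counts <- table(factor(chr, levels = lev))
  stats::setNames(as.integer(counts), names(counts))
}

round_half_up <- function(x, digits = 0L) {
  # round() is half-even; survey percentages use conventional half-up.
  p <- 10^digits
  floor(x * p + 0.5) / p
}
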