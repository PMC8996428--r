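#' Read a FASTA file into a named character vector
#'
#' Sequence identifiers are the first whitespace-delimited token of each
#' header line; sequences are uppercased. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, one per record.
#'   An empty file yields an empty vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  stats::setNames(toupper(as.character(set)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' @param seq Character scalar over A/C/G/T/N (IUPAC ambiguity codes allowed).
#' @return Reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a CDS to protein using the standard genetic code
#'
#' @param cds Nucleotide string with length divisible by 3 and no internal
#'   stop codons. A terminal stop codon is trimmed.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length not divisible by 3 (", nchar(cds), " nt)")
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  aa <- GENETIC_CODE_STD[codons]
  if (anyNA(aa)) stop("untranslatable codon(s): ",
                      paste(unique(codons[is.na(aa)]), collapse = ", "))
  if (length(aa) > 1L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) stop("internal stop codon in CDS")
  paste(aa, collapse = "")
}

#' Construct a gene model
#'
#' A gene model records location (1-based inclusive coordinates), strand,
#' transcript exon structure, and optionally the spliced CDS and protein.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name.
#' @param strand "+" or "-".
#' @param start,end Gene span, 1-based inclusive, `start <= end`.
#' @param exons Two-column matrix (start, end) of exon intervals, any order.
#' @param cds_seq Optional spliced CDS sequence.
#' @param protein_seq Optional protein sequence.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, start, end, exons,
                       cds_seq = NULL, protein_seq = NULL,
                       cds_start_genomic = NULL) {
  if (!strand %in% c("+", "-")) stop("unknown strand symbol: ", strand)
  if (start > end) stop("gene ", gene_id, ": start > end")
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] > exons[, 2L])) stop("gene ", gene_id, ": exon start > end")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
    stop("gene ", gene_id, ": overlapping exons")
  if (any(exons[, 1L] < start | exons[, 2L] > end))
    stop("gene ", gene_id, ": exon outside gene span")
  if (!is.null(cds_seq) && !is.null(protein_seq)) {
    if (nchar(cds_seq) %% 3L != 0L)
      stop("gene ", gene_id, ": CDS length not divisible by 3")
    pl <- nchar(protein_seq)
    if (!(pl == nchar(cds_seq) / 3L - 1L || pl == nchar(cds_seq) / 3L))
      stop("gene ", gene_id, ": protein length inconsistent with CDS")
  }
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 start = start, end = end, exons = exons,
                 cds_seq = cds_seq, protein_seq = protein_seq,
                 cds_start_genomic = cds_start_genomic),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d exon(s)%s\n", x$gene_id,
              x$chromosome, x$start, x$end, x$strand, nrow(x$exons),
              if (is.null(x$cds_seq)) "" else sprintf(", CDS %d nt", nchar(x$cds_seq))))
  invisible(x)
}

#' Bundle a genome with its gene models
#'
#' @param chromosomes Named character vector of chromosome sequences.
#' @param genes List of [gene_model()] objects.
#' @return Object of class `genome_bundle`.
#' @export
genome_bundle <- function(chromosomes, genes) {
  if (anyDuplicated(names(chromosomes)))
    stop("duplicate chromosome names")
  for (g in genes) {
    if (!g$chromosome %in% names(chromosomes))
      stop("gene ", g$gene_id, " references unknown chromosome ", g$chromosome)
    if (g$end > nchar(chromosomes[[g$chromosome]]))
      stop("gene ", g$gene_id, " extends beyond chromosome ", g$chromosome)
  }
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat(sprintf("<genome_bundle> %d chromosome(s) (%.1f kb), %d gene(s)\n",
              length(x$chromosomes), sum(nchar(x$chromosomes)) / 1000,
              length(x$genes)))
  invisible(x)
}

#' Read gene models from a GFF3 annotation
#'
#' Builds one [gene_model()] per `gene` feature. Exons are taken from the
#' representative mRNA: the single mRNA if there is one, otherwise the mRNA
#' with the longest total CDS. Exons are stored sorted ascending regardless
#' of file order. Coordinates are the GFF3 1-based inclusive dialect.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @param genome Optional named character vector of chromosome sequences;
#'   when supplied, the spliced CDS and its translation are attached to each
#'   model (the CDS must then be translatable).
#' @return List of `gene_model` objects, named by gene id.
#' @export
read_gff3 <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  getp <- function(row) {
    p <- df$Parent[[row]]
    if (length(p) == 0L) NA_character_ else as.character(p)[1L]
  }
  df$parent <- vapply(seq_len(nrow(df)), getp, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    strand <- genes$strand[i]
    if (!strand %in% c("+", "-")) stop("gene ", gid, ": unknown strand symbol '", strand, "'")
    mrnas <- df[df$type == "mRNA" & df$parent == gid, , drop = FALSE]
    if (nrow(mrnas) == 0L) {
      # gene without mRNA children: treat the gene span as a single exon
      exdf <- genes[i, , drop = FALSE]
      cdsdf <- df[df$type == "CDS" & df$parent == gid, , drop = FALSE]
    } else {
      if (nrow(mrnas) > 1L) {
        cdslen <- vapply(mrnas$ID, function(m) {
          sum(df$width[df$type == "CDS" & df$parent == m])
        }, numeric(1))
        mrnas <- mrnas[which.max(cdslen), , drop = FALSE]
      }
      mid <- mrnas$ID[1L]
      exdf <- df[df$type == "exon" & df$parent == mid, , drop = FALSE]
      if (nrow(exdf) == 0L) exdf <- mrnas
      cdsdf <- df[df$type == "CDS" & df$parent == mid, , drop = FALSE]
    }
    if (any(exdf$start < genes$start[i] | exdf$end > genes$end[i]))
      stop("gene ", gid, ": exon outside gene span")
    cds_seq <- NULL
    prot <- NULL
    cds_anchor_pos <- NULL
    if (nrow(cdsdf) > 0L)
      cds_anchor_pos <- if (strand == "+") min(cdsdf$start) else max(cdsdf$end)
    if (!is.null(genome) && nrow(cdsdf) > 0L) {
      cdsdf <- cdsdf[order(cdsdf$start), , drop = FALSE]
      chrom <- genome[[genes$seqnames[i]]]
      if (is.null(chrom)) stop("gene ", gid, ": chromosome ", genes$seqnames[i],
                               " absent from genome")
      pieces <- substring(chrom, cdsdf$start, cdsdf$end)
      cds_seq <- paste(pieces, collapse = "")
      if (strand == "-") cds_seq <- revcomp(cds_seq)
      prot <- translate_cds(cds_seq)
    }
    out[[gid]] <- gene_model(gid, genes$seqnames[i], strand,
                             genes$start[i], genes$end[i],
                             cbind(exdf$start, exdf$end),
                             cds_seq = cds_seq, protein_seq = prot,
                             cds_start_genomic = cds_anchor_pos)
  }
  out
}

cds_anchor <- function(gene) {
  # Genomic coordinate of the first CDS base in transcript orientation.
  # Falls back to the transcript boundary when CDS coordinates are unknown;
  # the generator and read_gff3() place the CDS start at the gene boundary
  # for models without a 5' UTR.
  if (!is.null(gene$cds_start_genomic)) return(gene$cds_start_genomic)
  if (gene$strand == "+") gene$start else gene$end
}

#' Extract the promoter of a gene
#'
#' The promoter is the `length` bp immediately 5' of the first CDS base
#' (translation start), read on the coding strand. For a plus-strand gene
#' with CDS starting at genomic position `s` this is positions
#' `[s - length, s - 1]`; for a minus-strand gene ending at `e` it is the
#' reverse complement of `[e + 1, e + length]`. The window is truncated at
#' the chromosome boundary, so fewer than `length` bp may be returned. The
#' promoter never overlaps the CDS.
#'
#' @param genome A [genome_bundle()].
#' @param gene_id Gene identifier present in the bundle.
#' @param length Promoter length in bp (default 1500).
#' @return Nucleotide string (possibly shorter than `length`).
#' @export
extract_promoter <- function(genome, gene_id, length = 1500L) {
  if (length <= 0L) stop("promoter length must be > 0")
  gene <- genome$genes[[gene_id]]
  if (is.null(gene)) stop("unknown gene: ", gene_id)
  chrom <- genome$chromosomes[[gene$chromosome]]
  anchor <- cds_anchor(gene)
  if (gene$strand == "+") {
    from <- max(1L, anchor - length)
    to <- anchor - 1L
    if (to < from) return("")
    substring(chrom, from, to)
  } else {
    from <- anchor + 1L
    to <- min(nchar(chrom), anchor + length)
    if (to < from) return("")
    revcomp(substring(chrom, from, to))
  }
}

#' Extract the genomic span of a gene (coding strand orientation)
#'
#' @param genome A [genome_bundle()].
#' @param gene_id Gene identifier.
#' @return Nucleotide string of the gene span; reverse-complemented for
#'   minus-strand genes.
#' @export
extract_gene_span <- function(genome, gene_id) {
  gene <- genome$genes[[gene_id]]
  if (is.null(gene)) stop("unknown gene: ", gene_id)
  s <- substring(genome$chromosomes[[gene$chromosome]], gene$start, gene$end)
  if (gene$strand == "-") revcomp(s) else s
}
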