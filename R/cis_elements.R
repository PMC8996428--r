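# Promoter cis-regulatory element scanning against an IUPAC consensus
# catalog. The default catalog carries PlantCARE-style consensus strings
# for the elements commonly tabulated in plant gene-family surveys; the
# W-box entry (TTGACC/TTGACT) is the WRKY-binding consensus. Every entry
# can be overridden by supplying a custom catalog.

#' Build a cis-element catalog
#'
#' @param entries Named list: element name -> character vector of IUPAC
#'   consensus strings.
#' @param categories Named character vector: element name -> category
#'   (`"WRKY-binding"`, `"hormone"`, `"stress"`, `"development"`).
#' @return Object of class `cis_catalog`.
#' @export
cis_catalog <- function(entries, categories) {
  if (anyDuplicated(names(entries))) stop("duplicate element names in catalog")
  for (el in names(entries)) {
    for (pat in entries[[el]]) {
      bad <- setdiff(strsplit(toupper(pat), "")[[1]], names(IUPAC_NT))
      if (length(bad) > 0L)
        stop("malformed IUPAC consensus for ", el, ": ", pat)
    }
    entries[[el]] <- toupper(entries[[el]])
  }
  structure(list(entries = entries, categories = categories),
            class = "cis_catalog")
}

#' Default PlantCARE-style element catalog
#'
#' Consensus strings are implementation defaults in the PlantCARE style;
#' only the W-box consensus (T)TGAC(C/T) is a fixed literature anchor.
#'
#' @return A [cis_catalog()].
#' @export
default_cis_catalog <- function() {
  entries <- list(
    `W-box` = c("TTGACC", "TTGACT"),
    ABRE = "ACGTGGC",
    `TGA-element` = "AACGAC",
    `AuxRR-core` = "GGTCCAT",
    `CGTCA-motif` = "CGTCA",
    `TGACG-motif` = "TGACG",
    `TATC-box` = "TATCCCA",
    `GARE-motif` = "TCTGTTG",
    `P-box` = "CCTTTTG",
    `TCA-element` = "CCATCTTTTT",
    LTR = "CCGAAA",
    MBS = "CAACTG",
    `TC-rich repeats` = "ATTCTCTAAC",
    MYB = "CAACCA",
    MYC = "CANNTG",
    `DRE core` = "RCCGAC",
    ARE = "AAACCA",
    `GC-motif` = "CCCCCG",
    `MSA-like` = "TCCAACGGT",
    `RY-element` = "CATGCA",
    `CAT-box` = "GCCACT")
  categories <- c(
    `W-box` = "WRKY-binding",
    ABRE = "hormone", `TGA-element` = "hormone", `AuxRR-core` = "hormone",
    `CGTCA-motif` = "hormone", `TGACG-motif` = "hormone",
    `TATC-box` = "hormone", `GARE-motif` = "hormone", `P-box` = "hormone",
    `TCA-element` = "hormone",
    LTR = "stress", MBS = "stress", `TC-rich repeats` = "stress",
    MYB = "stress", MYC = "stress", `DRE core` = "stress", ARE = "stress",
    `GC-motif` = "stress",
    `MSA-like` = "development", `RY-element` = "development",
    `CAT-box` = "development")
  cis_catalog(entries, categories)
}

iupac_regex <- function(pattern) {
  # IUPAC semantics over A/C/G/T only: an N in the scanned sequence is not
  # inside any class, so it never matches.
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_NT[[ch]]
    if (length(opts) == 1L) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

match_positions <- function(sequence, pattern) {
  # all (overlapping) 1-based match start positions
  re <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(re, sequence, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Scan a promoter for cis-element occurrences
#'
#' Every position where a consensus matches is reported; overlapping
#' matches of the same element all count. With `both_strands = TRUE` the
#' reverse complement of each consensus is also scanned and reported with
#' strand `"-"` (offset still 1-based on the supplied sequence).
#'
#' @param promoter_seq Nucleotide string (A/C/G/T/N).
#' @param catalog A [cis_catalog()].
#' @param both_strands Scan the minus strand as well (default TRUE).
#' @param promoter_id Identifier recorded in the output.
#' @return data.frame: promoter_id, element, strand, offset; sorted by
#'   offset then element name.
#' @export
scan_elements <- function(promoter_seq, catalog, both_strands = TRUE,
                          promoter_id = "promoter") {
  stopifnot(inherits(catalog, "cis_catalog"))
  seq <- toupper(promoter_seq)
  rows <- list()
  for (el in names(catalog$entries)) {
    for (pat in catalog$entries[[el]]) {
      pos <- match_positions(seq, pat)
      if (length(pos) > 0L)
        rows[[length(rows) + 1L]] <- data.frame(
          promoter_id = promoter_id, element = el, strand = "+",
          offset = pos, stringsAsFactors = FALSE)
      if (both_strands) {
        rpat <- revcomp_iupac(pat)
        # a palindromic consensus matches both strands at the same offset;
        # report each strand once
        neg <- match_positions(seq, rpat)
        if (length(neg) > 0L)
          rows[[length(rows) + 1L]] <- data.frame(
            promoter_id = promoter_id, element = el, strand = "-",
            offset = neg, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(promoter_id = character(0), element = character(0),
                      strand = character(0), offset = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, out$element, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

revcomp_iupac <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(toupper(pattern), "")[[1]]]), collapse = "")
}

#' Gene x element count matrix with per-element coverage
#'
#' @param hits data.frame of [scan_elements()] rows over all promoters.
#' @param promoter_ids Character vector of all scanned promoter ids
#'   (promoters without hits yield zero rows).
#' @param catalog A [cis_catalog()].
#' @return List: `counts` (integer matrix, genes x elements) and
#'   `coverage` (named vector, fraction of genes with at least one hit per
#'   element).
#' @export
element_count_matrix <- function(hits, promoter_ids, catalog) {
  elements <- names(catalog$entries)
  counts <- matrix(0L, nrow = length(promoter_ids), ncol = length(elements),
                   dimnames = list(promoter_ids, elements))
  if (nrow(hits) > 0L) {
    tab <- table(factor(hits$promoter_id, levels = promoter_ids),
                 factor(hits$element, levels = elements))
    counts <- matrix(as.integer(tab), nrow = length(promoter_ids),
                     dimnames = list(promoter_ids, elements))
  }
  coverage <- colMeans(counts > 0L)
  list(counts = counts, coverage = coverage)
}
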