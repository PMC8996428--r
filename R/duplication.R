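# Duplicated-gene-pair detection and Nei-Gojobori (1986) Ka/Ks.
#
# Pairs are screened with a protein-guided global alignment (Needleman-
# Wunsch on the translations, BLOSUM62, gap open 10 / extend 0.5, back-
# translated to codons), then accepted when the alignment covers > 75% of
# the longer CDS with > 75% nucleotide identity. Accepted pairs are
# classified tandem vs segmental from the annotation, and Ka/Ks is
# estimated with the NG86 counting method under a Jukes-Cantor correction.

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

pairwise_global <- function(a, b, substitutionMatrix = "BLOSUM62",
                            gapOpening = 10, gapExtension = 0.5) {
  # Biostrings (< Bioc 3.19) vs pwalign (>= 3.19) both export pairwiseAlignment.
  fn <- if (requireNamespace("pwalign", quietly = TRUE))
    pwalign::pairwiseAlignment else Biostrings::pairwiseAlignment
  fn(Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
     substitutionMatrix = substitutionMatrix,
     gapOpening = gapOpening, gapExtension = gapExtension)
}

back_translate_alignment <- function(aligned_aa, codons) {
  # Expand an aligned (gapped) protein row to codon units.
  chars <- strsplit(aligned_aa, "")[[1]]
  out <- character(length(chars))
  j <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "-") {
      out[i] <- "---"
    } else {
      j <- j + 1L
      out[i] <- codons[j]
    }
  }
  paste(out, collapse = "")
}

#' Globally align two CDS sequences via their translations
#'
#' @param cds_a,cds_b CDS nucleotide strings, length divisible by 3,
#'   translatable without internal stops (a terminal stop codon is trimmed
#'   before alignment).
#' @param gap_opening,gap_extension Gap penalties for the protein-level
#'   Needleman-Wunsch (BLOSUM62).
#' @return List of class `codon_alignment`: `aln_a`, `aln_b` (gapped codon
#'   alignments, gaps in whole-codon units), `coverage` (aligned non-gap
#'   codon length / length of the longer CDS) and `identity` (identical
#'   nucleotides / aligned non-gap nucleotide columns).
#' @export
align_cds_pair <- function(cds_a, cds_b, gap_opening = 10, gap_extension = 0.5) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  prot_a <- translate_cds(cds_a)
  prot_b <- translate_cds(cds_b)
  cod_a <- split_codons(cds_a)
  cod_b <- split_codons(cds_b)
  if (cod_a[length(cod_a)] %in% STOP_CODONS) cod_a <- cod_a[-length(cod_a)]
  if (cod_b[length(cod_b)] %in% STOP_CODONS) cod_b <- cod_b[-length(cod_b)]
  pa <- pairwise_global(prot_a, prot_b,
                        gapOpening = gap_opening, gapExtension = gap_extension)
  row_a <- as.character(Biostrings::alignedPattern(pa))
  row_b <- as.character(Biostrings::alignedSubject(pa))
  aln_a <- back_translate_alignment(row_a, cod_a)
  aln_b <- back_translate_alignment(row_b, cod_b)
  ca <- strsplit(aln_a, "")[[1]]
  cb <- strsplit(aln_b, "")[[1]]
  nongap <- ca != "-" & cb != "-"
  n_aln_nt <- sum(nongap)
  coverage <- n_aln_nt / max(nchar(cds_a), nchar(cds_b))
  identity <- if (n_aln_nt == 0L) 0 else sum(ca[nongap] == cb[nongap]) / n_aln_nt
  structure(list(aln_a = aln_a, aln_b = aln_b,
                 coverage = coverage, identity = identity),
            class = "codon_alignment")
}

#' Duplication criterion on coverage and identity
#'
#' Both thresholds are strict: the aligned region must cover more than
#' `cov_min` of the longer gene and exceed `id_min` nucleotide identity.
#'
#' @param coverage,identity Fractions in `[0, 1]`.
#' @param cov_min,id_min Strict thresholds (defaults 0.75).
#' @return TRUE iff `coverage > cov_min` and `identity > id_min`.
#' @export
is_duplicated_pair <- function(coverage, identity, cov_min = 0.75, id_min = 0.75) {
  coverage > cov_min & identity > id_min
}

#' Classify a duplicated pair as tandem or segmental
#'
#' Tandem iff the two genes lie on the same chromosome and either at most
#' `max_intervening` annotated genes sit between them or their midpoints
#' are within `max_distance` bp; segmental otherwise.
#'
#' @param gene_a,gene_b Gene ids.
#' @param genes List of [gene_model()] objects (the annotation context).
#' @param max_intervening Maximum intervening gene count for tandem.
#' @param max_distance Maximum midpoint distance (bp) for tandem.
#' @return `"tandem"` or `"segmental"`.
#' @export
classify_duplication <- function(gene_a, gene_b, genes,
                                 max_intervening = 5L, max_distance = 2e5) {
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  ga <- genes[[gene_a]]; gb <- genes[[gene_b]]
  if (is.null(ga) || is.null(gb))
    stop("unknown gene id: ", if (is.null(ga)) gene_a else gene_b)
  if (ga$chromosome != gb$chromosome) return("segmental")
  mid_a <- (ga$start + ga$end) / 2
  mid_b <- (gb$start + gb$end) / 2
  lo <- min(ga$start, gb$start); hi <- max(ga$end, gb$end)
  same_chr <- vapply(genes, function(g) g$chromosome == ga$chromosome, logical(1))
  between <- vapply(genes[same_chr], function(g)
    g$gene_id != gene_a && g$gene_id != gene_b && g$start > lo && g$end < hi,
    logical(1))
  if (sum(between) <= max_intervening || abs(mid_a - mid_b) <= max_distance)
    "tandem" else "segmental"
}

codon_syn_sites <- function(codon) {
  # Fraction of possible single-nucleotide changes that are synonymous, per
  # position, with changes to stop codons excluded from the denominator.
  aa <- GENETIC_CODE_STD[[codon]]
  nt <- c("T", "C", "A", "G")
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (alt in setdiff(nt, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (mut %in% STOP_CODONS) next
      valid <- valid + 1L
      if (GENETIC_CODE_STD[[mut]] == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  s
}

SYN_SITES_TABLE <- local({
  # memoised per-codon synonymous site counts for the 61 sense codons
  codons <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
  stats::setNames(vapply(codons, codon_syn_sites, numeric(1)), codons)
})

codon_pair_diffs <- function(ca, cb) {
  # Average synonymous/nonsynonymous difference counts over all minimal
  # substitution pathways between two codons; pathways through stop codons
  # are excluded (all-pathway fallback if every pathway is blocked).
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else if (k == 2L)
    list(pos, pos[2:1]) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  walk <- function(order_, allow_stop) {
    cur <- ca; sd <- 0; nd <- 0
    for (p in order_) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (!allow_stop && nxt %in% STOP_CODONS) return(NULL)
      if (GENETIC_CODE_STD[[cur]] == GENETIC_CODE_STD[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(perms, walk, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

#' NG86 synonymous and nonsynonymous substitution rates
#'
#' Classic Nei-Gojobori (1986) counting: per-codon synonymous site counts
#' (stop-codon changes excluded from the denominator), S averaged over the
#' two sequences, N = 3*codons - S; per-codon-pair differences partitioned
#' by equal-weight averaging over all minimal substitution pathways that
#' avoid stop codons; proportions corrected with Jukes-Cantor
#' `d = -(3/4) ln(1 - (4/3) p)`.
#'
#' @param alignment A `codon_alignment` from [align_cds_pair()], or a list
#'   with gapped codon strings `aln_a`, `aln_b`. Gap codons are removed
#'   before counting; neither ungapped sequence may contain a stop codon.
#' @return List: `ka`, `ks` (NA when the correction is undefined, i.e.
#'   p >= 3/4), `ratio` (NA when ks is 0 or either rate undefined), plus
#'   the counts `S`, `N`, `Sd`, `Nd`.
#' @export
ng86 <- function(alignment) {
  cod_a <- split_codons(alignment$aln_a)
  cod_b <- split_codons(alignment$aln_b)
  if (length(cod_a) != length(cod_b)) stop("aligned codon rows differ in length")
  keep <- cod_a != "---" & cod_b != "---"
  cod_a <- cod_a[keep]; cod_b <- cod_b[keep]
  if (length(cod_a) == 0L) stop("empty codon alignment")
  if (any(cod_a %in% STOP_CODONS) || any(cod_b %in% STOP_CODONS))
    stop("stop codon inside aligned CDS")
  s_a <- sum(SYN_SITES_TABLE[cod_a])
  s_b <- sum(SYN_SITES_TABLE[cod_b])
  S <- (s_a + s_b) / 2
  N <- 3 * length(cod_a) - S
  diffs <- mapply(codon_pair_diffs, cod_a, cod_b)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  if (S == 0 && Sd > 0) stop("synonymous differences with zero synonymous sites")
  ps <- if (S == 0) 0 else Sd / S
  pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps)
  ka <- jc(pn)
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  list(ka = ka, ks = ks, ratio = ratio, S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Selection-pressure call from Ka and Ks
#'
#' @param ka,ks Substitution rates per site (NA = undefined).
#' @return `"positive"` (ka/ks > 1), `"purifying"` (< 1), `"neutral"`
#'   (= 1), or `"undefined"` when ks is 0 or either rate is undefined.
#' @export
selection_call <- function(ka, ks) {
  if (is.na(ka) || is.na(ks) || ks == 0) return("undefined")
  r <- ka / ks
  if (r > 1) "positive" else if (r < 1) "purifying" else "neutral"
}

#' All-vs-all duplicated-pair detection
#'
#' Aligns every CDS pair, applies the coverage/identity criterion, then
#' classifies accepted pairs and computes NG86 Ka/Ks and selection calls.
#'
#' @param cds Named character vector of CDS sequences.
#' @param genes List of [gene_model()] objects (for tandem/segmental
#'   classification); pass NULL to skip classification.
#' @param cov_min,id_min Duplication thresholds (strict).
#' @param max_intervening,max_distance Tandem definition, see
#'   [classify_duplication()].
#' @return data.frame: gene_a, gene_b, coverage, identity, kind, ka, ks,
#'   ratio, selection. Zero rows when no pair passes.
#' @export
find_duplications <- function(cds, genes = NULL, cov_min = 0.75, id_min = 0.75,
                              max_intervening = 5L, max_distance = 2e5,
                              min_score = 0) {
  ids <- names(cds)
  n <- length(ids)
  rows <- list()
  if (n >= 2L) {
    prots <- vapply(cds, translate_cds, character(1))
    lens <- nchar(cds)
    fn <- if (requireNamespace("pwalign", quietly = TRUE))
      pwalign::pairwiseAlignment else Biostrings::pairwiseAlignment
    for (i in seq_len(n - 1L)) {
      js <- seq(i + 1L, n)
      # length-ratio screen: the ratio bounds the attainable coverage
      js <- js[pmin(lens[i], lens[js]) / pmax(lens[i], lens[js]) > cov_min]
      if (length(js) == 0L) next
      # vectorized protein-score prescreen: unrelated proteins score far
      # below zero under global BLOSUM62 alignment, near-identical
      # duplicates far above; the full codon alignment then decides
      scores <- fn(Biostrings::AAStringSet(prots[js]),
                   Biostrings::AAString(prots[[i]]), type = "global",
                   substitutionMatrix = "BLOSUM62",
                   gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
      js <- js[scores > min_score]
      for (j in js) {
        aln <- align_cds_pair(cds[[i]], cds[[j]])
        if (!is_duplicated_pair(aln$coverage, aln$identity, cov_min, id_min)) next
        rates <- ng86(aln)
        kind <- if (is.null(genes)) NA_character_ else
          classify_duplication(ids[i], ids[j], genes,
                               max_intervening, max_distance)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = ids[i], gene_b = ids[j],
          coverage = aln$coverage, identity = aln$identity, kind = kind,
          ka = rates$ka, ks = rates$ks, ratio = rates$ratio,
          selection = selection_call(rates$ka, rates$ks),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      coverage = numeric(0), identity = numeric(0),
                      kind = character(0), ka = numeric(0), ks = numeric(0),
                      ratio = numeric(0), selection = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
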