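# MISA-equivalent perfect microsatellite (SSR) mining.
#
# Maximal perfect tandem repeats of unit length 1-6 are located with a
# shift-comparison run-length scan; the per-unit-length minimum repeat
# counts default to the MISA thresholds (10, 6, 5, 5, 5, 5). A run
# reportable under several unit lengths is reported once, at the smallest
# unit (enforced through unit primitivity). N never matches anything, so
# it can neither start nor extend a repeat.

MISA_THRESHOLDS <- c(10L, 6L, 5L, 5L, 5L, 5L)

is_primitive_unit <- function(unit) {
  k <- nchar(unit)
  if (k == 1L) return(TRUE)
  for (d in seq_len(k - 1L)) {
    if (k %% d != 0L) next
    if (strrep(substr(unit, 1L, d), k / d) == unit) return(FALSE)
  }
  TRUE
}

#' Find perfect SSRs in a nucleotide sequence
#'
#' @param sequence Nucleotide string (A/C/G/T/N).
#' @param thresholds Minimum repeat counts for unit lengths 1..6
#'   (default MISA: 10, 6, 5, 5, 5, 5).
#' @param seq_id Identifier recorded in the output.
#' @return data.frame: seq_id, motif (repeat unit as found), repeat_count,
#'   start, end (1-based inclusive; `end - start + 1 ==
#'   nchar(motif) * repeat_count`), ssr_type (`"p1"`..`"p6"`), sorted by
#'   start. Zero rows when nothing passes.
#' @export
find_ssrs <- function(sequence, thresholds = MISA_THRESHOLDS, seq_id = "seq") {
  empty <- data.frame(seq_id = character(0), motif = character(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0), ssr_type = character(0),
                      stringsAsFactors = FALSE)
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  acgt <- s %in% c("A", "C", "G", "T")
  rows <- list()
  for (k in 1:6) {
    if (n < k * thresholds[k]) next
    m <- s[seq_len(n - k)] == s[seq_len(n - k) + k] &
      acgt[seq_len(n - k)] & acgt[seq_len(n - k) + k]
    r <- rle(m)
    ends_at <- cumsum(r$lengths)
    starts_at <- ends_at - r$lengths + 1L
    for (i in which(r$values)) {
      run_len <- r$lengths[i]                  # matched shifted positions
      region_len <- run_len + k                # periodic region, maybe partial unit
      count <- region_len %/% k
      if (count < thresholds[k]) next
      start <- starts_at[i]
      unit <- paste(s[start:(start + k - 1L)], collapse = "")
      if (!is_primitive_unit(unit)) next       # reported at a smaller unit
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = seq_id, motif = unit, repeat_count = count,
        start = start, end = start + count * k - 1L,
        ssr_type = paste0("p", k), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

#' Merge nearby SSRs into compound records
#'
#' Two simple SSRs on the same sequence separated by at most
#' `max_interruption` bp are merged into one compound record spanning both;
#' chains merge transitively.
#'
#' @param records data.frame from [find_ssrs()].
#' @param max_interruption Maximum gap (bp) between merged members.
#' @return data.frame with the same columns; merged rows carry
#'   `ssr_type = "compound"`, a `motif` of the form `(AG)6+(CT)6`, the
#'   summed `repeat_count`, and the overall span.
#' @export
merge_compound <- function(records, max_interruption = 100L) {
  if (nrow(records) < 2L) return(records)
  out <- list()
  for (id in unique(records$seq_id)) {
    rec <- records[records$seq_id == id, , drop = FALSE]
    rec <- rec[order(rec$start), , drop = FALSE]
    gap <- rec$start[-1L] - rec$end[-nrow(rec)] - 1L
    grp <- cumsum(c(0L, as.integer(gap > max_interruption)))
    for (g in unique(grp)) {
      part <- rec[grp == g, , drop = FALSE]
      if (nrow(part) == 1L) {
        out[[length(out) + 1L]] <- part
      } else {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = id,
          motif = paste(sprintf("(%s)%d", part$motif, part$repeat_count),
                        collapse = "+"),
          repeat_count = sum(part$repeat_count),
          start = min(part$start), end = max(part$end),
          ssr_type = "compound", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Family-level SSR census
#'
#' @param records data.frame of simple SSR records (pre-merge).
#' @param n_genes Number of genes scanned.
#' @return List: `n_ssrs`, `n_genes_with_ssr`, and `class_pct`, the percent
#'   of simple SSRs per unit-length class (p1..p6, 1 decimal, half-up).
#' @export
ssr_census <- function(records, n_genes) {
  classes <- paste0("p", 1:6)
  simple <- records[records$ssr_type %in% classes, , drop = FALSE]
  n <- nrow(simple)
  counts <- table(factor(simple$ssr_type, levels = classes))
  pct <- if (n == 0) stats::setNames(rep(0, 6L), classes) else
    stats::setNames(round_half_up(100 * as.numeric(counts) / n, 1L), classes)
  list(n_ssrs = n,
       n_genes_with_ssr = length(unique(simple$seq_id)),
       n_genes = n_genes,
       class_pct = pct)
}
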