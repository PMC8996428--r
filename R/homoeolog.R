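# Homoeologous-group assembly over the A/B/D subgenomes of hexaploid wheat
# and the triad/duplication/loss retention-ratio classification.

#' Parse a wheat-style chromosome name into group and subgenome
#'
#' @param chromosome_name Name matching digit+letter, e.g. `"2B"` (an
#'   optional leading "chr" prefix is tolerated).
#' @param pattern Regex with two capture groups (group digit, subgenome).
#' @return List with `group` (integer 1-7) and `subgenome` ("A"/"B"/"D").
#' @export
parse_subgenome <- function(chromosome_name,
                            pattern = "^(?:chr)?([1-7])([ABD])$") {
  m <- regmatches(chromosome_name, regexec(pattern, chromosome_name))[[1]]
  if (length(m) != 3L)
    stop("unparseable chromosome name: ", chromosome_name)
  list(group = as.integer(m[2L]), subgenome = m[3L])
}

#' Classify a homoeolog-group retention ratio
#'
#' Category from the per-subgenome member counts `(nA, nB, nD)`:
#' `TRIAD_1_1_1` for (1,1,1); `DUP_n_1_1` when exactly one count exceeds 1
#' and the others equal 1; `LOSS_1_1_0` when exactly one count is 0 and the
#' others equal 1; `ORPHAN` for a single gene; `OTHER` otherwise. The rule
#' is symmetric in the three subgenomes.
#'
#' @param nA,nB,nD Non-negative member counts, not all zero.
#' @return Category string.
#' @export
classify_ratio <- function(nA, nB, nD) {
  n <- c(nA, nB, nD)
  if (any(n < 0) || any(n != floor(n))) stop("counts must be non-negative integers")
  if (sum(n) == 0) stop("all-zero homoeolog counts")
  if (all(n == 1)) return("TRIAD_1_1_1")
  if (sum(n > 1) == 1 && sum(n == 1) == 2) return("DUP_n_1_1")
  if (sum(n == 0) == 1 && sum(n == 1) == 2) return("LOSS_1_1_0")
  if (sum(n) == 1) return("ORPHAN")
  "OTHER"
}

RATIO_CATEGORIES <- c("TRIAD_1_1_1", "DUP_n_1_1", "LOSS_1_1_0", "OTHER", "ORPHAN")

#' Build homoeolog groups from a membership list
#'
#' @param groups Named list: group id -> character vector of member gene ids.
#' @param gene_chromosomes Named character vector: gene id -> chromosome name.
#' @return data.frame: group_id, members (semicolon-joined), nA, nB, nD,
#'   category.
#' @export
build_homoeolog_groups <- function(groups, gene_chromosomes) {
  rows <- lapply(names(groups), function(gid) {
    members <- groups[[gid]]
    sg <- vapply(members, function(m) {
      chr <- gene_chromosomes[[m]]
      if (is.null(chr) || is.na(chr)) stop("gene without chromosome: ", m)
      parse_subgenome(chr)$subgenome
    }, character(1))
    n <- c(A = sum(sg == "A"), B = sum(sg == "B"), D = sum(sg == "D"))
    data.frame(group_id = gid, members = paste(members, collapse = ";"),
               nA = n[["A"]], nB = n[["B"]], nD = n[["D"]],
               category = classify_ratio(n[["A"]], n[["B"]], n[["D"]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Genome-wide reference percentages per retention category (IWGSC 2018),
# used as the comparison column of the triad summary.
WHEAT_REFERENCE_PERCENTS <- c(
  TRIAD_1_1_1 = 35.8, DUP_n_1_1 = 5.7, LOSS_1_1_0 = 13.2,
  OTHER = 8.0, ORPHAN = 37.1)

#' Summarize homoeolog groups by retention category
#'
#' @param groups data.frame from [build_homoeolog_groups()] (columns
#'   group_id, nA, nB, nD, category).
#' @param reference_percents Named vector of genome-wide reference
#'   percentages per category (default: all-wheat values).
#' @return data.frame, one row per category plus a Total row: category,
#'   reference_pct, n_groups, n_genes, pct_genes (percent of all genes, 1
#'   decimal, half-up rounding).
#' @export
summarize_triads <- function(groups, reference_percents = WHEAT_REFERENCE_PERCENTS) {
  ngen <- groups$nA + groups$nB + groups$nD
  total <- sum(ngen)
  rows <- lapply(RATIO_CATEGORIES, function(cat) {
    sel <- groups$category == cat
    data.frame(category = cat,
               reference_pct = unname(reference_percents[cat]),
               n_groups = sum(sel), n_genes = sum(ngen[sel]),
               pct_genes = if (total == 0) 0 else
                 round_half_up(100 * sum(ngen[sel]) / total, 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(category = "Total",
                        reference_pct = sum(out$reference_pct),
                        n_groups = sum(out$n_groups),
                        n_genes = sum(out$n_genes),
                        pct_genes = sum(out$pct_genes),
                        stringsAsFactors = FALSE))
}
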