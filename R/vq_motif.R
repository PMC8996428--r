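# VQ-domain identification by deterministic decamer scanning.
#
# The family-defining motif is the decamer FxxhVQxhTG (x any residue, h
# hydrophobic); natural variants swap the VQ core for VH or end in a
# non-TG terminus (the VMA type). Positions are checked literally, so the
# scan is exact and reproducible -- no profile scoring is involved.

#' Scan a protein for VQ-motif decamers
#'
#' Reports every 10-residue window matching `F,x,x,x,V,[QH],x,h,T,G`
#' (canonical), plus windows matching the stricter 8-position prefix
#' `F,x,x,x,V,[QH],x,h` whose positions 9-10 are not `TG` (non-canonical;
#' this is how VMA-type termini are captured). `h` is drawn from
#' `hydrophobic_set`; `X` in the sequence never satisfies a constrained
#' position. Hits are sorted by offset.
#'
#' @param protein_seq Amino-acid string (20-letter alphabet; `X` tolerated).
#' @param hydrophobic_set Residues accepted at the hydrophobic positions.
#' @return data.frame with columns `offset` (0-based index of the motif F),
#'   `decamer`, `core` ("VQ"/"VH"), `variant` (residues 8-10 of the window)
#'   and `canonical` (TRUE iff positions 9-10 are TG). Zero rows when there
#'   is no hit.
#' @export
scan_vq <- function(protein_seq, hydrophobic_set = HYDROPHOBIC_DEFAULT) {
  empty <- data.frame(offset = integer(0), decamer = character(0),
                      core = character(0), variant = character(0),
                      canonical = logical(0), stringsAsFactors = FALSE)
  n <- nchar(protein_seq)
  if (n < 10L) return(empty)
  s <- strsplit(toupper(protein_seq), "")[[1]]
  starts <- which(s == "F")
  starts <- starts[starts <= n - 9L]
  if (length(starts) == 0L) return(empty)
  ok8 <- s[starts + 4L] == "V" &
    s[starts + 5L] %in% c("Q", "H") &
    s[starts + 7L] %in% hydrophobic_set
  starts <- starts[ok8]
  if (length(starts) == 0L) return(empty)
  canonical <- s[starts + 8L] == "T" & s[starts + 9L] == "G"
  decamer <- substring(protein_seq, starts, starts + 9L)
  data.frame(offset = starts - 1L,
             decamer = decamer,
             core = paste0("V", s[starts + 5L]),
             variant = substring(decamer, 8L, 10L),
             canonical = canonical,
             stringsAsFactors = FALSE)
}

#' Classify a set of proteins as VQ-family members
#'
#' @param hits_by_gene Named list of [scan_vq()] results, one per gene.
#' @return List with `verdicts` (data.frame: gene_id, is_vq, best offset /
#'   decamer / core / variant / canonical of the best hit) and
#'   `variant_census` (named integer vector counting hits per variant label
#'   across the family). The best hit of a gene is its first canonical hit,
#'   or its first hit when none is canonical.
#' @export
classify_family <- function(hits_by_gene) {
  rows <- lapply(names(hits_by_gene), function(g) {
    h <- hits_by_gene[[g]]
    if (nrow(h) == 0L)
      return(data.frame(gene_id = g, is_vq = FALSE, offset = NA_integer_,
                        decamer = NA_character_, core = NA_character_,
                        variant = NA_character_, canonical = NA,
                        stringsAsFactors = FALSE))
    best <- if (any(h$canonical)) h[which(h$canonical)[1L], ] else h[1L, ]
    data.frame(gene_id = g, is_vq = TRUE, offset = best$offset,
               decamer = best$decamer, core = best$core,
               variant = best$variant, canonical = best$canonical,
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)
  all_hits <- do.call(rbind, hits_by_gene)
  census <- if (is.null(all_hits) || nrow(all_hits) == 0L) integer(0) else
    table(all_hits$variant)
  list(verdicts = verdicts,
       variant_census = stats::setNames(as.integer(census), names(census)))
}

#' Assign family names from chromosome location and homoeolog grouping
#'
#' Groups are numbered 1..G by (chromosome group number, then minimum gene
#' start coordinate among members, with subgenome alphabetical order as the
#' final tie-break); each member is named
#' `<prefix><groupNumber>-<chromosome>`, and when two or more inparalogs of
#' a group lie on the same chromosome they receive suffixes 1, 2, ... in
#' coordinate order (e.g. `TaVQ6-2B1`, `TaVQ6-2B2`).
#'
#' @param genes List of [gene_model()] objects (named by gene id).
#' @param groups Named list: group id -> character vector of member gene ids.
#'   Every gene must belong to exactly one group.
#' @param prefix Name prefix, e.g. `"TaVQ"`.
#' @return Named character vector: gene id -> family name.
#' @export
assign_family_names <- function(genes, groups, prefix = "VQ") {
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  names(genes) <- ids
  membership <- unlist(lapply(names(groups), function(g)
    stats::setNames(rep(g, length(groups[[g]])), groups[[g]])))
  if (anyDuplicated(names(membership)))
    stop("gene(s) in more than one group: ",
         paste(unique(names(membership)[duplicated(names(membership))]), collapse = ", "))
  missing <- setdiff(ids, names(membership))
  if (length(missing) > 0L)
    stop("gene(s) in no group: ", paste(missing, collapse = ", "))
  keyed <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    parsed <- lapply(members, function(m) parse_subgenome(genes[[m]]$chromosome))
    cg <- vapply(parsed, `[[`, numeric(1), "group")
    sg <- vapply(parsed, `[[`, character(1), "subgenome")
    st <- vapply(members, function(m) genes[[m]]$start, numeric(1))
    list(id = g, min_cg = min(cg), min_start = min(st),
         min_sg = min(sg), members = members, sg = sg, start = st)
  })
  ord <- order(vapply(keyed, `[[`, numeric(1), "min_cg"),
               vapply(keyed, `[[`, numeric(1), "min_start"),
               vapply(keyed, `[[`, character(1), "min_sg"))
  out <- character(0)
  for (k in seq_along(ord)) {
    gk <- keyed[[ord[k]]]
    chroms <- vapply(gk$members, function(m) genes[[m]]$chromosome, character(1))
    for (chr in unique(chroms)) {
      on_chr <- gk$members[chroms == chr]
      on_chr <- on_chr[order(gk$start[chroms == chr])]
      if (length(on_chr) == 1L) {
        out[on_chr] <- paste0(prefix, k, "-", chr)
      } else {
        out[on_chr] <- paste0(prefix, k, "-", chr, seq_along(on_chr))
      }
    }
  }
  out[ids]
}
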