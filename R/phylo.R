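# Distance-based phylogeny: p-distance matrix, an authored Saitou-Nei
# neighbor-joining implementation with deterministic tie-breaking,
# column-bootstrap support, and reference-guided subgroup assignment.
# Trees are returned as ape "phylo" objects; ape handles Newick I/O.

#' Pairwise p-distance matrix from an alignment
#'
#' `d(i,j)` = mismatches / compared columns, where columns with a gap
#' (`-`) or `X` in either row are skipped (pairwise deletion).
#'
#' @param aligned Named character vector of equal-length aligned sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(aligned) {
  n <- length(aligned)
  if (n < 2L) stop("need at least 2 sequences")
  L <- unique(nchar(aligned))
  if (length(L) != 1L) stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  ok <- mat != "-" & mat != "X"
  d <- matrix(0, n, n, dimnames = list(names(aligned), names(aligned)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp))
        stop("no comparable columns between ", names(aligned)[i], " and ",
             names(aligned)[j])
      d[i, j] <- d[j, i] <- sum(mat[i, comp] != mat[j, comp]) / sum(comp)
    }
  }
  d
}

#' Poisson-corrected protein distance
#'
#' `d = -ln(1 - p)` applied to the p-distance (undefined for p >= 1).
#'
#' @inheritParams p_distance
#' @return Symmetric numeric matrix.
#' @export
poisson_distance <- function(aligned) {
  p <- p_distance(aligned)
  if (any(p >= 1)) stop("p-distance of 1: Poisson correction undefined")
  -log(1 - p)
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Iteratively joins the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch
#' lengths from the standard rate-corrected formulas. Q ties are broken by
#' the lexicographically smallest taxa-name pair (each cluster is keyed by
#' its smallest member leaf). Negative branch-length estimates are clamped
#' to zero and flagged in the returned tree's `negative_clamped` attribute.
#'
#' @param dm Symmetric distance matrix with row/col names (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  taxa <- rownames(dm)
  n <- length(taxa)
  if (is.null(taxa) || n < 3L) stop("need a named distance matrix with >= 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12)))
    stop("distance matrix must be symmetric")
  d <- dm
  n_leaf <- n
  # node numbering: leaves 1..n, internal nodes n+1 .. 2n-2 (ape convention)
  active_node <- seq_len(n)          # tree-node id per active cluster
  active_key <- taxa                 # lexicographic representative per cluster
  edge <- matrix(0L, 0L, 2L)
  edge_len <- numeric(0)
  next_internal <- n_leaf + 2L       # reserve n+1 for the final root node
  clamped <- FALSE
  add_edge <- function(parent, child, len) {
    edge <<- rbind(edge, c(parent, child))
    if (len < -1e-12) clamped <<- TRUE
    edge_len <<- c(edge_len, max(0, len))
  }
  while (nrow(d) > 3L) {
    m <- nrow(d)
    rs <- rowSums(d)
    q <- (m - 2) * d - outer(rs, rs, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- apply(cand, 1L, function(ij) {
      p <- sort(c(active_key[ij[1L]], active_key[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    new_node <- next_internal
    next_internal <- next_internal + 1L
    add_edge(new_node, active_node[i], vi)
    add_edge(new_node, active_node[j], vj)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    dnew <- dnew[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, dnew), c(dnew, 0))
    key_new <- min(active_key[i], active_key[j])
    active_node <- c(active_node[-c(i, j)], new_node)
    active_key <- c(active_key[-c(i, j)], key_new)
    rn <- c(rownames(d)[seq_len(nrow(d) - 1L)], key_new)
    dimnames(d) <- list(rn, rn)
  }
  # final three clusters join at the root (degree-3 internal node n+1)
  root <- n_leaf + 1L
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  add_edge(root, active_node[1L], v1)
  add_edge(root, active_node[2L], v2)
  add_edge(root, active_node[3L], v3)
  tree <- structure(list(edge = edge, edge.length = edge_len,
                         tip.label = taxa, Nnode = max(edge) - n_leaf),
                    class = "phylo", order = NULL)
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "negative_clamped") <- clamped
  tree
}

#' Bootstrap support for NJ tree bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicates containing the same bipartition.
#'
#' @param aligned Named character vector of equal-length aligned sequences.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the column resampling.
#' @param distance `"p"` (default) or `"poisson"`.
#' @return List: `tree` (NJ tree from the full alignment), `node_support`
#'   (percentage per internal node, ordered as `ape::prop.clades`, NA for
#'   the root node of the unrooted representation), and `degenerate` (TRUE
#'   when the alignment carries no variable columns, making supports
#'   meaningless).
#' @export
bootstrap_support <- function(aligned, replicates = 1000L, seed = 1L,
                              distance = c("p", "poisson")) {
  distance <- match.arg(distance)
  dfun <- if (distance == "p") p_distance else poisson_distance
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  rownames(mat) <- names(aligned)
  tree <- neighbor_joining(dfun(aligned))
  variable <- any(apply(mat, 2L, function(col) {
    col <- col[col != "-" & col != "X"]
    length(unique(col)) > 1L
  }))
  boots <- local({
    set.seed(seed)
    lapply(seq_len(replicates), function(r) {
      idx <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      res <- mat[, idx, drop = FALSE]
      rows <- apply(res, 1L, paste, collapse = "")
      neighbor_joining(dfun(stats::setNames(rows, rownames(mat))))
    })
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  list(tree = tree, node_support = 100 * counts / replicates,
       degenerate = !variable)
}

#' Assign subgroup labels from labeled reference leaves
#'
#' Each unlabeled leaf receives the label of the smallest clade (over all
#' rootings of the unrooted tree) that contains it together with at least
#' one labeled leaf, provided all labeled leaves in that clade carry the
#' same label; disagreement yields `"UNASSIGNED"`.
#'
#' @param tree An `ape::phylo` tree.
#' @param labeled_leaves Named character vector: reference leaf name ->
#'   subgroup label.
#' @return Named character vector: unlabeled leaf -> label or
#'   `"UNASSIGNED"`.
#' @export
assign_subgroups <- function(tree, labeled_leaves) {
  tips <- tree$tip.label
  refs <- intersect(names(labeled_leaves), tips)
  if (length(refs) == 0L) stop("no labeled reference leaves in tree")
  queries <- setdiff(tips, refs)
  bip <- ape::prop.part(tree)     # clades as tip-index sets, arbitrary rooting
  tipsets <- lapply(bip, function(idx) tips[idx])
  # complement sides are clades under other rootings
  all_clades <- unique(c(tipsets, lapply(tipsets, function(x) setdiff(tips, x)),
                         lapply(tips, identity)))
  out <- stats::setNames(rep("UNASSIGNED", length(queries)), queries)
  for (q in queries) {
    containing <- Filter(function(cl) q %in% cl &&
                           length(intersect(cl, refs)) > 0L, all_clades)
    if (length(containing) == 0L) next
    sizes <- vapply(containing, length, integer(1))
    best <- containing[sizes == min(sizes)]
    labels <- unique(unlist(lapply(best, function(cl)
      labeled_leaves[intersect(cl, refs)])))
    if (length(labels) == 1L) out[q] <- labels
  }
  out
}

#' Fixture-grade center-star multiple alignment
#'
#' Aligns every sequence to the longest one with pairwise global alignment
#' (BLOSUM62) and merges the pairwise gap patterns. Intended for building
#' small test fixtures, not as a substitute for a real MSA program.
#'
#' @param seqs Named character vector of protein sequences.
#' @return Named character vector of equal-length aligned sequences.
#' @export
align_center_star <- function(seqs) {
  if (length(seqs) < 2L) return(seqs)
  center_i <- which.max(nchar(seqs))
  center <- seqs[[center_i]]
  others <- seqs[-center_i]
  pats <- lapply(others, function(s) {
    pa <- pairwise_global(center, s)
    list(c = strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]],
         s = strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]])
  })
  # per inter-residue slot of the center, the max number of inserted columns
  nslots <- nchar(center) + 1L
  ins <- integer(nslots)
  for (p in pats) {
    slot <- 1L; run <- 0L
    for (ch in p$c) {
      if (ch == "-") run <- run + 1L
      else { ins[slot] <- max(ins[slot], run); run <- 0L; slot <- slot + 1L }
    }
    ins[nslots] <- max(ins[nslots], run)
  }
  pad_row <- function(crow, srow) {
    out <- character(0); slot <- 1L; run_c <- character(0); run_s <- character(0)
    flush <- function(out, run_s, slot)
      c(out, run_s, rep("-", ins[slot] - length(run_s)))
    for (i in seq_along(crow)) {
      if (crow[i] == "-") { run_s <- c(run_s, srow[i]) }
      else {
        out <- flush(out, run_s, slot); run_s <- character(0)
        slot <- slot + 1L
        out <- c(out, srow[i])
      }
    }
    out <- flush(out, run_s, slot)
    paste(out, collapse = "")
  }
  center_chars <- strsplit(center, "")[[1]]
  aligned <- stats::setNames(vector("list", length(seqs)), names(seqs))
  aligned[[center_i]] <- pad_row(center_chars, center_chars)
  for (k in seq_along(others))
    aligned[[names(others)[k]]] <- pad_row(pats[[k]]$c, pats[[k]]$s)
  unlist(aligned)
}
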