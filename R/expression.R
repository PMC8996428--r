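# RNA-seq TPM summarization and qRT-PCR relative quantification (2^-ddCt).

#' Average a TPM matrix over homoeolog groups
#'
#' @param matrix Numeric matrix, genes x tissues (non-negative TPM).
#' @param groups Named list: group id -> character vector of member gene
#'   ids (all present as matrix rows; empty groups are an error).
#' @return Numeric matrix, groups x tissues, arithmetic member mean per
#'   column.
#' @export
average_homoeologs <- function(matrix, groups) {
  if (any(lengths(groups) == 0L)) stop("empty homoeolog group")
  missing <- setdiff(unlist(groups), rownames(matrix))
  if (length(missing) > 0L)
    stop("group member(s) absent from matrix: ", paste(missing, collapse = ", "))
  out <- t(vapply(groups, function(members)
    colMeans(matrix[members, , drop = FALSE]), numeric(ncol(matrix))))
  dimnames(out) <- list(names(groups), colnames(matrix))
  out
}

#' Expression flags at a TPM threshold
#'
#' A value counts as expressed when `tpm >= threshold` (the survey
#' convention reads "tpm < 1 is unexpressed" strictly, so exactly 1 is
#' expressed).
#'
#' @param matrix Numeric TPM matrix (genes or groups x tissues).
#' @param threshold Expression threshold (default 1).
#' @param column_classes Optional named character vector: column ->
#'   organ-class label for the roll-up.
#' @return List: `flags` (logical matrix), `expressed_anywhere` (logical
#'   per row), and, when `column_classes` is given, `by_class` (logical
#'   row x class matrix: expressed in >= 1 column of the class).
#' @export
expression_flags <- function(matrix, threshold = 1.0, column_classes = NULL) {
  flags <- matrix >= threshold
  out <- list(flags = flags, expressed_anywhere = apply(flags, 1L, any))
  if (!is.null(column_classes)) {
    classes <- unique(column_classes[colnames(matrix)])
    by_class <- vapply(classes, function(cl) {
      cols <- names(column_classes)[column_classes == cl]
      apply(flags[, intersect(cols, colnames(matrix)), drop = FALSE], 1L, any)
    }, logical(nrow(matrix)))
    colnames(by_class) <- classes
    out$by_class <- by_class
  }
  out
}

#' Heatmap transform log2(tpm + 1)
#'
#' @param matrix Numeric TPM matrix.
#' @return Transformed matrix.
#' @export
heatmap_values <- function(matrix) {
  log2(matrix + 1)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per (gene, condition, timepoint): `dCt` is the replicate mean of
#' `Ct_target - Ct_reference`; `ddCt = dCt_sample - dCt_control`, where
#' the control is the record at `control_timepoint` of the same gene and
#' condition; `RQ = 2^-ddCt`.
#'
#' @param table data.frame with columns gene, condition, timepoint,
#'   replicate, ct_target, ct_reference.
#' @param control_timepoint Timepoint value designating the control
#'   sample (default 0).
#' @return data.frame: gene, condition, timepoint, dct, ddct, rq,
#'   log2_rq.
#' @export
ddct <- function(table, control_timepoint = 0) {
  need <- c("gene", "condition", "timepoint", "replicate",
            "ct_target", "ct_reference")
  if (!all(need %in% names(table)))
    stop("missing column(s): ", paste(setdiff(need, names(table)), collapse = ", "))
  if (any(table$ct_target <= 0 | table$ct_reference <= 0))
    stop("Ct values must be positive")
  dct <- stats::aggregate(ct_target - ct_reference ~ gene + condition + timepoint,
                          data = table, FUN = mean)
  names(dct)[4L] <- "dct"
  out <- list()
  for (g in unique(dct$gene)) {
    for (cond in unique(dct$condition[dct$gene == g])) {
      sub <- dct[dct$gene == g & dct$condition == cond, , drop = FALSE]
      ctrl <- sub$dct[sub$timepoint == control_timepoint]
      if (length(ctrl) != 1L)
        stop("missing control record for gene ", g, " under ", cond)
      sub$ddct <- sub$dct - ctrl
      sub$rq <- 2^(-sub$ddct)
      sub$log2_rq <- -sub$ddct
      out[[length(out) + 1L]] <- sub
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene, res$condition, res$timepoint), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fold-change categories for RQ values
#'
#' @param rq Numeric vector of relative quantities.
#' @param up_fold,down_fold Fold thresholds (default 15, i.e. the
#'   ">15-fold up" convention; down = 1/15).
#' @return Character vector: "strong_up", "up", "unchanged", "down",
#'   "strong_down".
#' @export
fold_category <- function(rq, up_fold = 15, down_fold = 1 / up_fold) {
  ifelse(rq > up_fold, "strong_up",
         ifelse(rq > 2, "up",
                ifelse(rq >= 0.5, "unchanged",
                       ifelse(rq >= down_fold, "down", "strong_down"))))
}
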