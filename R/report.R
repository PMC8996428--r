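# Pipeline orchestration: run every survey stage on a directory of inputs
# and consolidate per-gene and family-level results into a survey_report.

read_tsv_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

log_stage <- function(verbose, stage, ...) {
  if (verbose)
    message(sprintf("[vqsurvey] %s: %s", stage, sprintf(...)))
}

#' Run the full gene-family survey pipeline
#'
#' Expects a directory holding `genome.fasta`, `annotation.gff3`,
#' `cds.fasta`, `proteins.fasta`, `groups.tsv` (gene_id, group_id) and
#' optionally `tpm.tsv` (gene_id + tissue columns) and `qpcr.tsv`
#' (long-form Ct table) -- the layout written by
#' [generate_survey_data()]. All stages are deterministic; ids must be
#' consistent across files.
#'
#' @param input_dir Input directory.
#' @param out_dir Optional directory for per-stage TSV artifacts.
#' @param name_prefix Family-name prefix for [assign_family_names()].
#' @param promoter_length Promoter window (bp).
#' @param catalog Cis-element catalog (default [default_cis_catalog()]).
#' @param cov_min,id_min Duplication thresholds.
#' @param max_intervening,max_distance Tandem definition.
#' @param ssr_thresholds MISA-style per-unit-length minimum repeat counts.
#' @param tpm_threshold Expression threshold.
#' @param column_classes Optional tissue-column organ classes; defaults to
#'   the prefix before the last underscore of each column name.
#' @param aligned_proteins Optional named vector of aligned proteins for
#'   the phylogeny stage (skipped when NULL; alignment is out of pipeline
#'   scope).
#' @param verbose Log stage progress to stderr.
#' @return Object of class `survey_report`.
#' @export
run_survey <- function(input_dir, out_dir = NULL, name_prefix = "VQ",
                       promoter_length = 1500L,
                       catalog = default_cis_catalog(),
                       cov_min = 0.75, id_min = 0.75,
                       max_intervening = 5L, max_distance = 2e5,
                       ssr_thresholds = MISA_THRESHOLDS,
                       tpm_threshold = 1.0,
                       column_classes = NULL,
                       aligned_proteins = NULL,
                       verbose = FALSE) {
  t0 <- Sys.time()
  need <- c("genome.fasta", "annotation.gff3", "cds.fasta", "proteins.fasta",
            "groups.tsv")
  paths <- file.path(input_dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("missing input file(s) in ", input_dir, ": ",
         paste(missing, collapse = ", "))

  ## load
  chroms <- read_fasta(file.path(input_dir, "genome.fasta"))
  cds <- read_fasta(file.path(input_dir, "cds.fasta"))
  prots <- read_fasta(file.path(input_dir, "proteins.fasta"))
  models <- read_gff3(file.path(input_dir, "annotation.gff3"))
  grp_tab <- read_tsv_file(file.path(input_dir, "groups.tsv"))
  ids <- names(models)
  bad <- unique(c(setdiff(ids, names(cds)), setdiff(names(cds), ids),
                  setdiff(ids, names(prots)), setdiff(grp_tab$gene_id, ids)))
  if (length(bad) > 0L)
    stop("id mismatch across input files: ", paste(bad, collapse = ", "))
  genome <- genome_bundle(chroms, models)
  models <- genome$genes
  groups <- split(grp_tab$gene_id, grp_tab$group_id)
  log_stage(verbose, "load", "%d genes, %d chromosomes, %d groups",
            length(ids), length(chroms), length(groups))

  ## motif scan + family naming
  hits <- lapply(stats::setNames(ids, ids), function(id) scan_vq(prots[[id]]))
  fam <- classify_family(hits)
  names_map <- assign_family_names(models, groups, prefix = name_prefix)
  log_stage(verbose, "vqscan", "%d/%d genes carry the motif",
            sum(fam$verdicts$is_vq), length(ids))

  ## protein properties
  props <- do.call(rbind, lapply(ids, function(id)
    cbind(gene_id = id, protein_properties(prots[[id]]))))
  log_stage(verbose, "protparam", "%d proteins", nrow(props))

  ## structure + distribution
  structure_summary <- intron_counts(models)
  chrom_dist <- chromosome_distribution(models, names(chroms))

  ## homoeolog triads
  gene_chrom <- stats::setNames(
    vapply(models, `[[`, character(1), "chromosome"), ids)
  hgroups <- build_homoeolog_groups(groups, gene_chrom)
  triads <- summarize_triads(hgroups)
  log_stage(verbose, "triads", "%d groups", nrow(hgroups))

  ## duplications
  dups <- find_duplications(cds, models, cov_min, id_min,
                            max_intervening, max_distance)
  log_stage(verbose, "dup", "%d pairs pass %g/%g", nrow(dups), cov_min, id_min)

  ## SSRs over gene genomic spans
  ssr_records <- do.call(rbind, lapply(ids, function(id)
    find_ssrs(extract_gene_span(genome, id), ssr_thresholds, seq_id = id)))
  if (is.null(ssr_records)) ssr_records <- find_ssrs("", ssr_thresholds)
  ssr_merged <- merge_compound(ssr_records)
  ssr_sum <- ssr_census(ssr_records, length(ids))
  log_stage(verbose, "ssr", "%d SSRs in %d genes", ssr_sum$n_ssrs,
            ssr_sum$n_genes_with_ssr)

  ## promoter cis-elements
  promoters <- vapply(ids, function(id)
    extract_promoter(genome, id, promoter_length), character(1))
  cis_hits <- do.call(rbind, lapply(ids, function(id)
    scan_elements(promoters[[id]], catalog, promoter_id = id)))
  if (is.null(cis_hits))
    cis_hits <- scan_elements("", catalog)
  cis_mat <- element_count_matrix(cis_hits, ids, catalog)
  log_stage(verbose, "cis", "%d hits over %d elements", nrow(cis_hits),
            length(catalog$entries))

  ## expression
  expr <- NULL
  tpm_path <- file.path(input_dir, "tpm.tsv")
  if (file.exists(tpm_path)) {
    tab <- read_tsv_file(tpm_path)
    tpm <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(tpm) <- tab[[1L]]
    if (is.null(column_classes))
      column_classes <- stats::setNames(sub("_[^_]*$", "", colnames(tpm)),
                                        colnames(tpm))
    grp_tpm <- average_homoeologs(tpm, groups)
    flags <- expression_flags(grp_tpm, tpm_threshold, column_classes)
    expr <- list(tpm = tpm, group_tpm = grp_tpm,
                 log2_tpm = heatmap_values(grp_tpm), flags = flags)
    log_stage(verbose, "expr", "%d/%d groups expressed somewhere",
              sum(flags$expressed_anywhere), nrow(grp_tpm))
  }
  qpcr <- NULL
  qpcr_path <- file.path(input_dir, "qpcr.tsv")
  if (file.exists(qpcr_path)) {
    qpcr <- ddct(read_tsv_file(qpcr_path))
    log_stage(verbose, "qpcr", "%d RQ records", nrow(qpcr))
  }

  ## phylogeny (optional; requires a supplied alignment)
  tree <- NULL
  if (!is.null(aligned_proteins) && length(aligned_proteins) >= 3L)
    tree <- neighbor_joining(p_distance(aligned_proteins))

  ## per-gene wide table
  group_of <- stats::setNames(grp_tab$group_id, grp_tab$gene_id)
  cat_of <- stats::setNames(hgroups$category, hgroups$group_id)
  partners <- vapply(ids, function(id) {
    p <- c(dups$gene_b[dups$gene_a == id], dups$gene_a[dups$gene_b == id])
    paste(p, collapse = ";")
  }, character(1))
  ssr_count <- vapply(ids, function(id)
    sum(ssr_records$seq_id == id), integer(1))
  gene_table <- data.frame(
    gene_id = ids,
    name = unname(names_map[ids]),
    chromosome = gene_chrom[ids],
    start = vapply(models, `[[`, numeric(1), "start"),
    end = vapply(models, `[[`, numeric(1), "end"),
    strand = vapply(models, `[[`, character(1), "strand"),
    group_id = unname(group_of[ids]),
    group_category = unname(cat_of[unname(group_of[ids])]),
    is_vq = fam$verdicts$is_vq[match(ids, fam$verdicts$gene_id)],
    motif_variant = fam$verdicts$variant[match(ids, fam$verdicts$gene_id)],
    motif_core = fam$verdicts$core[match(ids, fam$verdicts$gene_id)],
    motif_offset = fam$verdicts$offset[match(ids, fam$verdicts$gene_id)],
    n_introns = structure_summary$per_gene$n_introns[
      match(ids, structure_summary$per_gene$gene_id)],
    n_ssrs = unname(ssr_count),
    duplication_partners = unname(partners),
    row.names = NULL, stringsAsFactors = FALSE)
  gene_table <- cbind(gene_table,
                      props[match(ids, props$gene_id),
                            c("length", "mw", "pi", "instability",
                              "aliphatic", "gravy"), drop = FALSE])
  if (!is.null(expr)) {
    expressed_group <- expr$flags$expressed_anywhere
    gene_table$expressed_group <- unname(
      expressed_group[unname(group_of[ids])])
  }
  rownames(gene_table) <- NULL

  report <- structure(list(
    gene_table = gene_table,
    variant_census = fam$variant_census,
    structure = structure_summary,
    chromosome_distribution = chrom_dist,
    homoeolog_groups = hgroups,
    triad_summary = triads,
    duplications = dups,
    ssr_records = ssr_records,
    ssr_compound = ssr_merged,
    ssr_census = ssr_sum,
    cis_hits = cis_hits,
    cis_counts = cis_mat$counts,
    cis_coverage = cis_mat$coverage,
    expression = expr,
    qpcr = qpcr,
    tree = tree,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "survey_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write per-stage TSV artifacts of a survey report
#'
#' @param report A `survey_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(report$gene_table, "gene_table.tsv")
  w(report$triad_summary, "triad_summary.tsv")
  w(report$homoeolog_groups, "homoeolog_groups.tsv")
  w(report$duplications, "duplications.tsv")
  w(report$ssr_records, "ssr_records.tsv")
  w(report$ssr_compound, "ssr_compound.tsv")
  w(report$cis_hits, "cis_hits.tsv")
  utils::write.table(report$cis_counts, file.path(out_dir, "cis_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)
  if (!is.null(report$qpcr)) w(report$qpcr, "qpcr_rq.tsv")
  if (!is.null(report$tree))
    ape::write.tree(report$tree, file.path(out_dir, "tree.nwk"))
  invisible(out_dir)
}

#' @export
print.survey_report <- function(x, ...) {
  n <- nrow(x$gene_table)
  cat("Gene-family survey report\n")
  cat(sprintf("  genes: %d (%d motif-positive), groups: %d\n", n,
              sum(x$gene_table$is_vq), nrow(x$homoeolog_groups)))
  cat(sprintf("  intronless: %d (%.2f%%)\n", x$structure$n_intronless,
              x$structure$pct_intronless))
  tr <- x$triad_summary
  cat(sprintf("  triads (1:1:1): %.1f%% of genes\n",
              tr$pct_genes[tr$category == "TRIAD_1_1_1"]))
  cat(sprintf("  duplication pairs: %d (%d tandem)\n", nrow(x$duplications),
              sum(x$duplications$kind == "tandem", na.rm = TRUE)))
  cat(sprintf("  SSRs: %d in %d genes\n", x$ssr_census$n_ssrs,
              x$ssr_census$n_genes_with_ssr))
  if ("W-box" %in% names(x$cis_coverage))
    cat(sprintf("  W-box promoter coverage: %.1f%%\n",
                100 * x$cis_coverage[["W-box"]]))
  if (!is.null(x$expression))
    cat(sprintf("  expressed groups (tpm >= 1): %d/%d\n",
                sum(x$expression$flags$expressed_anywhere),
                nrow(x$expression$group_tpm)))
  invisible(x)
}

#' @method summary survey_report
#' @export
summary.survey_report <- function(object, ...) {
  list(n_genes = nrow(object$gene_table),
       n_groups = nrow(object$homoeolog_groups),
       variant_census = object$variant_census,
       triad_summary = object$triad_summary,
       pct_intronless = object$structure$pct_intronless,
       n_duplication_pairs = nrow(object$duplications),
       ssr_census = object$ssr_census,
       cis_coverage = object$cis_coverage)
}
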