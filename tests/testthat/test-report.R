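test_that("run_survey consolidates all stages on the small fixture", {
  fx <- small_fixture()
  man <- fx$manifest
  rep <- run_survey(fx$dir, out_dir = file.path(tempdir(), "small_report"))
  expect_s3_class(rep, "survey_report")
  expect_equal(nrow(rep$gene_table), nrow(man$genes))
  expect_true(all(rep$gene_table$is_vq))
  # family names match the manifest's independently computed expectation
  expect_identical(rep$gene_table$name, man$genes$name)
  # summaries recomputable from the per-gene table
  expect_equal(sum(rep$gene_table$n_introns == 0),
               rep$structure$n_intronless)
  expect_equal(unname(table(factor(rep$gene_table$group_category,
                                   levels = rep$triad_summary$category))[
    rep$triad_summary$category != "Total"]),
    unname(rep$triad_summary$n_genes[rep$triad_summary$category != "Total"]),
    ignore_attr = TRUE)
  # artifacts written
  expect_true(file.exists(file.path(tempdir(), "small_report",
                                    "gene_table.tsv")))
  # print method runs
  expect_output(print(rep), "Gene-family survey report")
  expect_named(summary(rep), c("n_genes", "n_groups", "variant_census",
                               "triad_summary", "pct_intronless",
                               "n_duplication_pairs", "ssr_census",
                               "cis_coverage"),
               ignore.order = TRUE)
})

test_that("run_survey recovers the small fixture's planted features", {
  fx <- small_fixture()
  man <- fx$manifest
  rep <- run_survey(fx$dir)
  # duplication pairs: exactly the planted set
  planted <- apply(man$duplication_pairs[, c("gene_a", "gene_b")], 1,
                   function(r) paste(sort(r), collapse = "|"))
  found <- apply(rep$duplications[, c("gene_a", "gene_b")], 1,
                 function(r) paste(sort(r), collapse = "|"))
  expect_setequal(found, planted)
  expect_equal(rep$duplications$kind[match(planted, found)],
               man$duplication_pairs$kind)
  # SSRs: per-gene motif/count/position match
  expect_equal(nrow(rep$ssr_records), nrow(man$ssrs))
  key <- function(df, motif, count, start, id)
    sort(paste(df[[id]], df[[motif]], df[[count]], df[[start]]))
  expect_identical(
    key(rep$ssr_records, "motif", "repeat_count", "start", "seq_id"),
    sort(paste(man$ssrs$gene_id, man$ssrs$motif, man$ssrs$repeat_count,
               man$ssrs$span_start)))
  # expression flags at group level
  expect_setequal(
    rownames(rep$expression$group_tpm)[
      rep$expression$flags$expressed_anywhere],
    man$expressed_groups)
  # qPCR: control RQ is 1, log2 RQ tracks the simulated truth
  q <- rep$qpcr
  expect_true(all(abs(q$rq[q$timepoint == 0] - 1) < 1e-12))
  mg <- merge(q, man$qpcr_truth,
              by = c("gene", "condition", "timepoint"))
  expect_gt(nrow(mg), 0)
  expect_lt(max(abs(mg$log2_rq - mg$true_log2_rq)), 0.5)
})

test_that("rerunning the pipeline is deterministic", {
  fx <- small_fixture()
  r1 <- run_survey(fx$dir)
  r2 <- run_survey(fx$dir)
  r1$elapsed <- r2$elapsed <- NULL
  expect_identical(r1$gene_table, r2$gene_table)
  expect_identical(r1$duplications, r2$duplications)
  expect_identical(r1$cis_counts, r2$cis_counts)
})

test_that("missing inputs and id mismatches abort with clear messages", {
  expect_error(run_survey(tempfile()), "missing input file")
  fx <- small_fixture()
  broken <- file.path(tempdir(), "broken_fixture")
  dir.create(broken, showWarnings = FALSE)
  for (f in list.files(fx$dir)) file.copy(file.path(fx$dir, f), broken,
                                          overwrite = TRUE)
  cds <- read_fasta(file.path(broken, "cds.fasta"))
  names(cds)[1] <- "ALIEN"
  write_fasta(cds, file.path(broken, "cds.fasta"))
  expect_error(run_survey(broken), "id mismatch")
})
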