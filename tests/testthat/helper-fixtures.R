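# Shared fixtures: a reduced generator configuration for fast unit tests
# and a lazily built, memoised copy of the default fixture + pipeline run
# (used by the end-to-end recovery tests).

.fixture_env <- new.env(parent = emptyenv())

small_survey_config <- function(seed = 7L) {
  survey_config(
    seed = seed,
    ratio_census = list(
      TRIAD_1_1_1 = replicate(3, c(1, 1, 1), simplify = FALSE),
      DUP_n_1_1 = list(c(2, 1, 1)),
      LOSS_1_1_0 = list(c(1, 1, 0)),
      OTHER = list(),
      ORPHAN = list(c(0, 1, 0))),
    motif_variant_census = c(LTG = 12, FTG = 2, ITG = 0, VTG = 1,
                             VTG_VH = 0, VMA = 1),
    intronless_count = 14L,
    duplication_pairs = list(
      list(syn = 3L, nonsyn = 1L, kind = "tandem"),
      list(syn = 2L, nonsyn = 2L, kind = "segmental")),
    ssr_plan = list(n_mono = 1L, n_di = 1L, n_tri = 2L,
                    n_genes = 3L, n_two_ssr_genes = 1L,
                    n_compound_genes = 1L),
    cis_plan = c(`W-box` = 5L, `CGTCA-motif` = 8L),
    expression = list(
      n_expressed_groups = 4L,
      tpm_range = c(1.5, 55),
      columns = c(leaf_1 = "leaf_stem", root_1 = "root", spike_1 = "spike",
                  grain_1 = "grain")),
    qpcr = list(n_genes = 2L, conditions = c("NaCl", "LT"),
                timepoints = c(0, 1, 6), replicates = 3L,
                ct_noise_sd = 0.1, strong_fold_log2 = 4))
}

small_fixture <- function() {
  if (is.null(.fixture_env$small)) {
    dir <- file.path(tempdir(), "vqsurvey_small_fixture")
    manifest <- generate_survey_data(small_survey_config(), dir)
    .fixture_env$small <- list(dir = dir, manifest = manifest)
  }
  .fixture_env$small
}

default_fixture <- function() {
  if (is.null(.fixture_env$default)) {
    dir <- file.path(tempdir(), "vqsurvey_default_fixture")
    manifest <- generate_survey_data(survey_config(seed = 42L), dir)
    .fixture_env$default <- list(dir = dir, manifest = manifest)
  }
  .fixture_env$default
}

default_report <- function() {
  if (is.null(.fixture_env$default_report)) {
    fx <- default_fixture()
    .fixture_env$default_report <- run_survey(fx$dir)
  }
  .fixture_env$default_report
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
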