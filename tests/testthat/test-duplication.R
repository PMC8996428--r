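rand_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(rand_sense_codons(n_codons), collapse = "")
}

test_that("alignment of identical and near-identical CDSs", {
  a <- rand_cds(100, seed = 51)
  aln <- align_cds_pair(a, a)
  expect_equal(aln$coverage, 1)
  expect_equal(aln$identity, 1)

  b <- a
  substr(b, 34, 34) <- setdiff(c("A", "C", "G", "T"), substr(a, 34, 34))[1]
  aln2 <- align_cds_pair(a, b)
  expect_equal(aln2$identity, 299 / 300)
  expect_equal(aln2$coverage, 1)
})

test_that("a pair sharing half the longer gene has coverage 0.5", {
  a <- rand_cds(100, seed = 52)
  half <- substr(a, 1, 150)
  aln <- align_cds_pair(a, half)
  expect_equal(aln$coverage, 0.5)
  expect_equal(aln$identity, 1)
})

test_that("duplication criterion is strict at the 75/75 thresholds", {
  expect_true(is_duplicated_pair(0.80, 0.80))
  expect_false(is_duplicated_pair(0.70, 0.99))
  expect_false(is_duplicated_pair(0.75, 0.99))
  expect_false(is_duplicated_pair(0.99, 0.75))
})

test_that("tandem/segmental classification follows the locality rule", {
  mk <- function(id, chr, start)
    gene_model(id, chr, "+", start, start + 999, cbind(start, start + 999))
  adj <- list(mk("a", "2B", 1000), mk("b", "2B", 3000))
  expect_equal(classify_duplication("a", "b", adj), "tandem")
  expect_equal(classify_duplication("a", "b",
                                    list(mk("a", "2B", 1), mk("b", "3B", 1))),
               "segmental")
  # same chromosome, 10 Mb apart with 200 intervening genes
  filler <- lapply(1:200, function(i) mk(paste0("f", i), "2B", 5000 + i * 40000))
  far <- c(list(mk("a", "2B", 1000), mk("b", "2B", 1e7)), filler)
  expect_equal(classify_duplication("a", "b", far), "segmental")
})

test_that("ng86 reproduces trivial cases and is symmetric", {
  a <- rand_cds(30, seed = 53)
  same <- list(aln_a = a, aln_b = a)
  r <- ng86(same)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)

  set.seed(54)
  for (i in 1:10) {
    p <- rand_codon_pair(25, sample(1:8, 1))
    r1 <- ng86(list(aln_a = p$a, aln_b = p$b))
    r2 <- ng86(list(aln_a = p$b, aln_b = p$a))
    expect_equal(r1$ka, r2$ka, tolerance = 1e-12)
    expect_equal(r1$ks, r2$ks, tolerance = 1e-12)
  }
})

test_that("planted synonymous-only and nonsynonymous-only changes", {
  # third-position synonymous changes in 4-fold codons: ka must be 0
  a <- paste(rep(c("GCT", "GGA", "CTG", "ACC", "GTA", "TCC"), 5), collapse = "")
  b <- a
  substr(b, 3, 3) <- "C"    # GCT -> GCC (Ala, synonymous)
  substr(b, 6, 6) <- "G"    # GGA -> GGG (Gly, synonymous)
  r <- ng86(list(aln_a = a, aln_b = b))
  expect_equal(r$ka, 0)
  ok <- oracle_ng86(a, b)
  expect_equal(r$ks, ok$ks, tolerance = 1e-9)
  expect_gt(r$ks, 0)

  b2 <- a
  substr(b2, 4, 4) <- "T"   # GGA -> TGA? no: position 4 starts codon 2
  # make an unambiguous nonsynonymous first-position change: GGA -> CGA
  substr(b2, 4, 4) <- "C"
  r2 <- ng86(list(aln_a = a, aln_b = b2))
  expect_equal(r2$ks, 0)
  expect_gt(r2$ka, 0)
  ok2 <- oracle_ng86(a, b2)
  expect_equal(r2$ka, ok2$ka, tolerance = 1e-9)
})

test_that("ks never decreases with added synonymous substitutions", {
  # one synonymous third-position change per codon, cumulatively
  base <- paste(rep(c("GCT", "GGT", "CTT", "ACT", "GTT", "TCT", "CCT", "CGT"),
                    4), collapse = "")
  ks_prev <- 0
  mut <- base
  for (lvl in 1:20) {
    substr(mut, lvl * 3, lvl * 3) <- "C"   # XYT -> XYC, synonymous in these
    r <- ng86(list(aln_a = base, aln_b = mut))
    expect_equal(r$ka, 0)
    expect_gte(r$ks, ks_prev - 1e-12)
    ks_prev <- r$ks
  }
})

test_that("gap codons are removed and saturation is flagged", {
  a <- paste0("ATGGCT", "---", "GAA")
  b <- paste0("ATGGCT", "GGG", "GAA")
  r <- ng86(list(aln_a = a, aln_b = b))
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  # saturated synonymous proportion is undefined under Jukes-Cantor
  r2 <- ng86(list(aln_a = "TTT", aln_b = "TTC"))
  expect_true(is.na(r2$ks))
})

test_that("selection calls follow the Ka/Ks rule", {
  expect_equal(selection_call(0.1, 0.5), "purifying")
  expect_equal(selection_call(0.5, 0.5), "neutral")
  expect_equal(selection_call(0.6, 0.5), "positive")
  expect_equal(selection_call(0.2, 0.0), "undefined")
  expect_equal(selection_call(NA, 0.5), "undefined")
})

test_that("find_duplications recovers a planted duplicate among decoys", {
  set.seed(55)
  a <- rand_cds(80)
  b <- a
  for (pos in c(10, 40, 70, 100, 130)) {
    repeat {
      alt <- sample(c("A", "C", "G", "T"), 1)
      cand <- b
      substr(cand, pos, pos) <- alt
      cods <- substring(cand, seq(1, nchar(cand), 3), seq(3, nchar(cand), 3))
      if (alt != substr(b, pos, pos) && !any(cods %in% STOPS)) {
        b <- cand; break
      }
    }
  }
  decoy1 <- rand_cds(80)
  decoy2 <- rand_cds(85)
  cds <- c(g1 = a, g2 = b, g3 = decoy1, g4 = decoy2)
  d <- find_duplications(cds)
  expect_equal(nrow(d), 1)
  expect_setequal(c(d$gene_a, d$gene_b), c("g1", "g2"))
  expect_gt(d$identity, 0.97)
})
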