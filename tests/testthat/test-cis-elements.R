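test_that("W-box consensus matches on both strands", {
  cat_ <- default_cis_catalog()
  h <- scan_elements("AATTGACCAA", cat_)
  expect_equal(nrow(h), 1)
  expect_equal(h$element, "W-box")
  expect_equal(h$strand, "+")
  expect_equal(h$offset, 3)

  h2 <- scan_elements("TTGGTCAAAA", cat_)   # revcomp carries TTGACC
  expect_equal(h2$element, "W-box")
  expect_equal(h2$strand, "-")

  expect_equal(nrow(scan_elements(strrep("A", 100), cat_)), 0)
  # minus strand can be disabled
  expect_equal(nrow(scan_elements("TTGGTCAAAA", cat_, both_strands = FALSE)), 0)
})

test_that("IUPAC codes follow their ACGT expansions and N never matches", {
  cat_ <- cis_catalog(list(DRE = "RCCGAC"), c(DRE = "stress"))
  expect_equal(scan_elements("TTACCGACTT", cat_,
                             both_strands = FALSE)$offset, 3)
  expect_equal(scan_elements("TTGCCGACTT", cat_,
                             both_strands = FALSE)$offset, 3)
  expect_equal(nrow(scan_elements("TTCCCGACTT", cat_, both_strands = FALSE)), 0)
  expect_equal(nrow(scan_elements("TTNCCGACTT", cat_, both_strands = FALSE)), 0)
  expect_error(cis_catalog(list(bad = "ACGQ"), c(bad = "stress")),
               "malformed")
})

test_that("overlapping matches are all reported", {
  cat_ <- cis_catalog(list(E = "TGACG"), c(E = "hormone"))
  h <- scan_elements("TTGACGACGT", cat_, both_strands = FALSE)
  # TGACG at 2; no second overlapping plus-strand instance
  expect_equal(h$offset, 2)
  h2 <- scan_elements("TGACGTGACGTGACG", cat_, both_strands = FALSE)
  expect_equal(h2$offset, c(1, 6, 11))
})

test_that("count matrix and coverage fractions", {
  cat_ <- default_cis_catalog()
  proms <- c(p1 = "AATTGACCAATTGACTAA", p2 = "AACCGGTTACGGCCGGTA",
             p3 = strrep("A", 18))
  hits <- do.call(rbind, lapply(names(proms), function(id)
    scan_elements(proms[[id]], cat_, promoter_id = id)))
  m <- element_count_matrix(hits, names(proms), cat_)
  expect_equal(m$counts["p1", "W-box"], 2L)
  expect_equal(m$counts["p3", "W-box"], 0L)
  expect_equal(unname(m$coverage[["W-box"]]), 1 / 3)
  # zero hit list gives a zero matrix
  m0 <- element_count_matrix(scan_elements("", cat_), names(proms), cat_)
  expect_true(all(m0$counts == 0))
})

test_that("both-strand totals are invariant to reverse complement", {
  set.seed(71)
  cat_ <- default_cis_catalog()
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    h_fwd <- scan_elements(s, cat_)
    h_rev <- scan_elements(revcomp(s), cat_)
    t_fwd <- table(factor(h_fwd$element, names(cat_$entries)))
    t_rev <- table(factor(h_rev$element, names(cat_$entries)))
    expect_equal(as.vector(t_fwd), as.vector(t_rev))
  }
})

test_that("planted elements are recovered with full precision and recall", {
  fx <- small_fixture()
  man <- fx$manifest
  genome <- read_fasta(file.path(fx$dir, "genome.fasta"))
  models <- read_gff3(file.path(fx$dir, "annotation.gff3"))
  gb <- genome_bundle(genome, models)
  cat_ <- default_cis_catalog()
  planted_els <- names(man$cis_expected)
  for (id in unique(man$genes$gene_id)) {
    prom <- extract_promoter(gb, id, 1500)
    h <- scan_elements(prom, cat_, promoter_id = id)
    truth <- man$cis[man$cis$gene_id == id, , drop = FALSE]
    for (el in planted_els) {
      expect_equal(sum(h$element == el), sum(truth$element == el),
                   info = paste(id, el))
    }
    # planted offsets are reported exactly
    if (nrow(truth) > 0)
      expect_true(all(truth$offset %in% h$offset[h$strand == "+"]))
  }
})
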