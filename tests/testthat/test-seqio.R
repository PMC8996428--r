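test_that("read_fasta normalizes case, keeps order, rejects duplicates", {
  p <- write_temp_fasta(c(">g1 some description", "acgt"))
  expect_identical(read_fasta(p), c(g1 = "ACGT"))

  p2 <- write_temp_fasta(c(">b", "AC", "GT", ">a", "TTTT"))
  x <- read_fasta(p2)
  expect_identical(names(x), c("b", "a"))
  expect_identical(unname(x), c("ACGT", "TTTT"))

  p3 <- write_temp_fasta(c(">g1", "AC", ">g1", "GT"))
  expect_error(read_fasta(p3), "g1")

  p4 <- write_temp_fasta(character(0))
  expect_length(read_fasta(p4), 0)
})

test_that("fasta round-trip reproduces sequences byte-identically", {
  set.seed(1)
  seqs <- setNames(
    vapply(1:5, function(i) paste(sample(c("A", "C", "G", "T"),
                                         sample(50:200, 1), TRUE),
                                  collapse = ""), character(1)),
    paste0("s", 1:5))
  path <- tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  expect_identical(read_fasta(path), seqs)
})

test_that("gene_model enforces its invariants", {
  expect_error(gene_model("g", "1A", "?", 1, 10, cbind(1, 10)), "strand")
  expect_error(gene_model("g", "1A", "+", 10, 1, cbind(1, 10)), "start > end")
  expect_error(gene_model("g", "1A", "+", 1, 100, cbind(c(1, 5), c(10, 20))),
               "overlapping")
  expect_error(gene_model("g", "1A", "+", 10, 20, cbind(1, 20)), "outside")
  # exons sorted regardless of input order
  g <- gene_model("g", "1A", "+", 1, 100, rbind(c(50, 60), c(1, 10)))
  expect_equal(g$exons[, "start"], c(1, 50))
  expect_error(gene_model("g", "1A", "+", 1, 100, cbind(1, 30),
                          cds_seq = "ACGTA", protein_seq = "M"),
               "divisible")
})

test_that("read_gff3 builds models, sorts exons and flags bad input", {
  gff <- c("##gff-version 3",
           "1A\tsrc\tgene\t100\t400\t.\t+\t.\tID=g1",
           "1A\tsrc\tmRNA\t100\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
           "1A\tsrc\texon\t300\t400\t.\t+\t.\tID=g1.e2;Parent=g1.t1",
           "1A\tsrc\texon\t100\t200\t.\t+\t.\tID=g1.e1;Parent=g1.t1",
           "1A\tsrc\tCDS\t100\t200\t.\t+\t0\tID=g1.c1;Parent=g1.t1",
           "1A\tsrc\tCDS\t300\t400\t.\t+\t0\tID=g1.c2;Parent=g1.t1",
           "1A\tsrc\tgene\t500\t600\t.\t+\t.\tID=g2",
           "1A\tsrc\tmRNA\t500\t600\t.\t+\t.\tID=g2.t1;Parent=g2",
           "1A\tsrc\texon\t500\t600\t.\t+\t.\tID=g2.e1;Parent=g2.t1")
  path <- tempfile(fileext = ".gff3")
  writeLines(gff, path)
  models <- read_gff3(path)
  expect_length(models, 2)
  expect_equal(nrow(models$g1$exons), 2)
  expect_equal(models$g1$exons[, "start"], c(100, 300))
  expect_equal(nrow(models$g2$exons), 1)

  bad <- sub("exon\t300\t400", "exon\t300\t500", gff)
  writeLines(bad, path)
  expect_error(read_gff3(path), "outside gene span")

  # CDS length not divisible by 3 when translation is requested
  gff2 <- c("##gff-version 3",
            "1A\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1",
            "1A\tsrc\tmRNA\t1\t10\t.\t+\t.\tID=g1.t1;Parent=g1",
            "1A\tsrc\texon\t1\t10\t.\t+\t.\tID=g1.e1;Parent=g1.t1",
            "1A\tsrc\tCDS\t1\t10\t.\t+\t0\tID=g1.c1;Parent=g1.t1")
  writeLines(gff2, path)
  genome <- c(`1A` = strrep("ACGT", 5))
  expect_error(read_gff3(path, genome), "divisible")
})

test_that("extract_promoter follows the stated coordinate convention", {
  set.seed(11)
  chrom <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  g_plus <- gene_model("gp", "1A", "+", 2001, 2300, cbind(2001, 2300),
                       cds_start_genomic = 2001)
  gb <- genome_bundle(c(`1A` = chrom), list(g_plus))
  expect_identical(extract_promoter(gb, "gp", 1500),
                   substring(chrom, 501, 2000))
  # truncation at the chromosome boundary
  g_edge <- gene_model("ge", "1A", "+", 100, 400, cbind(100, 400),
                       cds_start_genomic = 100)
  gb2 <- genome_bundle(c(`1A` = chrom), list(g_edge))
  expect_identical(nchar(extract_promoter(gb2, "ge", 1500)), 99L)
  expect_error(extract_promoter(gb, "nope"), "unknown gene")
})

test_that("promoters of mirrored plus/minus constructs are identical", {
  set.seed(12)
  promoter <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  body <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  pad <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  chr_plus <- paste0(pad, promoter, body, pad)
  chr_minus <- revcomp(chr_plus)
  gp <- gene_model("gp", "c1", "+", 1601, 1900, cbind(1601, 1900),
                   cds_start_genomic = 1601)
  gm <- gene_model("gm", "c2", "-", 101, 400, cbind(101, 400),
                   cds_start_genomic = 400)
  gb <- genome_bundle(c(c1 = chr_plus, c2 = chr_minus), list(gp, gm))
  pp <- extract_promoter(gb, "gp", 1500)
  pm <- extract_promoter(gb, "gm", 1500)
  expect_identical(pp, promoter)
  expect_identical(pm, pp)
  # the promoter never overlaps the CDS
  expect_identical(extract_gene_span(gb, "gp"), body)
  expect_identical(extract_gene_span(gb, "gm"), body)
})

test_that("translate_cds handles stops and bad codons", {
  expect_identical(translate_cds("ATGGCTTAA"), "MA")
  expect_identical(translate_cds("ATGGCT"), "MA")
  expect_error(translate_cds("ATGGC"), "divisible")
  expect_error(translate_cds("ATGTAAGCT"), "internal stop")
})
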