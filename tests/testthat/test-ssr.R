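test_that("MISA thresholds are honored at the boundaries", {
  flank <- function(x) paste0("GCGT", x, "CAAC")
  r <- find_ssrs(flank(strrep("A", 10)))
  expect_equal(nrow(r), 1)
  expect_equal(r$ssr_type, "p1")
  expect_equal(r$repeat_count, 10)
  expect_equal(r$start, 5)
  expect_equal(r$end, 14)
  expect_equal(nrow(find_ssrs(flank(strrep("A", 9)))), 0)

  r2 <- find_ssrs(flank(strrep("AG", 6)))
  expect_equal(r2$ssr_type, "p2")
  expect_equal(r2$repeat_count, 6)
  expect_equal(nrow(find_ssrs(flank(strrep("AG", 5)))), 0)

  r3 <- find_ssrs(flank(strrep("AGC", 5)))
  expect_equal(r3$ssr_type, "p3")
  expect_equal(nrow(find_ssrs(flank(strrep("AGC", 4)))), 0)

  for (k in 4:6) {
    unit <- substr("ACGTGC", 1, k)
    expect_equal(find_ssrs(flank(strrep(unit, 5)))$ssr_type, paste0("p", k))
    expect_equal(nrow(find_ssrs(flank(strrep(unit, 4)))), 0)
  }
})

test_that("runs are reported once, at the smallest unit", {
  r <- find_ssrs(paste0("GC", strrep("A", 12), "GC"))
  expect_equal(nrow(r), 1)
  expect_equal(r$motif, "A")
  # (AT)8 must not additionally be reported as ATAT
  r2 <- find_ssrs(paste0("GC", strrep("AT", 8), "GC"))
  expect_equal(nrow(r2), 1)
  expect_equal(r2$ssr_type, "p2")
})

test_that("N never extends or starts a repeat", {
  expect_equal(nrow(find_ssrs(paste0(strrep("A", 6), "N", strrep("A", 6)))), 0)
  expect_equal(nrow(find_ssrs(strrep("N", 30))), 0)
})

test_that("compound merging respects the interruption limit", {
  s1 <- paste0("GCTC", strrep("AG", 6), strrep("C", 9), "T",
               strrep("CT", 6), "GGAA")
  rec <- find_ssrs(s1)
  expect_equal(nrow(rec), 2)
  merged <- merge_compound(rec)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$ssr_type, "compound")
  expect_equal(merged$start, min(rec$start))
  expect_equal(merged$end, max(rec$end))

  # the 10-mer period of the spacer is outside the 1-6 nt unit range
  s2 <- paste0("GCTC", strrep("AG", 6), strrep("GGCATACTGA", 11), "T",
               strrep("CT", 6), "GGAA")
  rec2 <- find_ssrs(s2)
  expect_equal(nrow(rec2), 2)
  expect_equal(nrow(merge_compound(rec2)), 2)   # 106 bp apart: stays simple

  single <- find_ssrs(paste0("GG", strrep("AGC", 5), "TT"))
  expect_identical(merge_compound(single), single)
})

test_that("census percentages count simple SSRs by unit class", {
  rec <- rbind(
    find_ssrs(strrep("AGC", 5), seq_id = "g1"),
    find_ssrs(strrep("CTT", 6), seq_id = "g2"),
    find_ssrs(strrep("GAT", 5), seq_id = "g3"),
    find_ssrs(strrep("AG", 7), seq_id = "g3"))
  cen <- ssr_census(rec, n_genes = 10)
  expect_equal(cen$n_ssrs, 4)
  expect_equal(cen$n_genes_with_ssr, 3)
  expect_equal(unname(cen$class_pct[["p3"]]), 75.0)
  expect_equal(unname(cen$class_pct[["p2"]]), 25.0)
  empty <- ssr_census(find_ssrs("ACGT"), n_genes = 5)
  expect_equal(empty$n_ssrs, 0)
  expect_true(all(empty$class_pct == 0))
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  set.seed(61)
  for (i in 1:60) {
    # enriched alphabet runs make threshold-passing repeats likely
    n <- 500
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    # splice in a few repeat stretches at random spots
    for (j in 1:3) {
      unit <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), TRUE),
                    collapse = "")
      reps <- sample(4:12, 1)
      at <- sample(n - nchar(unit) * reps, 1)
      substr(s, at, at + nchar(unit) * reps - 1) <- strrep(unit, reps)
    }
    mine <- find_ssrs(s)
    oracle <- oracle_ssrs(s)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(mine) > 0) {
      expect_equal(mine$start, oracle$start)
      expect_equal(mine$motif, oracle$motif)
      expect_equal(mine$repeat_count, oracle$repeat_count)
      expect_equal(mine$end, oracle$end)
    }
  }
})

test_that("reversing a sequence mirrors record coordinates", {
  set.seed(62)
  s <- paste0(paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
              strrep("TGA", 6),
              paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""))
  n <- nchar(s)
  r_fwd <- find_ssrs(s)
  r_rev <- find_ssrs(paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_equal(nrow(r_fwd), nrow(r_rev))
  expect_setequal(n - r_fwd$end + 1, r_rev$start)
})
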