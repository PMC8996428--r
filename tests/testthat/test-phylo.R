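test_that("p-distance uses pairwise deletion", {
  a <- c(x = "AAAA", y = "AAAT")
  expect_equal(p_distance(a)["x", "y"], 0.25)
  expect_equal(p_distance(c(x = "AAAA", y = "AAAA"))["x", "y"], 0)
  expect_equal(p_distance(c(x = "AA--", y = "AAAA"))["x", "y"], 0)
  expect_error(p_distance(c(x = "--AA", y = "AA--")), "no comparable")
  expect_error(p_distance(c(x = "AAA", y = "AAAA")), "equal length")
})

test_that("three-taxon NJ matches the closed form", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(dm)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 1)
  expect_equal(len[["B"]], 1)
  expect_equal(len[["C"]], 3)
  expect_error(neighbor_joining(dm[1:2, 1:2]), ">= 3 taxa")
})

test_that("NJ recovers additive quartets with exact lengths", {
  tr0 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  dm <- ape::cophenetic.phylo(tr0)
  nj <- neighbor_joining(dm)
  co <- ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)]
  expect_lt(max(abs(co - dm)), 1e-9)
  # AB|CD split present
  parts <- ape::prop.part(nj)
  sets <- lapply(parts, function(p) sort(nj$tip.label[p]))
  expect_true(any(vapply(sets, function(s)
    identical(s, c("A", "B")) || identical(s, c("C", "D")), logical(1))))
})

test_that("NJ path lengths reproduce ultrametric and random additive matrices", {
  d <- matrix(c(0, 1, 4, 4, 1, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  nj <- neighbor_joining(d)
  expect_lt(max(abs(ape::cophenetic.phylo(nj)[LETTERS[1:4], LETTERS[1:4]] - d)),
            1e-9)
  set.seed(81)
  for (i in 1:25) {
    tr <- ape::rtree(8)
    tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
    dm <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(dm)
    co <- ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(co - dm)), 1e-9)
    # independent cross-check of the topology against ape's NJ
    expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(ape::nj(dm))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ output is invariant to taxa input order", {
  set.seed(82)
  tr <- ape::rtree(7)
  dm <- ape::cophenetic.phylo(tr)
  nj1 <- neighbor_joining(dm)
  perm <- sample(rownames(dm))
  nj2 <- neighbor_joining(dm[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(nj1), ape::unroot(nj2)), 0,
               ignore_attr = TRUE)
  co1 <- ape::cophenetic.phylo(nj1)[perm, perm]
  co2 <- ape::cophenetic.phylo(nj2)[perm, perm]
  expect_lt(max(abs(co1 - co2)), 1e-9)
})

test_that("bootstrap supports strong clades and stays within [0, 100]", {
  blockA <- strrep("A", 25); blockC <- strrep("C", 25)
  blockG <- strrep("G", 25); blockT <- strrep("T", 25)
  aligned <- c(
    a1 = paste0(blockA, blockA, blockG),
    a2 = paste0(blockA, blockA, blockT),
    a3 = paste0(blockA, blockC, blockG),
    b1 = paste0(blockC, blockG, blockG),
    b2 = paste0(blockC, blockG, blockT),
    b3 = paste0(blockC, blockT, blockG))
  bs <- bootstrap_support(aligned, replicates = 200, seed = 5)
  expect_false(bs$degenerate)
  sup <- bs$node_support[!is.na(bs$node_support)]
  expect_true(all(sup >= 0 & sup <= 100))
  # the a-clade and b-clade are separated by 25 fixed columns
  expect_gte(max(sup), 95)

  same <- c(x = "AAAA", y = "AAAA", z = "AAAA")
  bs2 <- bootstrap_support(same, replicates = 10, seed = 1)
  expect_true(bs2$degenerate)
})

test_that("subgroup labels propagate from the nearest reference clade", {
  tr <- ape::read.tree(text = "((q1:1,refA:1):1,((refB1:1,refB2:1):1,(q2:1,(refC:1,refD:1):1):1):1);")
  labels <- c(refA = "II", refB1 = "III", refB2 = "III",
              refC = "IV", refD = "V")
  out <- assign_subgroups(tr, labels)
  expect_equal(out[["q1"]], "II")       # sister to a single reference
  expect_equal(out[["q2"]], "UNASSIGNED")  # smallest labeled clade conflicts
})

test_that("center-star alignment preserves sequences and equalizes length", {
  seqs <- c(s1 = "MKLVQTG", s2 = "MKLVTG", s3 = "MKLVQTGA")
  al <- align_center_star(seqs)
  expect_length(unique(nchar(al)), 1)
  expect_identical(gsub("-", "", al[names(seqs)]), seqs)
})
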