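test_that("p-distances use pairwise deletion with per-pair denominators", {
  aln <- makeAln(c(a = "ACGTAA", b = "ACGTAA", c = "TTGTAA"))
  dm <- pdistanceMatrix(aln)
  expect_equal(dm$d["a", "b"], 0)
  expect_equal(dm$d["a", "c"], 2 / 6)

  # gap column dropped only for pairs involving the gapped sequence
  aln <- makeAln(c(a = "ACGTAA", b = "AC-TAT", c = "TCGTAA"))
  dm <- pdistanceMatrix(aln)
  expect_equal(dm$comparable["a", "b"], 5L)
  expect_equal(dm$d["a", "b"], 1 / 5)   # mismatch at last site
  expect_equal(dm$comparable["a", "c"], 6L)
  expect_equal(dm$d["a", "c"], 1 / 6)

  gap <- makeAln(c(a = "AC--", b = "--GT", c = "ACGT"))
  expect_error(pdistanceMatrix(gap), "no comparable sites.*a.*b")
})

test_that("neighbor joining is exact on additive distances", {
  # ((A:2,B:3):1,(C:4,D:5))
  d <- matrix(0, 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  d["A", "B"] <- 5; d["A", "C"] <- 7; d["A", "D"] <- 8
  d["B", "C"] <- 8; d["B", "D"] <- 9; d["C", "D"] <- 9
  d <- d + t(d)
  tr <- neighborJoining(d)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)

  # three taxa: closed-form star lengths
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighborJoining(d3)
  lens <- setNames(tr3$edge.length,
                   tr3$tip.label[tr3$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 5 - 6) / 2)
  expect_equal(lens[["B"]], (3 + 6 - 5) / 2)
  expect_equal(lens[["C"]], (5 + 6 - 3) / 2)

  expect_error(neighborJoining(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric|3 taxa")
})

test_that("NJ recovers 50 random additive trees of 5-12 taxa", {
  set.seed(77)
  for (rep in 1:50) {
    k <- sample(5:12, 1)
    case <- randomAdditiveCase(k)
    tr <- neighborJoining(case$d)
    expect_equal(ape::dist.topo(tr, case$tree)[[1]], 0,
                 label = paste("replicate", rep))
    expect_equal(ape::cophenetic.phylo(tr)[rownames(case$d),
                                           colnames(case$d)],
                 case$d, tolerance = 1e-8)
  }
})

test_that("NJ topology is invariant to input label order", {
  case <- randomAdditiveCase(8)
  tr1 <- neighborJoining(case$d)
  perm <- sample(8)
  tr2 <- neighborJoining(case$d[perm, perm])
  expect_equal(ape::dist.topo(tr1, tr2)[[1]], 0)
})

test_that("bootstrap supports are deterministic and saturate on unambiguous data", {
  # every column supports the split {a,b,c} | {d,e,f}
  seqs <- c(a = strrep("A", 30), b = strrep("A", 30),
            c = strrep("A", 30), d = strrep("T", 30),
            e = strrep("T", 30), f = strrep("T", 30))
  # add within-group variation so distances are informative
  substr(seqs["a"], 1, 3) <- "CCC"
  substr(seqs["d"], 1, 3) <- "GGG"
  aln <- SequenceAlignment(seqs)
  tr <- bootstrapSupport(aln, reps = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  # the central split must be recovered with support 1
  expect_true(any(abs(sup - 1) < 1e-12, na.rm = TRUE))

  tr2 <- bootstrapSupport(aln, reps = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  expect_error(bootstrapSupport(aln, reps = 0), "reps")
})

test_that("bootstrap supports match ape's bipartition counting", {
  aln <- randomCoalAln(n = 6, theta = 10, nSites = 200, seed = 42)
  m <- alignmentMatrix(aln)
  reps <- 200
  tr <- bootstrapSupport(aln, reps = reps, seed = 99)

  # regenerate the identical replicate trees, then count bipartitions
  # with ape::prop.clades as the independent oracle
  set.seed(99)
  point <- neighborJoining(pdistanceMatrix(aln))
  boots <- vector("list", reps)
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    seqs <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    boots[[r]] <- neighborJoining(pdistanceMatrix(
      SequenceAlignment(seqs)))
  }
  oracle <- ape::prop.clades(point, boots, rooted = FALSE) / reps
  mine <- suppressWarnings(as.numeric(tr$node.label))
  cmp <- !is.na(mine) & !is.na(oracle)
  expect_true(any(cmp))
  expect_equal(mine[cmp], oracle[cmp], tolerance = 1e-9)
})
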