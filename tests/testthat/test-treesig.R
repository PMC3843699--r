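test_that("JC distances match the closed form and ape's implementation", {
  # identical -> 0
  aln0 <- mk_aln(c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(jc_distance_matrix(aln0)[1, 2], 0)
  # p = 0.1 -> 0.10732
  s1 <- strrep("A", 10)
  s2 <- paste0("C", strrep("A", 9))
  d <- jc_distance_matrix(mk_aln(c(s1, s2)))
  expect_equal(d[1, 2], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(d[1, 2], 0.10732, tolerance = 1e-4)
  # saturation boundary flagged with sentinel
  s3 <- paste0(strrep("C", 3), "A")
  s4 <- strrep("A", 4)
  d2 <- jc_distance_matrix(mk_aln(c(s3, s4)))
  expect_true(attr(d2, "saturated")[1, 2])
  # cross-check against ape on a random alignment
  set.seed(8)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                             collapse = ""))
  mine <- jc_distance_matrix(mk_aln(seqs))
  theirs <- as.matrix(ape::dist.dna(ape::as.DNAbin(t(sapply(
    strsplit(tolower(seqs), ""), identity))), model = "JC69"))
  sat <- attr(mine, "saturated")
  cmp <- !sat & upper.tri(mine)
  expect_equal(unname(mine[cmp]), unname(theirs[cmp]), tolerance = 1e-9)
})

test_that("complete deletion removes gapped columns before distances", {
  aln <- mk_aln(c("A-GT", "AAGT", "AAGA"))
  d <- jc_distance_matrix(aln)  # column 2 dropped everywhere
  expect_equal(d[1, 2], 0)
  expect_gt(d[1, 3], 0)
})

test_that("NJ recovers additive four-taxon trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  dm <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 5
  dm["A", "D"] <- dm["D", "A"] <- 6
  dm["B", "C"] <- dm["C", "B"] <- 6
  dm["B", "D"] <- dm["D", "B"] <- 7
  dm["C", "D"] <- dm["D", "C"] <- 7
  tr <- nj_tree(dm)
  # split AB|CD present
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  # path distances reproduce the input matrix exactly (NJ consistency)
  pd <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(pd, dm, tolerance = 1e-10)
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("negative NJ branches are clamped without breaking the topology", {
  set.seed(42)
  # noisy non-additive matrix prone to tiny negative edges
  m <- matrix(runif(36, 0.1, 0.2), 6, 6)
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:6], letters[1:6])
  tr <- nj_tree(m)
  expect_true(all(tr$edge.length >= 0))
  expect_equal(ape::Ntip(tr), 6L)
})

test_that("bootstrap support is near-certain for deeply split clades", {
  left <- strrep("A", 30); right <- strrep("C", 30)
  aln <- mk_aln(c(paste0(left, "ACGTAC"), paste0(left, "ACGTAA"),
                  paste0(right, "ACGTAC"), paste0(right, "ACGTAT")),
                ids = c("l1", "l2", "r1", "r2"))
  bs <- bootstrap_support(aln, B = 100, seed = 5)
  expect_true(all(bs$support >= 95))
  bs2 <- bootstrap_support(aln, B = 100, seed = 5)
  expect_identical(bs$support, bs2$support)
  expect_true(all(bs$support <= 100))
})

test_that("the BootScan track crosses at a recombination breakpoint", {
  set.seed(19)
  L <- 300
  B <- c("A", "C", "G", "T")
  flipit <- function(s, idx) {
    s[idx] <- vapply(s[idx], function(b) sample(setdiff(B, b), 1), character(1))
    s
  }
  # two paralogue lineages and a deeper outgroup, all from one ancestor
  anc <- sample(B, L, TRUE)
  p1c <- flipit(anc, sample.int(L, 30))
  p2c <- flipit(anc, sample.int(L, 30))
  xc <- flipit(anc, sample.int(L, 80))
  rec <- c(p1c[1:150], p2c[151:300])  # mosaic: left from p1, right from p2
  aln <- mk_aln(c(paste(rec, collapse = ""), paste(p1c, collapse = ""),
                  paste(p2c, collapse = ""), paste(xc, collapse = "")),
                ids = c("rec", "p1", "p2", "x"))
  tr <- bootscan_signal(aln, c("rec", "p1"), spec = window_spec(100, 100),
                        B = 60, seed = 3)
  expect_gt(tr$pct_trees[1], 80)   # left window: rec == p1
  expect_lt(tr$pct_trees[3], 20)   # right window: rec == p2
  expect_true(all(tr$pct_trees >= 0 & tr$pct_trees <= 100))
  expect_error(bootscan_signal(mk_aln(c("AC", "AG", "AT")), c("a", "b")),
               "fewer than 4")
})

test_that("normalized RF is 0 on identity, 1 on disjoint quartets, symmetric", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds_normalized(t1, t1), 0)
  expect_equal(robinson_foulds_normalized(t1, t2), 1)
  expect_equal(robinson_foulds_normalized(t2, t1), 1)
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(robinson_foulds_normalized(t1, t3), "tip set")
})

test_that("normalized RF agrees with phangorn on random resolved trees", {
  set.seed(23)
  for (i in 1:12) {
    nt <- sample(5:10, 1)
    a <- ape::rtopology(nt, rooted = FALSE)
    b <- ape::rtopology(nt, rooted = FALSE, tip.label = a$tip.label)
    mine <- robinson_foulds_normalized(a, b)
    theirs <- phangorn::RF.dist(a, b, normalize = TRUE)
    expect_equal(mine, theirs, tolerance = 1e-12)
  }
})

test_that("normalized RF is a metric on enumerated five-taxon topologies", {
  trees <- phangorn::allTrees(5, rooted = FALSE)
  idx <- cbind(sample(length(trees), 40, TRUE), sample(length(trees), 40, TRUE),
               sample(length(trees), 40, TRUE))
  for (r in seq_len(nrow(idx))) {
    a <- trees[[idx[r, 1]]]; b <- trees[[idx[r, 2]]]; c <- trees[[idx[r, 3]]]
    ab <- robinson_foulds_normalized(a, b)
    expect_equal(ab, robinson_foulds_normalized(b, a))
    expect_equal(robinson_foulds_normalized(a, a), 0)
    expect_lte(ab, robinson_foulds_normalized(a, c) +
                 robinson_foulds_normalized(c, b) + 1e-12)
  }
})

test_that("random-topology RF baseline matches the quartet expectation", {
  ref <- ape::read.tree(text = "((A,B),(C,D));")
  rb <- random_rf_baseline(ref, R = 1500, seed = 9)
  # three equiprobable quartet topologies: mean RF = 2/3
  # (SE of the mean at R = 1500 is ~0.012; allow 4 SE)
  expect_equal(rb$mean, 2 / 3, tolerance = 0.075)
  rb2 <- random_rf_baseline(ref, R = 1500, seed = 9)
  expect_identical(rb$values, rb2$values)
  # many tips: random trees share almost no splits
  big <- ape::rtopology(40, rooted = FALSE)
  rb3 <- random_rf_baseline(big, R = 30, seed = 2)
  expect_gt(rb3$mean, 0.9)
})

test_that("newick files round-trip through the tree I/O helpers", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):2);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(robinson_foulds_normalized(tr, back), 0)
  expect_equal(sort(back$tip.label), c("A", "B", "C", "D"))
})
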