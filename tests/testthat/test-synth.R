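test_that("generated class counts equal the configured targets exactly", {
  for (seed in c(42L, 7L, 101L)) {
    d <- generate_paralogue_dataset(synth_config(seed = seed))
    sA <- call_segregating_sites(d$aln_A, regions = d$regions)
    sB <- call_segregating_sites(d$aln_B, regions = d$regions)
    cls <- classify_paralogue_sites(sA, consensus_seq(d$aln_A),
                                    sB, consensus_seq(d$aln_B))
    cc <- count_classes_by_region(cls, d$regions)
    tg <- default_class_targets()
    for (rg in tg$region) {
      expect_equal(cc$fixed[cc$region == rg], tg$fixed[tg$region == rg])
      expect_equal(cc$shared[cc$region == rg], tg$shared[tg$region == rg])
      expect_equal(cc$specific_A[cc$region == rg],
                   tg$specific_A[tg$region == rg])
      expect_equal(cc$specific_B[cc$region == rg],
                   tg$specific_B[tg$region == rg])
    }
    expect_true(recovery_report(d$truth, cls)$exact_match)
    expect_equal(nrow(collapse_haplotypes(d$aln_A)), 33L)
    expect_equal(n_chromosomes(d$aln_A), 64L)
  }
})

test_that("truth derived counts match the emitted alignments", {
  fx <- synth_fixture()
  polyA <- fx$truth[fx$truth$class %in% c("SHARED", "SPECIFIC_A"), ]
  idx <- match(polyA$position, fx$sitesA$position)
  expect_false(anyNA(idx))
  for (j in seq_len(nrow(polyA))) {
    ac <- fx$sitesA$allele_counts[[idx[j]]]
    anc_base <- substring(fx$outgroup$seq, polyA$position[j], polyA$position[j])
    expect_equal(sum(ac) - ac[[anc_base]], polyA$derived_count_A[j])
  }
})

test_that("zero targets produce monomorphic paralogues", {
  tg <- default_class_targets()
  tg[, c("fixed", "shared", "specific_A", "specific_B")] <- 0L
  d <- generate_paralogue_dataset(synth_config(targets = tg, seed = 3,
                                               og_noncds_subs = 0L,
                                               og_syn_codons = 0L,
                                               og_nonsyn_codons = 0L))
  expect_equal(nrow(call_segregating_sites(d$aln_A)), 0L)
  cls <- classify_paralogue_sites(
    call_segregating_sites(d$aln_A), consensus_seq(d$aln_A),
    call_segregating_sites(d$aln_B), consensus_seq(d$aln_B))
  expect_true(all(cls$class == "INVARIANT"))
})

test_that("targets beyond region capacity are rejected", {
  tg <- default_class_targets()
  tg$specific_A[tg$region == "intron2"] <- 300L
  expect_error(synth_config(targets = tg), "capacity")
})

test_that("sweep-skewed intron spectra depress H below the other regions", {
  worked <- 0L
  nseeds <- 25L
  for (seed in seq_len(nseeds)) {
    d <- generate_paralogue_dataset(synth_config(sfs_mode = "sweep_skewed",
                                                 seed = 1000L + seed))
    sA <- polarize_sites(call_segregating_sites(d$aln_A, regions = d$regions),
                         d$outgroup)
    h_of <- function(rg) {
      sub <- sA[sA$region == rg, , drop = FALSE]
      attr(sub, "n") <- attr(sA, "n")
      class(sub) <- class(sA)
      fay_wu_h(sfs_from_sites(sub))$H
    }
    hs <- vapply(c("intron2", "noncds", "cds"), h_of, numeric(1))
    if (hs["intron2"] < 0 && hs["intron2"] < min(hs[-1])) worked <- worked + 1L
  }
  expect_gte(worked, round(0.9 * nseeds))
})

test_that("paired seeds show sweep mode lowering H relative to neutral mode", {
  diffs <- vapply(1:15, function(seed) {
    hn <- local({
      d <- generate_paralogue_dataset(synth_config(seed = seed))
      s <- polarize_sites(call_segregating_sites(d$aln_A), d$outgroup)
      fay_wu_h(sfs_from_sites(s))$H
    })
    hs <- local({
      d <- generate_paralogue_dataset(synth_config(sfs_mode = "sweep_skewed",
                                                   seed = seed))
      s <- polarize_sites(call_segregating_sites(d$aln_A), d$outgroup)
      fay_wu_h(sfs_from_sites(s))$H
    })
    hs - hn
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gt(mean(diffs < 0), 0.8)
})

test_that("neutral coalescent datasets conserve S and are polarizable", {
  nd <- generate_neutral_dataset(16, 20, constant_demography(5000), seed = 5)
  st <- call_segregating_sites(nd$aln)
  expect_equal(nrow(st), 20L)
  expect_equal(n_chromosomes(nd$aln), 16L)
  pol <- polarize_sites(st, nd$outgroup)
  expect_false(any(pol$unpolarizable))
  # determinism
  nd2 <- generate_neutral_dataset(16, 20, constant_demography(5000), seed = 5)
  expect_identical(nd$aln$seqs, nd2$aln$seqs)
})

test_that("neutral datasets reproduce the 1/i spectrum in aggregate", {
  n <- 10L; S <- 8L; R <- 150L
  xi_sum <- numeric(n - 1)
  for (r in seq_len(R)) {
    nd <- generate_neutral_dataset(n, S, constant_demography(2000),
                                   seed = 5000L + r)
    pol <- polarize_sites(call_segregating_sites(nd$aln), nd$outgroup)
    xi_sum <- xi_sum + sfs_from_sites(pol, n = n)$xi
  }
  prop <- xi_sum / sum(xi_sum)
  expected <- (1 / (1:(n - 1))) / sum(1 / (1:(n - 1)))
  se <- sqrt(expected * (1 - expected) / sum(xi_sum)) * 3  # correlated, loose
  expect_true(all(abs(prop - expected) < 6 * se + 0.02))
})

test_that("recovery reports expose deliberate misclassification", {
  fx <- synth_fixture()
  rr <- recovery_report(fx$truth, fx$cls)
  expect_true(rr$exact_match)
  expect_true(all(rr$confusion[row(rr$confusion) != col(rr$confusion)] == 0))
  broken <- fx$cls
  i <- which(broken$position == fx$truth$position[1])
  broken$class[i] <- setdiff(c("FIXED", "SHARED"), broken$class[i])[1]
  rr2 <- recovery_report(fx$truth, broken)
  expect_false(rr2$exact_match)
  expect_equal(sum(rr2$confusion) - sum(diag(rr2$confusion)), 1)
  empty <- recovery_report(fx$truth[0, ], fx$cls)
  expect_true(empty$exact_match)
})
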