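test_that("FASTA round trip preserves sequences, ids and multiplicities", {
  aln <- mk_aln(c("ACGTACGTAC", "ACGTACGTAA", "ACGTACGTAG", "ACGTACGTAT"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta_alignment(aln, f)
  back <- read_fasta_alignment(f, counts_from_header = TRUE)
  expect_equal(back$seqs, aln$seqs)
  expect_equal(back$counts, aln$counts)
  expect_equal(n_chromosomes(back), 4L)
  expect_equal(back$L, 10L)
})

test_that("count tags in headers scale the sample size", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">h1;count=32", "ACGTACGTAC", ">h2;count=32", "ACGTACGTAA"), f)
  aln <- read_fasta_alignment(f, counts_from_header = TRUE)
  expect_equal(n_chromosomes(aln), 64L)
  expect_equal(aln$ids, c("h1", "h2"))
})

test_that("malformed FASTA input is rejected", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), f)
  expect_error(read_fasta_alignment(f), "unequal")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), f2)
  expect_error(read_fasta_alignment(f2))
})

test_that("site-table TSV reads haplotype rows and rejects bad columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos\t5\t9",
               "h1\t2\tA\tC",
               "h2\t1\tG\tC",
               "h3\t1\tA\tT"), f)
  r <- read_site_table(f)
  expect_equal(n_chromosomes(r$aln), 4L)
  expect_equal(nrow(r$sites), 2L)
  expect_equal(r$sites$position, c(5L, 9L))
  expect_equal(r$sites$allele_counts[[1]], c(A = 3L, G = 1L))
  # monomorphic column
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos\t5\t9", "h1\t2\tA\tC", "h2\t1\tA\tC"), f2)
  expect_error(read_site_table(f2), "monomorphic")
  # duplicate positions
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pos\t5\t5", "h1\t2\tA\tC", "h2\t1\tG\tT"), f3)
  expect_error(read_site_table(f3), "duplicate")
})

test_that("packaged haplotype table fixture has the study's totals", {
  r <- read_site_table(extdata("cyp21_synthetic_haplotypes.tsv"))
  expect_equal(nrow(r$sites), 44L)
  expect_equal(n_chromosomes(r$aln), 64L)
  expect_equal(length(r$aln$ids), 33L)
})

test_that("site-table write/read round trip is exact", {
  fx <- synth_fixture()
  sub <- subset_columns(fx$aln_A, cbind(fx$sitesA$position, fx$sitesA$position),
                        mode = "keep")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(sub, f)
  back <- read_site_table(f)
  expect_equal(back$aln$seqs, sub$seqs)
  expect_equal(back$aln$counts, sub$counts)
  expect_equal(back$sites$position, fx$sitesA$position)
})

test_that("haplotype collapse orders by multiplicity then sequence", {
  aln <- mk_aln(c("AAAA", "AAAA", "CCCC", "GGGG"))
  sp <- collapse_haplotypes(aln)
  expect_equal(sp$count, c(2L, 1L, 1L))
  expect_equal(sp$seq, c("AAAA", "CCCC", "GGGG"))
  expect_equal(sum(sp$count), 4L)
  one <- collapse_haplotypes(mk_aln(rep("ACGT", 4)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$count, 4L)
})

test_that("MAF filtering keeps the boundary case and drops below it", {
  # n = 100, minor count 1: freq 0.01 >= 0.01 -> retained
  aln <- mk_aln(c(paste(rep("A", 5), collapse = ""),
                  paste(c("C", rep("A", 4)), collapse = "")),
                counts = c(99L, 1L))
  st <- call_segregating_sites(aln, maf_threshold = 0.01)
  expect_equal(nrow(st), 1L)
  # n = 200, minor count 1: freq 0.005 < 0.01 -> excluded
  aln2 <- mk_aln(aln$seqs, counts = c(199L, 1L))
  expect_equal(nrow(call_segregating_sites(aln2, maf_threshold = 0.01)), 0L)
  # threshold 0 keeps every polymorphic column
  expect_equal(nrow(call_segregating_sites(aln2, maf_threshold = 0)), 1L)
  expect_error(call_segregating_sites(mk_aln("ACGT")), "at least 2")
})

test_that("gapped columns are dropped under the default gap policy", {
  aln <- mk_aln(c("A-GT", "ACGA", "ACGA"))
  st <- call_segregating_sites(aln)
  expect_equal(st$position, 4L)  # column 2 dropped, column 4 segregates
})

test_that("sites recalled from a reconstructed alignment match the table", {
  r <- read_site_table(extdata("cyp21_synthetic_haplotypes.tsv"))
  st <- call_segregating_sites(r$aln, maf_threshold = 0)
  expect_equal(st$position, seq_len(r$aln$L))
  expect_equal(vapply(st$allele_counts, sum, numeric(1)),
               rep(64, nrow(st)))
  # polymorphism bound: max allele count <= n - 1
  expect_true(all(vapply(st$allele_counts, max, numeric(1)) <= 63))
})

test_that("outgroup polarization sets derived counts and flags mismatches", {
  aln <- mk_aln(c("AAG", "GAG"), counts = c(60L, 4L))
  st <- call_segregating_sites(aln)
  p1 <- polarize_sites(st, outgroup("ACA"))  # matches the major allele
  expect_equal(p1$ancestral[1], "A")
  expect_equal(p1$derived_count[1], 4L)
  p2 <- polarize_sites(st, outgroup("CCA"))  # matches neither allele
  expect_true(p2$unpolarizable[1])
  expect_true(is.na(p2$derived_count[1]))
  # high-frequency derived
  aln3 <- mk_aln(c("A", "G"), counts = c(1L, 63L))
  p3 <- polarize_sites(call_segregating_sites(aln3), outgroup("A"))
  expect_equal(p3$derived_count[1], 63L)
})

test_that("keep and drop of complementary intervals agree", {
  fx <- synth_fixture()
  iv <- fx$regions[fx$regions$label == "intron2", c("start", "end")]
  kept <- subset_columns(fx$aln_A, iv, mode = "keep")
  expect_equal(kept$L, 282L)
  comp <- fx$regions[fx$regions$label != "intron2", c("start", "end")]
  dropped <- subset_columns(fx$aln_A, comp, mode = "drop")
  expect_equal(dropped$seqs, kept$seqs)
  expect_equal(attr(dropped, "frame_positions"), attr(kept, "frame_positions"))
  # empty interval list = identity
  ident <- subset_columns(fx$aln_A, NULL, mode = "drop")
  expect_equal(ident$seqs, fx$aln_A$seqs)
  expect_error(subset_columns(fx$aln_A, c(3000, 4000), mode = "keep"),
               "out of range")
})

test_that("dropping the intron-2 conversion tract removes its four sites", {
  fx <- synth_fixture()
  expect_equal(nrow(fx$sitesA) - nrow(drop_sites_in_tracts(fx$sitesA, c(624, 634))),
               4L)
})

test_that("region map enforces bounds and non-overlap; lengths match", {
  expect_error(region_map("a", 0, 5, L = 10), "1 <= start")
  expect_error(region_map(c("a", "b"), c(1, 4), c(5, 8), L = 10), "overlap")
  rl <- region_lengths(default_gene_regions())
  expect_equal(unname(rl["intron2"]), 282L)
  expect_equal(unname(rl["cds"]), 1488L)
  expect_equal(unname(rl["noncds"]), 1587L)
  expect_equal(sum(rl), 3357L)
})
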