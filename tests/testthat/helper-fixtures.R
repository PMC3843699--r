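# Shared fixtures, built once per test run.

# the packaged default synthetic paralogue dataset plus derived objects
synth_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- generate_paralogue_dataset(synth_config(seed = 42))
      sitesA <- call_segregating_sites(d$aln_A, regions = d$regions)
      sitesA <- polarize_sites(sitesA, d$outgroup)
      sitesB <- call_segregating_sites(d$aln_B, regions = d$regions)
      cls <- classify_paralogue_sites(sitesA, consensus_seq(d$aln_A),
                                      sitesB, consensus_seq(d$aln_B))
      cache <<- c(d, list(sitesA = sitesA, sitesB = sitesB, cls = cls,
                          class_counts = count_classes_by_region(cls, d$regions)))
    }
    cache
  }
})

extdata <- function(f) {
  system.file("extdata", f, package = "paraldiv", mustWork = TRUE)
}

# small deterministic alignment from explicit sequences
mk_aln <- function(seqs, counts = NULL, ids = NULL) {
  hap_alignment(seqs, ids = ids, counts = counts)
}

# brute-force average pairwise difference count per site, expanding
# multiplicities (independent oracle for pi)
brute_pi_total <- function(aln, skip_gap_cols = TRUE) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  m <- m[rep(seq_along(aln$counts), aln$counts), , drop = FALSE]
  if (skip_gap_cols) {
    keep <- apply(m, 2, function(col) !any(col %in% c("-", "N")))
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ])
  tot / (n * (n - 1) / 2)
}

# exhaustive Ewens-sampling distribution of the haplotype-number K for
# small n, by recursive enumeration of set partitions (oracle for fus_fs)
ewens_k_distribution <- function(n, theta) {
  # enumerate partitions of {1..n} via restricted growth strings
  probs <- numeric(n)
  rgs <- function(prefix, maxblock) {
    if (length(prefix) == n) {
      sizes <- tabulate(prefix)
      sizes <- sizes[sizes > 0]
      k <- length(sizes)
      logp <- k * log(theta) + sum(lfactorial(sizes - 1)) -
        sum(log(theta + 0:(n - 1)))
      probs[k] <<- probs[k] + exp(logp)
      return(invisible(NULL))
    }
    for (b in seq_len(maxblock + 1)) {
      rgs(c(prefix, b), max(maxblock, b))
    }
  }
  rgs(integer(0), 0L)
  probs
}
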