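# ---------------------------------------------------------------------------
# Minimal MaxChi-style breakpoint detection between a sequence pair, used to
# nominate minimum conversion tracts for masking. The pipeline also accepts
# externally supplied tracts, so masking never depends on detection.
# ---------------------------------------------------------------------------

maxchi_chi2 <- function(mismatch, split) {
  left <- mismatch[seq_len(split)]
  right <- mismatch[(split + 1L):length(mismatch)]
  tab <- rbind(c(sum(left), length(left) - sum(left)),
               c(sum(right), length(right) - sum(right)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(0)
  suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
}

#' MaxChi breakpoint scan between two aligned sequences
#'
#' Scans the sequence of comparable columns (both bases in `A,C,G,T`) of an
#' aligned pair. A window of `2 * window_sites` consecutive comparable sites
#' slides along; at its midpoint the 2x2 chi-square of (left/right half) x
#' (match/mismatch between the pair) is evaluated, and maxima of the
#' chi-square profile become breakpoint candidates. Significance is assessed
#' by permuting the per-site match/mismatch labels (`permutations` shuffles,
#' max-chi-square null), which accounts for the scan's multiplicity.
#'
#' @param seqA,seqB aligned sequence strings (or `hap_alignment` rows) of
#'   equal length.
#' @param window_sites half-window size k in comparable sites (default 20).
#' @param permutations permutation replicates (default 200).
#' @param seed RNG seed.
#' @param alpha significance level for candidate reporting (default 0.05).
#' @return data frame of candidates (possibly 0 rows): `breakpoint`
#'   (frame position of the window midpoint), `chi2`, `p` (permutation),
#'   `tract_start`, `tract_end` (span of the mismatching sites inside the
#'   window's denser half, the minimum-tract nomination).
#' @export
maxchi_scan <- function(seqA, seqB, window_sites = 20L, permutations = 200L,
                        seed = 1L, alpha = 0.05) {
  a <- strsplit(toupper(seqA), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seqB), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  pos <- which(ok)
  mm <- a[ok] != b[ok]
  empty <- data.frame(breakpoint = integer(0), chi2 = numeric(0),
                      p = numeric(0), tract_start = integer(0),
                      tract_end = integer(0))
  if (length(pos) < 2L * window_sites || sum(mm) == 0L) return(empty)
  w <- 2L * window_sites
  starts <- seq_len(length(pos) - w + 1L)
  chi <- vapply(starts, function(s)
    maxchi_chi2(mm[s:(s + w - 1L)], window_sites), numeric(1))
  best <- which.max(chi)
  obs <- chi[best]
  if (obs <= 0) return(empty)
  set.seed(seed)
  null_max <- vapply(seq_len(permutations), function(i) {
    pm <- sample(mm)
    max(vapply(starts, function(s)
      maxchi_chi2(pm[s:(s + w - 1L)], window_sites), numeric(1)))
  }, numeric(1))
  p <- (1 + sum(null_max >= obs)) / (permutations + 1)
  if (p > alpha) return(empty)
  s <- starts[best]
  left <- s:(s + window_sites - 1L)
  right <- (s + window_sites):(s + w - 1L)
  denser <- if (sum(mm[left]) >= sum(mm[right])) left else right
  implicated <- pos[denser][mm[denser]]
  data.frame(breakpoint = pos[s + window_sites - 1L],
             chi2 = obs, p = p,
             tract_start = min(implicated), tract_end = max(implicated))
}

#' Nominate minimum conversion tracts from scan candidates
#'
#' The minimum tract of a candidate is the closed interval from the first to
#' the last implicated segregating site; candidates whose implicated spans
#' overlap are merged.
#'
#' @param candidates data frame from [maxchi_scan()] (or any frame with
#'   `tract_start`, `tract_end`).
#' @return data frame `(start, end)` of tract intervals (0 rows when no
#'   candidates).
#' @export
nominate_tracts <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  iv <- candidates[order(candidates$tract_start),
                   c("tract_start", "tract_end")]
  out <- list(c(iv$tract_start[1L], iv$tract_end[1L]))
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- out[[length(out)]]
    if (iv$tract_start[i] <= last[2L] + 1L) {
      out[[length(out)]][2L] <- max(last[2L], iv$tract_end[i])
    } else {
      out[[length(out) + 1L]] <- c(iv$tract_start[i], iv$tract_end[i])
    }
  }
  data.frame(start = vapply(out, `[`, numeric(1), 1L),
             end = vapply(out, `[`, numeric(1), 2L))
}
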