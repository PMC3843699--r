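# ---------------------------------------------------------------------------
# Site-frequency-spectrum and haplotype neutrality statistics.
# All statistics are on the per-gene (total, length-unscaled) scale, the
# convention of the standard software output they mirror.
# ---------------------------------------------------------------------------

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Build an unfolded site frequency spectrum
#'
#' @param sites a polarized `site_table` (see [polarize_sites()]); rows
#'   flagged `unpolarizable` are excluded (their number is reported).
#' @param n sample size; defaults to the table's `n`.
#' @return object of class `sfs`: `n`, `xi` (length `n-1`; `xi[i]` = number
#'   of sites with derived count `i`), `S = sum(xi)`, `n_unpolarizable`.
#' @export
sfs_from_sites <- function(sites, n = site_table_n(sites)) {
  usable <- !sites$unpolarizable & !is.na(sites$derived_count)
  dc <- sites$derived_count[usable]
  if (length(dc) && (any(dc < 1L) || any(dc > n - 1L)))
    stop("derived_count out of [1, n-1]")
  sfs(tabulate(dc, nbins = n - 1L), n = n,
      n_unpolarizable = sum(sites$unpolarizable, na.rm = TRUE))
}

#' Construct an SFS from frequency-class counts
#' @param xi integer vector of length `n-1`; `xi[i]` = sites with derived
#'   allele count `i`.
#' @param n sample size.
#' @param n_unpolarizable count of sites excluded from the spectrum.
#' @export
sfs <- function(xi, n, n_unpolarizable = 0L) {
  xi <- as.integer(xi)
  if (length(xi) != n - 1L) stop("xi must have length n - 1")
  if (any(xi < 0L)) stop("xi must be non-negative")
  structure(list(n = as.integer(n), xi = xi, S = sum(xi),
                 n_unpolarizable = as.integer(n_unpolarizable)),
            class = "sfs")
}

# theta-pi (total) from an unfolded SFS
sfs_theta_pi <- function(sp) {
  i <- seq_len(sp$n - 1L)
  sum(2 * i * (sp$n - i) * sp$xi) / (sp$n * (sp$n - 1))
}

#' Tajima's D
#'
#' `D = (theta_pi - S/a1) / sqrt(e1 S + e2 S (S-1))` with the standard
#' constants `a1, a2, b1, b2, c1, c2, e1, e2`. Quantities are per-gene totals.
#'
#' @param S number of segregating sites (>= 1 for a defined value).
#' @param theta_pi_total average pairwise differences (total over sites).
#' @param n sample size.
#' @return list `D`, `undefined`.
#' @export
tajimas_d <- function(S, theta_pi_total, n) {
  if (n < 4L) stop("Tajima's D requires n >= 4")
  if (S < 1) return(list(D = NA_real_, undefined = TRUE))
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  list(D = (theta_pi_total - S / a1) / sqrt(v), undefined = FALSE)
}

# log unsigned Stirling numbers of the first kind |s(n, k)|, k = 1..n,
# via the recurrence |s(n+1,k)| = |s(n,k-1)| + n |s(n,k)| in log space.
.stirling_env <- new.env(parent = emptyenv())

log_stirling1 <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_env[[key]])) return(.stirling_env[[key]])
  ls <- c(0)                      # n = 1: |s(1,1)| = 1
  if (n > 1L) {
    for (m in 1:(n - 1L)) {
      new <- numeric(m + 1L)
      for (k in 1:(m + 1L)) {
        a <- if (k >= 2L) ls[k - 1L] else -Inf
        b <- if (k <= m) log(m) + ls[k] else -Inf
        new[k] <- logsumexp(c(a, b))
      }
      ls <- new
    }
  }
  .stirling_env[[key]] <- ls
  ls
}

#' Probability that a neutral sample has at least k haplotypes (Ewens)
#'
#' `P(K >= k | theta, n) = sum_{j=k}^{n} |s(n,j)| theta^j / (theta)_n`,
#' computed in log space with unsigned Stirling numbers of the first kind
#' and the rising factorial `(theta)_n`.
#'
#' @param n sample size; @param k observed haplotype count; @param theta
#'   scaled mutation parameter (> 0).
#' @return list `log_Sprime` (log of the upper-tail probability) and
#'   `log_1m` (log of its complement), both exact to log-space precision.
#' @keywords internal
ewens_k_tail <- function(n, k, theta) {
  ls <- log_stirling1(n)
  j <- seq_len(n)
  logterm <- ls + j * log(theta) - sum(log(theta + 0:(n - 1L)))
  list(log_Sprime = logsumexp(logterm[j >= k]),
       log_1m = if (k <= 1L) -Inf else logsumexp(logterm[j < k]))
}

#' Fu's Fs
#'
#' `Fs = ln(S' / (1 - S'))` where `S'` is the Ewens-formula probability of
#' observing at least the observed number of haplotypes `k` given
#' `theta = theta_pi`. Both `S'` and `1 - S'` are accumulated in log space so
#' extreme values keep precision.
#'
#' @param n sample size; @param k distinct haplotype count (1..n);
#' @param theta_pi_total per-gene theta-pi used as the theta estimate (> 0).
#' @return list `Fs`, `Sprime`, `infinite` flag (`TRUE` when `S'` is 0 or 1
#'   to machine precision).
#' @export
fus_fs <- function(n, k, theta_pi_total) {
  if (k < 1L || k > n) stop("k must lie in [1, n]")
  if (theta_pi_total <= 0) return(list(Fs = NA_real_, Sprime = NA_real_,
                                       infinite = TRUE))
  tail <- ewens_k_tail(n, k, theta_pi_total)
  if (!is.finite(tail$log_1m))
    return(list(Fs = Inf, Sprime = 1, infinite = TRUE))
  Fs <- tail$log_Sprime - tail$log_1m
  list(Fs = Fs, Sprime = exp(tail$log_Sprime), infinite = !is.finite(Fs))
}

#' Fay and Wu's H (with theta_H and theta_L)
#'
#' `theta_H = sum 2 xi_i i^2 / (n(n-1))`, `theta_L = sum i xi_i / (n-1)`,
#' `H = theta_pi - theta_H` (per-gene totals). The algebraic identity
#' `H = 2 (theta_pi - theta_L)` holds for every spectrum.
#'
#' @param sp an unfolded [sfs()].
#' @return list `H`, `theta_H`, `theta_L`, `theta_pi`, `undefined`.
#' @export
fay_wu_h <- function(sp) {
  if (sp$S == 0L)
    return(list(H = NA_real_, theta_H = NA_real_, theta_L = NA_real_,
                theta_pi = 0, undefined = TRUE))
  n <- sp$n; i <- seq_len(n - 1L)
  th <- sum(2 * sp$xi * i^2) / (n * (n - 1))
  tl <- sum(i * sp$xi) / (n - 1)
  tp <- sfs_theta_pi(sp)
  list(H = tp - th, theta_H = th, theta_L = tl, theta_pi = tp,
       undefined = FALSE)
}

#' Normalized Fay and Wu's H
#'
#' `nH = (theta_pi - theta_L) / sqrt(Var)` with the published variance of
#' `theta_pi - theta_L`, evaluated at `theta = S/a1` and
#' `theta^2 = S(S-1)/(a1^2 + a2)`:
#' `Var = (n-2)/(6(n-1)) theta +
#'  [18 n^2 (3n+2) b_{n+1} - (88 n^3 + 9 n^2 - 13 n + 6)] / (9 n (n-1)^2) theta^2`
#' where `b_{n+1} = sum_{i=1}^{n} 1/i^2`.
#'
#' @param sp an unfolded [sfs()] with `S >= 1`.
#' @return list `nH`, `undefined`.
#' @export
zeng_nh <- function(sp) {
  if (sp$S == 0L) return(list(nH = NA_real_, undefined = TRUE))
  n <- sp$n; S <- sp$S
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  bn1 <- a2 + 1 / n^2
  th <- S / a1
  th2 <- S * (S - 1) / (a1^2 + a2)
  v <- (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
    (9 * n * (n - 1)^2) * th2
  if (!is.finite(v) || v <= 0) return(list(nH = NA_real_, undefined = TRUE))
  tl <- sum(i * sp$xi) / (n - 1)
  tp <- sfs_theta_pi(sp)
  list(nH = (tp - tl) / sqrt(v), undefined = FALSE)
}

# solve E[K | theta, n] = sum_{i=0}^{n-1} theta/(theta+i) = k by bisection
ewens_theta_for_k <- function(n, k) {
  if (k <= 1L) return(1e-8)
  if (k >= n) return(1e8)
  ek <- function(th) sum(th / (th + 0:(n - 1L)))
  lo <- 1e-8; hi <- 1
  while (ek(hi) < k) hi <- hi * 2
  stats::uniroot(function(th) ek(th) - k, c(lo, hi), tol = 1e-10)$root
}

# one Chinese-restaurant draw of a partition of n; returns table sizes
crp_draw <- function(n, theta) {
  sizes <- integer(0)
  for (i in seq_len(n)) {
    tot <- i - 1
    if (length(sizes) == 0L ||
        stats::runif(1) < theta / (theta + tot)) {
      sizes <- c(sizes, 1L)
    } else {
      j <- sample.int(length(sizes), 1L, prob = sizes)
      sizes[j] <- sizes[j] + 1L
    }
  }
  sizes
}

#' Ewens-Watterson homozygosity test
#'
#' Observed homozygosity `F = sum p_i^2` over haplotype frequencies, with a
#' Monte-Carlo null conditional on `(n, k)`: partitions are drawn from the
#' Ewens sampling formula by the Chinese-restaurant construction at the
#' `theta` solving `E[K] = k`, and draws are retained only when they produce
#' exactly `k` haplotypes (conditioning removes the theta dependence). The
#' reported `p_lower = P(F_null <= F_obs)` targets the excess-of-even-
#' haplotype-frequencies (sweep/balancing-sensitive) tail; the upper tail is
#' returned alongside.
#'
#' @param hap_counts integer multiplicities of the distinct haplotypes.
#' @param reps Monte-Carlo replicates retained (default 1000).
#' @param rng_seed mandatory seed for reproducibility.
#' @return list `F`, `p_lower`, `p_upper`, `reps`.
#' @export
ewens_watterson_test <- function(hap_counts, reps = 1000L, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is required for reproducibility")
  n <- sum(hap_counts); k <- length(hap_counts)
  Fobs <- sum((hap_counts / n)^2)
  if (k == 1L) return(list(F = 1, p_lower = 1, p_upper = 1, reps = 0L))
  if (k == n)  return(list(F = 1 / n, p_lower = 1, p_upper = 1, reps = 0L))
  set.seed(rng_seed)
  theta <- ewens_theta_for_k(n, k)
  Fnull <- numeric(reps)
  got <- 0L; tries <- 0L; max_tries <- reps * 2000L
  while (got < reps && tries < max_tries) {
    tries <- tries + 1L
    sz <- crp_draw(n, theta)
    if (length(sz) == k) {
      got <- got + 1L
      Fnull[got] <- sum((sz / n)^2)
    }
  }
  if (got < reps) {
    Fnull <- Fnull[seq_len(got)]
    warning("only ", got, " conditional draws obtained")
  }
  list(F = Fobs,
       p_lower = (1 + sum(Fnull <= Fobs)) / (length(Fnull) + 1),
       p_upper = (1 + sum(Fnull >= Fobs)) / (length(Fnull) + 1),
       reps = length(Fnull))
}

#' All SFS/haplotype neutrality statistics for one region
#'
#' Convenience wrapper combining [tajimas_d()], [fus_fs()], [fay_wu_h()],
#' [zeng_nh()] and the Ewens-Watterson homozygosity on one dataset.
#'
#' @param aln a `hap_alignment`; @param sites its (polarized) `site_table`.
#' @param ew_reps,ew_seed Monte-Carlo settings for the EW test (`NULL` skips
#'   the EW p-value).
#' @return list of class `neutrality_stats`.
#' @export
neutrality_stats <- function(aln, sites, ew_reps = 1000L, ew_seed = NULL) {
  n <- n_chromosomes(aln)
  S <- nrow(sites)
  tp <- theta_pi_total(sites)
  spec <- collapse_haplotypes(aln)
  k <- nrow(spec)
  sp <- sfs_from_sites(sites, n = n)
  d <- tajimas_d(S, tp, n)
  fs <- if (tp > 0) fus_fs(n, k, tp) else list(Fs = NA_real_, infinite = TRUE)
  h <- fay_wu_h(sp)
  nh <- zeng_nh(sp)
  ew <- list(F = sum((spec$count / n)^2), p_lower = NA_real_)
  if (!is.null(ew_seed))
    ew <- ewens_watterson_test(spec$count, reps = ew_reps, rng_seed = ew_seed)
  structure(list(n = n, S = S, k = k,
                 theta_pi_total = tp,
                 theta_w_total = S / sum(1 / seq_len(n - 1L)),
                 theta_H = h$theta_H, theta_L = h$theta_L,
                 D = d$D, Fs = fs$Fs, H = h$H, nH = nh$nH,
                 EW_F = ew$F, EW_p = ew$p_lower,
                 flags = list(D_undefined = d$undefined,
                              Fs_infinite = isTRUE(fs$infinite),
                              H_undefined = isTRUE(h$undefined),
                              nH_undefined = isTRUE(nh$undefined),
                              sfs_unpolarizable = sp$n_unpolarizable)),
            class = "neutrality_stats")
}

#' @export
print.neutrality_stats <- function(x, ...) {
  cat(sprintf("n=%d S=%d k=%d | D=%.3f Fs=%.2f H=%.2f nH=%.2f EW=%.3f\n",
              x$n, x$S, x$k, x$D, x$Fs, x$H, x$nH, x$EW_F))
  invisible(x)
}
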