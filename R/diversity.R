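# ---------------------------------------------------------------------------
# Diversity summaries and coding-sequence selection statistics (NG86, MK).
# ---------------------------------------------------------------------------

#' Per-region diversity summary
#'
#' Computes the standard summary block: segregating sites S, distinct
#' haplotype count k, expected haplotype heterozygosity (with Nei's sampling
#' standard deviation), per-site nucleotide diversity pi and Watterson's
#' theta.
#'
#' `pi` is computed from the site table as
#' `sum_sites 2 * sum_{a<b} c_a c_b / (n (n-1)) / L_effective`, which equals
#' the multiplicity-weighted average pairwise difference per analyzed site.
#'
#' @param aln a `hap_alignment` (`n >= 2`).
#' @param sites the corresponding `site_table` (e.g. from
#'   [call_segregating_sites()]).
#' @param L_effective number of sites analyzed; defaults to the count of
#'   gap-free alignment columns (matching the default gap policy).
#' @return list of class `diversity_summary`: `S`, `k`, `HHe`, `HHe_sd`,
#'   `pi`, `theta_w`, `theta_pi_total`, `theta_w_total`, `L_effective`, `n`.
#' @export
diversity_summary <- function(aln, sites, L_effective = NULL) {
  n <- n_chromosomes(aln)
  if (n < 2L) stop("need n >= 2")
  if (is.null(L_effective)) {
    m <- aln_matrix(aln)
    L_effective <- sum(apply(m, 2L, function(col) !any(col %in% c("-", "N"))))
  }
  S <- nrow(sites)
  spec <- collapse_haplotypes(aln)
  k <- nrow(spec)
  p <- spec$count / n
  sum2 <- sum(p^2); sum3 <- sum(p^3)
  HHe <- n / (n - 1) * (1 - sum2)
  # Nei (1987) sampling variance of haplotype diversity
  vh <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum3 - sum2^2) + sum2 - sum2^2)
  pi_total <- theta_pi_total(sites)
  a1 <- sum(1 / seq_len(n - 1))
  list_out <- list(S = S, k = k, HHe = HHe, HHe_sd = sqrt(max(vh, 0)),
                   pi = pi_total / L_effective,
                   theta_w = S / (a1 * L_effective),
                   theta_pi_total = pi_total,
                   theta_w_total = S / a1,
                   L_effective = L_effective, n = n)
  class(list_out) <- "diversity_summary"
  list_out
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "S = %d  k = %d  HHe = %.3f (sd %.3f)  pi = %.4g  theta_w = %.4g  (L = %d, n = %d)\n",
    x$S, x$k, x$HHe, x$HHe_sd, x$pi, x$theta_w, x$L_effective, x$n))
  invisible(x)
}

#' Total (per-gene) pairwise diversity from a site table
#' @param sites a `site_table`.
#' @return theta-pi summed over sites (not divided by length).
#' @export
theta_pi_total <- function(sites) {
  n <- site_table_n(sites)
  if (nrow(sites) == 0L) return(0)
  sum(vapply(sites$allele_counts, function(ac) {
    tot <- 0
    cc <- as.numeric(ac)
    for (i in seq_along(cc)) for (j in seq_along(cc))
      if (i < j) tot <- tot + cc[i] * cc[j]
    2 * tot / (n * (n - 1))
  }, numeric(1)))
}

# ---------------------------------------------------------------------------
# Nei-Gojobori 1986 machinery
# ---------------------------------------------------------------------------

.codon_env <- new.env(parent = emptyenv())

codon_aa <- function() {
  if (is.null(.codon_env$map)) {
    bases <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    aa <- vapply(codons, function(cd)
      seqinr::translate(strsplit(cd, "")[[1L]]), character(1))
    .codon_env$map <- stats::setNames(aa, codons)
  }
  .codon_env$map
}

# fractional synonymous sites of one codon (brute force over 9 mutants;
# mutations to stop count as nonsynonymous)
codon_syn_sites <- function(codon) {
  map <- codon_aa()
  aa0 <- map[[codon]]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (b in setdiff(bases, orig)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (map[[mut]] == aa0) s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged (syn, nonsyn) differences between two codons
codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  map <- codon_aa()
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  perms <- if (length(pos) == 1L) list(pos)
  else if (length(pos) == 2L) list(pos, rev(pos))
  else {
    p <- pos
    list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
  }
  syn <- 0; nonsyn <- 0
  for (path in perms) {
    cur <- c1
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (map[[cur]] == map[[nxt]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
  }
  c(syn = syn / length(perms), nonsyn = nonsyn / length(perms))
}

split_codons <- function(seq) {
  L <- nchar(seq)
  substring(seq, seq(1, L, 3), seq(3, L, 3))
}

# codons containing any gap/N in any row of `mats` (list of codon vectors)
usable_codons <- function(codon_lists) {
  k <- length(codon_lists[[1L]])
  ok <- rep(TRUE, k)
  for (cl in codon_lists)
    ok <- ok & !grepl("[^ACGT]", cl)
  ok
}

jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Synonymous / nonsynonymous diversity and divergence (NG86)
#'
#' Counts synonymous and nonsynonymous sites and differences by the
#' Nei-Gojobori (1986) pathway method. Within-sample `piA` and `piS` are the
#' multiplicity-weighted average pairwise nonsynonymous (synonymous)
#' differences per nonsynonymous (synonymous) site, uncorrected. Against an
#' outgroup coding sequence, `Ka` and `Ks` are Jukes-Cantor-corrected NG86
#' proportions between the ingroup consensus and the outgroup (raw
#' proportions are returned alongside).
#'
#' Codons containing a gap or `N` in any haplotype (or the outgroup) are
#' excluded from both site and difference counting (complete deletion).
#'
#' @param cds_aln in-frame coding `hap_alignment` (length divisible by 3).
#' @param outgroup_cds optional outgroup coding sequence (string or
#'   `outgroup`), same frame.
#' @return list of class `coding_stats` with `syn_sites`, `nonsyn_sites`,
#'   `piA`, `piS`, `piA_piS`, `Ka`, `Ks`, `Ka_Ks`, `Ka_raw`, `Ks_raw`,
#'   `Ka_Ks_raw` and undefined-ratio flags.
#' @export
syn_nonsyn_stats <- function(cds_aln, outgroup_cds = NULL) {
  if (cds_aln$L %% 3L != 0L) stop("cds length must be divisible by 3")
  n <- n_chromosomes(cds_aln)
  codons <- lapply(cds_aln$seqs, split_codons)
  og <- NULL
  if (!is.null(outgroup_cds)) {
    og_seq <- if (inherits(outgroup_cds, "outgroup")) outgroup_cds$seq
    else toupper(outgroup_cds)
    if (nchar(og_seq) != cds_aln$L) stop("outgroup cds length mismatch")
    og <- split_codons(og_seq)
  }
  ok <- usable_codons(c(codons, if (!is.null(og)) list(og)))
  codons <- lapply(codons, `[`, ok)
  if (!is.null(og)) og <- og[ok]
  # consensus codons (majority haplotype weighting)
  cons <- vapply(seq_len(sum(ok)), function(j) {
    tab <- tapply(cds_aln$counts, vapply(codons, `[`, character(1), j), sum)
    names(tab)[which.max(tab)]
  }, character(1))
  map <- codon_aa()
  if (any(map[cons] == "*" & seq_along(cons) < length(cons)))
    warning("internal stop codon in consensus cds")
  syn_sites <- sum(vapply(cons, codon_syn_sites, numeric(1)))
  nonsyn_sites <- 3 * length(cons) - syn_sites
  # within-sample pairwise differences, weighted by multiplicities
  hap_k <- length(codons)
  sd_sum <- 0; nd_sum <- 0; wsum <- 0
  if (hap_k >= 2L) {
    for (i in seq_len(hap_k - 1L)) for (j in (i + 1L):hap_k) {
      w <- cds_aln$counts[i] * cds_aln$counts[j]
      diff_pos <- which(codons[[i]] != codons[[j]])
      d <- c(syn = 0, nonsyn = 0)
      for (p in diff_pos) d <- d + codon_diffs(codons[[i]][p], codons[[j]][p])
      sd_sum <- sd_sum + w * d[["syn"]]
      nd_sum <- nd_sum + w * d[["nonsyn"]]
    }
  }
  npairs <- n * (n - 1) / 2
  piS <- (sd_sum / npairs) / syn_sites
  piA <- (nd_sum / npairs) / nonsyn_sites
  out <- list(syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
              piA = piA, piS = piS,
              piA_piS = if (piS > 0) piA / piS else NA_real_,
              piA_piS_undefined = piS == 0)
  if (!is.null(og)) {
    # site counts averaged between consensus and outgroup (NG86)
    syn_og <- sum(vapply(og, codon_syn_sites, numeric(1)))
    Ssites <- (syn_sites + syn_og) / 2
    Nsites <- (3 * length(cons)) - Ssites
    d <- c(syn = 0, nonsyn = 0)
    for (p in which(cons != og)) d <- d + codon_diffs(cons[p], og[p])
    pS <- d[["syn"]] / Ssites
    pN <- d[["nonsyn"]] / Nsites
    out$Ka_raw <- pN; out$Ks_raw <- pS
    out$Ka <- jc_correct(pN); out$Ks <- jc_correct(pS)
    out$Ka_Ks <- if (!is.na(out$Ks) && out$Ks > 0) out$Ka / out$Ks else NA_real_
    out$Ka_Ks_raw <- if (pS > 0) pN / pS else NA_real_
    out$Ka_Ks_undefined <- is.na(out$Ka_Ks)
  }
  class(out) <- "coding_stats"
  out
}

#' McDonald-Kreitman test
#'
#' Contrasts within-sample polymorphism against fixed divergence from an
#' outgroup, partitioned into synonymous and nonsynonymous changes. Fixed
#' differences are positions monomorphic in-sample whose allele differs from
#' the outgroup; polymorphisms are in-sample segregating positions (each
#' classified in the consensus codon context). The p-value is the two-sided
#' Fisher exact test; the neutrality index is `NI = (Pn/Ps) / (Dn/Ds)`.
#'
#' @param cds_aln in-frame coding `hap_alignment`.
#' @param outgroup_cds outgroup coding sequence on the same frame.
#' @return list of class `mk_table`: `table` (2x2: rows syn/nonsyn, columns
#'   polymorphic/divergent), `p`, `NI`, `NI_undefined`.
#' @export
mcdonald_kreitman <- function(cds_aln, outgroup_cds) {
  if (cds_aln$L %% 3L != 0L) stop("cds length must be divisible by 3")
  og_seq <- if (inherits(outgroup_cds, "outgroup")) outgroup_cds$seq
  else toupper(outgroup_cds)
  if (nchar(og_seq) != cds_aln$L) stop("outgroup cds length mismatch")
  codons <- lapply(cds_aln$seqs, split_codons)
  og <- split_codons(og_seq)
  ok <- usable_codons(c(codons, list(og)))
  codons <- lapply(codons, `[`, ok)
  og <- og[ok]
  ncod <- sum(ok)
  map <- codon_aa()
  Ps <- 0; Pn <- 0; Ds <- 0; Dn <- 0
  for (j in seq_len(ncod)) {
    obs <- vapply(codons, `[`, character(1), j)
    tab <- tapply(cds_aln$counts, obs, sum)
    cons <- names(tab)[which.max(tab)]
    if (length(tab) > 1L) {
      # polymorphic codon: classify each observed variant against consensus
      for (alt in setdiff(names(tab), cons)) {
        d <- codon_diffs(cons, alt)
        Ps <- Ps + d[["syn"]]; Pn <- Pn + d[["nonsyn"]]
      }
    } else if (cons != og[j]) {
      d <- codon_diffs(cons, og[j])
      Ds <- Ds + d[["syn"]]; Dn <- Dn + d[["nonsyn"]]
    }
  }
  tab <- matrix(round(c(Ps, Pn, Ds, Dn)), nrow = 2,
                dimnames = list(c("syn", "nonsyn"),
                                c("polymorphic", "divergent")))
  p <- stats::fisher.test(tab)$p.value
  NI <- NA_real_
  undef <- Ps == 0 || Ds == 0 || Dn == 0
  if (!undef) NI <- (Pn / Ps) / (Dn / Ds)
  structure(list(table = tab, p = p, NI = NI, NI_undefined = undef),
            class = "mk_table")
}

#' Translate coding haplotypes and count distinct protein variants
#'
#' @param cds_aln in-frame coding `hap_alignment`.
#' @return data frame `(protein, count)` of distinct translated variants with
#'   summed multiplicities, sorted by count then sequence.
#' @export
protein_variants <- function(cds_aln) {
  if (cds_aln$L %% 3L != 0L) stop("cds length must be divisible by 3")
  prot <- vapply(cds_aln$seqs, function(s)
    paste(seqinr::translate(strsplit(s, "")[[1L]]), collapse = ""),
    character(1))
  tab <- tapply(cds_aln$counts, prot, sum)
  d <- data.frame(protein = names(tab), count = as.integer(tab),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$count, d$protein), , drop = FALSE]
  rownames(d) <- NULL
  d
}
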