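# ---------------------------------------------------------------------------
# Site classification across a paralogue pair, per-region class counts, and
# the spatial / contingency tests used on them.
# ---------------------------------------------------------------------------

SITE_CLASSES <- c("FIXED", "SHARED", "SPECIFIC_A", "SPECIFIC_B", "INVARIANT")

#' Classify sites by coexistence across a paralogue pair
#'
#' For every position of a common alignment frame, a site is `SHARED` when
#' polymorphic in both paralogues, `SPECIFIC_A`/`SPECIFIC_B` when polymorphic
#' in one only, `FIXED` when monomorphic in both but with different alleles,
#' and `INVARIANT` otherwise. The pseudogene (B) dataset often comes as a
#' frequency table rather than full haplotypes, so classification consumes
#' site tables plus per-gene consensus sequences, not alignments.
#'
#' @param sitesA,sitesB `site_table`s of the two paralogues on the same frame.
#' @param consensusA,consensusB consensus (majority) sequence strings of the
#'   two paralogues; used for the monomorphic background.
#' @param maf_threshold sites of gene B whose minor-allele fraction falls
#'   below this are treated as monomorphic before classification (the
#'   external pseudogene data convention); default 0.
#' @return A `site_classification` data frame `(position, class)` covering
#'   every position of the frame.
#' @export
classify_paralogue_sites <- function(sitesA, consensusA, sitesB, consensusB,
                                     maf_threshold = 0) {
  consensusA <- toupper(consensusA); consensusB <- toupper(consensusB)
  L <- nchar(consensusA)
  if (nchar(consensusB) != L)
    stop("consensus sequences differ in length; paralogues must share a frame")
  polyB <- sitesB$position
  if (maf_threshold > 0 && length(polyB)) {
    keep <- vapply(sitesB$allele_counts, function(ac)
      (sum(ac) - max(ac)) / sum(ac) >= maf_threshold, logical(1))
    polyB <- polyB[keep]
  }
  polyA <- sitesA$position
  baseA <- strsplit(consensusA, "", fixed = TRUE)[[1L]]
  baseB <- strsplit(consensusB, "", fixed = TRUE)[[1L]]
  cls <- rep("INVARIANT", L)
  cls[baseA != baseB] <- "FIXED"
  inA <- seq_len(L) %in% polyA
  inB <- seq_len(L) %in% polyB
  cls[inA & !inB] <- "SPECIFIC_A"
  cls[!inA & inB] <- "SPECIFIC_B"
  cls[inA & inB] <- "SHARED"
  out <- data.frame(position = seq_len(L), class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_classification", "data.frame")
  out
}

#' Tabulate site classes per region
#'
#' @param cls a `site_classification`.
#' @param regions a `region_map`; positions outside every interval count
#'   under `"other"`.
#' @return A data frame with one row per region (plus a `total` row) and
#'   columns `fixed`, `shared`, `specific_A`, `specific_B`.
#' @export
count_classes_by_region <- function(cls, regions) {
  lab <- region_of(cls$position, regions)
  labs <- unique(regions$label)
  if (any(lab == "other")) labs <- c(labs, "other")
  count1 <- function(sel) {
    c(fixed = sum(cls$class[sel] == "FIXED"),
      shared = sum(cls$class[sel] == "SHARED"),
      specific_A = sum(cls$class[sel] == "SPECIFIC_A"),
      specific_B = sum(cls$class[sel] == "SPECIFIC_B"))
  }
  rows <- t(vapply(labs, function(l) count1(lab == l), numeric(4)))
  rows <- rbind(rows, total = count1(rep(TRUE, nrow(cls))))
  out <- data.frame(region = rownames(rows), rows, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Write a per-region class-count table as TSV
#' @param tab output of [count_classes_by_region()].
#' @param path output path.
#' @export
write_class_counts <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson chi-square test on an r x c count table
#'
#' Asymptotic Pearson statistic without continuity correction, as used for
#' the region-by-class contrasts.
#'
#' @param tab matrix of non-negative counts, at least 2x2, with positive row
#'   and column sums.
#' @return list with `chi2`, `df`, `p`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal row/column")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Power of the chi-square test at effect size w
#'
#' Standard noncentral formulation: `power = P(chi2_nc(df, ncp = n * w^2) >
#' q)` with `q` the upper-alpha quantile of the central chi-square.
#'
#' @param effect_w Cohen's w effect size (> 0).
#' @param n_total total count.
#' @param df degrees of freedom.
#' @param alpha significance level in (0, 1).
#' @return power in `[0, 1]`.
#' @export
chi2_power <- function(effect_w, n_total, df, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (effect_w <= 0 || n_total <= 0) stop("effect_w and n_total must be > 0")
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = n_total * effect_w^2, lower.tail = FALSE)
}

#' Test spatial uniformity of site positions
#'
#' A continuous one-sample Kolmogorov-Smirnov test of positions against
#' Uniform(0, L), and a Pearson chi-square over equal-width bins whose
#' expected counts are proportional to bin length (the terminal short bin's
#' expectation is scaled accordingly).
#'
#' @param positions site positions in `[1, L]`.
#' @param L frame length.
#' @param bin_width chi-square bin width in bp (default 300, the sliding-
#'   window width).
#' @return list with `ks_D`, `ks_p`, `chi2`, `chi2_p`, `few_sites` (warning
#'   flag set when fewer than 5 positions were supplied).
#' @export
position_uniformity <- function(positions, L, bin_width = 300) {
  if (any(positions < 1 | positions > L)) stop("positions outside [1, L]")
  if (bin_width <= 0) stop("bin_width must be positive")
  few <- length(positions) < 5L
  ks <- suppressWarnings(stats::ks.test(positions, "punif", 0, L))
  breaks <- unique(c(seq(0, L, by = bin_width), L))
  counts <- table(cut(positions, breaks = breaks, include.lowest = TRUE))
  widths <- diff(breaks)
  ch <- suppressWarnings(stats::chisq.test(as.integer(counts),
                                           p = widths / sum(widths)))
  list(ks_D = unname(ks$statistic), ks_p = unname(ks$p.value),
       chi2 = unname(ch$statistic), chi2_p = unname(ch$p.value),
       few_sites = few)
}
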