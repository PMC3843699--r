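# ---------------------------------------------------------------------------
# Distance-based phylogenetics for concerted-evolution diagnostics:
# JC distances, NJ trees, bootstrap support, BootScan-style signal scans,
# Robinson-Foulds topology comparisons.
# ---------------------------------------------------------------------------

JC_SATURATION_SENTINEL <- 5

#' Jukes-Cantor distance matrix
#'
#' Mismatch proportions are computed over gap-free columns (complete
#' deletion: any column containing `-`/`N` in any sequence is removed before
#' comparison) and transformed as `d = -(3/4) ln(1 - (4/3) p)`. Saturated
#' pairs (`p >= 0.75`) get a large sentinel distance and are flagged.
#'
#' @param aln a `hap_alignment` with at least 2 sequences.
#' @return symmetric matrix with zero diagonal, taxon labels as dimnames,
#'   and attribute `saturated` (logical matrix).
#' @export
jc_distance_matrix <- function(aln) {
  if (length(aln$seqs) < 2L) stop("need at least 2 sequences")
  m <- aln_matrix(aln)
  keep <- apply(m, 2L, function(col) !any(col %in% c("-", "N")))
  m <- m[, keep, drop = FALSE]
  if (ncol(m) == 0L) stop("no gap-free columns left after complete deletion")
  k <- nrow(m)
  d <- matrix(0, k, k, dimnames = list(aln$ids, aln$ids))
  sat <- matrix(FALSE, k, k, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    p <- mean(m[i, ] != m[j, ])
    if (p >= 0.75) {
      d[i, j] <- d[j, i] <- JC_SATURATION_SENTINEL
      sat[i, j] <- sat[j, i] <- TRUE
    } else {
      d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix. Negative branch lengths
#' (a known NJ artefact on non-additive inputs) are clamped to zero with the
#' deficit transferred to the adjacent branch at the same node, preserving
#' path lengths through the pair.
#'
#' @param dm symmetric distance matrix with labels (>= 3 taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("NJ needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(dm))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    node <- tr$edge[e, 2L]
    sib <- which(tr$edge[, 1L] == tr$edge[e, 1L] & seq_along(tr$edge[, 2L]) != e)
    if (length(sib)) tr$edge.length[sib[1L]] <-
        max(tr$edge.length[sib[1L]] + deficit, 0)
  }
  tr
}

# non-trivial bipartitions of an unrooted tree as canonical strings
tree_bipartitions <- function(tr) {
  tips <- sort(tr$tip.label)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (p in pp) {
    side <- sort(labs[p])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    other <- setdiff(tips, side)
    key <- if (paste(side, collapse = "|") < paste(other, collapse = "|"))
      paste(side, collapse = "|") else paste(other, collapse = "|")
    out <- c(out, key)
  }
  unique(out)
}

#' Bootstrap support for NJ tree bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds the JC/NJ tree for
#' each replicate, and scores every internal edge of the original tree by
#' the percentage of replicate trees containing its bipartition.
#'
#' @param aln a `hap_alignment`.
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list: `tree` (original NJ tree), `support` (named percentage per
#'   original bipartition key), `B`.
#' @export
bootstrap_support <- function(aln, B = 1000L, seed = 1L) {
  set.seed(seed)
  base_tree <- nj_tree(jc_distance_matrix(aln))
  orig <- tree_bipartitions(base_tree)
  hits <- stats::setNames(numeric(length(orig)), orig)
  m <- aln_matrix(aln)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rb <- hap_alignment(apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""),
                        ids = aln$ids)
    bp <- tryCatch(tree_bipartitions(nj_tree(jc_distance_matrix(rb))),
                   error = function(e) character(0))
    hits[orig %in% bp] <- hits[orig %in% bp] + 1
  }
  list(tree = base_tree, support = 100 * hits / B, B = B)
}

# is the (unrooted) pair a cherry, i.e. separated from all other taxa?
pair_is_clade <- function(tr, pair) {
  i <- match(pair, tr$tip.label)
  p1 <- tr$edge[tr$edge[, 2L] == i[1L], 1L]
  p2 <- tr$edge[tr$edge[, 2L] == i[2L], 1L]
  length(p1) == 1L && length(p2) == 1L && p1 == p2
}

#' BootScan-style phylogenetic signal scan
#'
#' Slides a window along the alignment; within each window, builds `B`
#' bootstrap JC/NJ trees and reports the percentage in which the designated
#' sequence pair forms a clade against all other taxa (pair monophyly = the
#' two tips form a cherry of the unrooted tree).
#'
#' @param aln a `hap_alignment` with at least 4 sequences.
#' @param pair character vector of 2 taxon ids.
#' @param spec a [window_spec()] (default 300/30).
#' @param B bootstrap replicates per window (default 100).
#' @param seed RNG seed.
#' @return data frame `(start, end, midpoint, pct_trees)`.
#' @export
bootscan_signal <- function(aln, pair, spec = window_spec(), B = 100L,
                            seed = 1L) {
  if (length(aln$seqs) < 4L)
    stop("pair monophyly is undefined with fewer than 4 taxa")
  if (!all(pair %in% aln$ids)) stop("pair must name taxa of the alignment")
  set.seed(seed)
  win <- make_windows(aln$L, spec)
  m <- aln_matrix(aln)
  pct <- vapply(seq_len(nrow(win)), function(i) {
    wm <- m[, win$start[i]:win$end[i], drop = FALSE]
    hits <- 0L
    for (b in seq_len(B)) {
      cols <- sample.int(ncol(wm), ncol(wm), replace = TRUE)
      rb <- hap_alignment(apply(wm[, cols, drop = FALSE], 1L, paste,
                                collapse = ""), ids = aln$ids)
      ok <- tryCatch(pair_is_clade(nj_tree(jc_distance_matrix(rb)), pair),
                     error = function(e) FALSE)
      if (ok) hits <- hits + 1L
    }
    100 * hits / B
  }, numeric(1))
  cbind(win, pct_trees = pct)
}

#' Normalized Robinson-Foulds distance
#'
#' Symmetric-difference count of non-trivial bipartitions divided by the
#' maximum attainable for the tip set (`2 (t - 3)` for fully resolved
#' trees); unresolved trees contribute only their present bipartitions while
#' the denominator stays at the resolved maximum, keeping the value in
#' `[0, 1]`.
#'
#' @param t1,t2 `phylo` trees on the same tip set.
#' @return value in `[0, 1]`.
#' @export
robinson_foulds_normalized <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share an identical tip set")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  denom <- 2 * (length(t1$tip.label) - 3)
  if (denom <= 0) return(0)
  length(setdiff(b1, b2)) / denom + length(setdiff(b2, b1)) / denom
}

#' Robinson-Foulds baseline from random topologies
#'
#' Scores `R` uniform random resolved topologies (random sequential
#' addition) against a reference tree and reports the mean normalized RF
#' distance with a normal-approximation 95 percent confidence half-width.
#'
#' @param reference a `phylo` tree (>= 4 tips).
#' @param R number of random trees (default 100).
#' @param seed RNG seed.
#' @return list `mean`, `ci_halfwidth`, `values`.
#' @export
random_rf_baseline <- function(reference, R = 100L, seed = 1L) {
  tips <- reference$tip.label
  if (length(tips) < 4L) stop("need at least 4 tips")
  set.seed(seed)
  vals <- vapply(seq_len(R), function(i) {
    rt <- ape::rtopology(length(tips), rooted = FALSE, tip.label = tips)
    robinson_foulds_normalized(reference, rt)
  }, numeric(1))
  list(mean = mean(vals),
       ci_halfwidth = 1.96 * stats::sd(vals) / sqrt(R),
       values = vals)
}

#' Read / write trees in newick format
#' @param path file path.
#' @rdname newick_io
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @param tree a `phylo` object.
#' @rdname newick_io
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
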