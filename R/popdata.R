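#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Core containers: haplotype alignments, region maps, site tables, outgroups.
# Coordinates are 1-based and closed within the analysis frame; `frame_offset`
# maps internal positions to external labels (external = internal + offset).
# ---------------------------------------------------------------------------

#' Construct a haplotype alignment
#'
#' A haplotype alignment stores one row per *distinct* haplotype together with
#' its multiplicity (number of sampled chromosomes carrying it), so that a
#' sample of, say, 64 chromosomes collapsing to 33 variants is represented
#' without duplicating rows. All sequences must have equal length and use the
#' alphabet `A,C,G,T,-,N`.
#'
#' @param seqs character vector of aligned sequences (equal length).
#' @param ids optional haplotype labels; defaults to `hap1..hapk`.
#' @param counts positive integer multiplicities, one per sequence; default 1.
#' @param frame_offset integer added to internal 1-based positions to obtain
#'   external coordinate labels (default 0).
#' @return An object of class `hap_alignment` with fields `ids`, `seqs`,
#'   `counts`, `L`, `frame_offset`.
#' @export
hap_alignment <- function(seqs, ids = NULL, counts = NULL, frame_offset = 0L) {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 1L) stop("alignment must contain at least one sequence")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences have unequal lengths: ",
                            paste(sort(unique(nchar(seqs))), collapse = ", "))
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) stop("sequence(s) contain symbols outside {A,C,G,T,-,N}: ",
                     paste(which(bad), collapse = ", "))
  if (is.null(ids)) ids <- paste0("hap", seq_along(seqs))
  if (is.null(counts)) counts <- rep(1L, length(seqs))
  counts <- as.integer(counts)
  if (length(counts) != length(seqs) || any(counts < 1L))
    stop("counts must be positive integers, one per sequence")
  if (sum(counts) < 1L) stop("total sample size must be >= 1")
  structure(list(ids = as.character(ids), seqs = seqs, counts = counts,
                 L = as.integer(L), frame_offset = as.integer(frame_offset)),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %d distinct haplotypes, n = %d chromosomes, L = %d bp\n",
              length(x$seqs), n_chromosomes(x), x$L))
  invisible(x)
}

#' Number of sampled chromosomes in an alignment
#' @param aln a `hap_alignment`.
#' @return integer sample size `n` (sum of haplotype multiplicities).
#' @export
n_chromosomes <- function(aln) sum(aln$counts)

# character matrix view; expand = one row per chromosome
aln_matrix <- function(aln, expand = FALSE) {
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  if (expand) m <- m[rep(seq_along(aln$counts), aln$counts), , drop = FALSE]
  m
}

# ---------------------------------------------------------------------------
# Region maps
# ---------------------------------------------------------------------------

#' Construct a region map
#'
#' Named, non-overlapping, 1-based closed intervals labelling parts of the
#' analysis frame. Labels are free-form; the packaged gene layout uses `cds`
#' (a union of exon intervals), `intron2` and `noncds`.
#'
#' @param label character vector of region labels.
#' @param start,end integer interval bounds (1-based, closed).
#' @param L total frame length; intervals must fall within `[1, L]`.
#' @return A `region_map` data frame with attribute `L`.
#' @export
region_map <- function(label, start, end, L) {
  start <- as.integer(start); end <- as.integer(end); L <- as.integer(L)
  if (any(start < 1L) || any(end > L) || any(end < start))
    stop("region intervals must satisfy 1 <= start <= end <= L")
  o <- order(start)
  label <- as.character(label)[o]; start <- start[o]; end <- end[o]
  if (any(start[-1L] <= end[-length(end)]))
    stop("region intervals overlap")
  rm <- data.frame(label = label, start = start, end = end,
                   stringsAsFactors = FALSE)
  attr(rm, "L") <- L
  class(rm) <- c("region_map", "data.frame")
  rm
}

#' Total length covered by each region label
#' @param regions a `region_map`.
#' @return named integer vector of summed interval lengths per label.
#' @export
region_lengths <- function(regions) {
  tapply(regions$end - regions$start + 1L, regions$label, sum)
}

#' Label positions by region
#' @param positions integer positions in the frame.
#' @param regions a `region_map`.
#' @return character vector of labels; positions outside all intervals get
#'   `"other"`.
#' @export
region_of <- function(positions, regions) {
  lab <- rep("other", length(positions))
  for (i in seq_len(nrow(regions))) {
    hit <- positions >= regions$start[i] & positions <= regions$end[i]
    lab[hit] <- regions$label[i]
  }
  lab
}

#' Read / write a region map as BED-like TSV (label, start, end; 1-based closed)
#' @param path file path.
#' @param L frame length.
#' @rdname region_map_io
#' @export
read_region_map <- function(path, L) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  region_map(d$label, d$start, d$end, L = L)
}

#' @param regions a `region_map` to write.
#' @rdname region_map_io
#' @export
write_region_map <- function(regions, path) {
  utils::write.table(as.data.frame(regions)[, c("label", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Site tables
# ---------------------------------------------------------------------------

#' Construct a site table
#'
#' One row per segregating site: position, observed alleles with per-allele
#' chromosome counts, region label, and (after polarization) the ancestral
#' base and derived-allele count.
#'
#' @param position strictly increasing 1-based integer positions.
#' @param allele_counts list of named integer vectors (names = bases), each
#'   summing to `n`.
#' @param n sample size (chromosomes).
#' @param region optional character labels (default `"other"`).
#' @param ancestral optional ancestral base per site (`NA` = unpolarized).
#' @param derived_count optional derived-allele counts in `[1, n-1]`.
#' @param unpolarizable logical flag per site.
#' @return A `site_table` data frame with attribute `n`.
#' @export
site_table <- function(position, allele_counts, n, region = NULL,
                       ancestral = NULL, derived_count = NULL,
                       unpolarizable = NULL) {
  position <- as.integer(position)
  if (is.unsorted(position, strictly = TRUE))
    stop("positions must be strictly increasing (duplicates not allowed)")
  if (length(allele_counts) != length(position))
    stop("allele_counts must have one entry per position")
  sums <- vapply(allele_counts, sum, numeric(1))
  if (length(position) && any(sums != n))
    stop("per-site allele counts must sum to n = ", n)
  k <- length(position)
  st <- data.frame(position = position,
                   region = if (is.null(region)) rep("other", k) else as.character(region),
                   ancestral = if (is.null(ancestral)) rep(NA_character_, k) else as.character(ancestral),
                   derived_count = if (is.null(derived_count)) rep(NA_integer_, k) else as.integer(derived_count),
                   unpolarizable = if (is.null(unpolarizable)) rep(FALSE, k) else as.logical(unpolarizable),
                   stringsAsFactors = FALSE)
  st$allele_counts <- unname(allele_counts)
  dc <- st$derived_count
  if (any(!is.na(dc) & (dc < 1L | dc > n - 1L)))
    stop("derived_count must lie in [1, n-1]")
  attr(st, "n") <- as.integer(n)
  class(st) <- c("site_table", "data.frame")
  st
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("<site_table> S = %d sites, n = %d chromosomes\n",
              nrow(x), attr(x, "n")))
  if (nrow(x)) {
    al <- vapply(x$allele_counts, function(a)
      paste(sprintf("%s:%d", names(a), a), collapse = "/"), character(1))
    print(utils::head(data.frame(position = x$position, alleles = al,
                                 region = x$region,
                                 derived = x$derived_count), 10L))
    if (nrow(x) > 10L) cat("  ...\n")
  }
  invisible(x)
}

site_table_n <- function(sites) attr(sites, "n")

# subset rows of a site table, preserving attributes
st_rows <- function(sites, idx) {
  out <- sites[idx, , drop = FALSE]
  attr(out, "n") <- attr(sites, "n")
  class(out) <- class(sites)
  out
}

#' Assign region labels to site-table rows
#' @param sites a `site_table`.
#' @param regions a `region_map`.
#' @return the site table with its `region` column filled from the map.
#' @export
assign_regions <- function(sites, regions) {
  sites$region <- region_of(sites$position, regions)
  sites
}

# ---------------------------------------------------------------------------
# FASTA I/O
# ---------------------------------------------------------------------------

#' Read a haplotype alignment from FASTA
#'
#' @param path FASTA file of pre-aligned, equal-length sequences.
#' @param counts_from_header if `TRUE`, haplotype multiplicities are parsed
#'   from a `;count=k` suffix on each header (absent suffix = 1).
#' @param frame_offset passed to [hap_alignment()].
#' @return a `hap_alignment`.
#' @export
read_fasta_alignment <- function(path, counts_from_header = FALSE,
                                 frame_offset = 0L) {
  x <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(x) || length(x) == 0L)
    stop("FASTA file is empty or unreadable: ", path)
  seqs <- vapply(as.character(x), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  ids <- names(x)
  counts <- rep(1L, length(seqs))
  if (counts_from_header) {
    has <- grepl(";count=\\d+", ids)
    counts[has] <- as.integer(sub(".*;count=(\\d+).*", "\\1", ids[has]))
    ids <- sub(";count=\\d+", "", ids)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("FASTA records have unequal lengths (", paste(unique(lens), collapse = ", "),
         "); input must be a pre-built alignment")
  hap_alignment(seqs, ids = ids, counts = counts, frame_offset = frame_offset)
}

#' Write a haplotype alignment to FASTA
#' @param aln a `hap_alignment`.
#' @param path output path.
#' @param counts_in_header append `;count=k` to headers so multiplicities
#'   round-trip through [read_fasta_alignment()].
#' @export
write_fasta_alignment <- function(aln, path, counts_in_header = TRUE) {
  hdr <- if (counts_in_header) paste0(aln$ids, ";count=", aln$counts) else aln$ids
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$seqs))
    writeLines(c(paste0(">", hdr[i]), aln$seqs[i]), con)
  invisible(path)
}

#' Read a single-record outgroup FASTA
#' @param path FASTA with one aligned sequence on the same frame.
#' @return list with `id` and `seq` (class `outgroup`).
#' @export
read_outgroup <- function(path) {
  x <- ape::read.FASTA(path)
  if (length(x) != 1L) stop("outgroup FASTA must contain exactly one record")
  structure(list(id = names(x)[1L],
                 seq = paste(toupper(as.character(x)[[1L]]), collapse = "")),
            class = "outgroup")
}

#' Construct an outgroup object from a sequence string
#' @param seq aligned sequence string.
#' @param id species label.
#' @export
outgroup <- function(seq, id = "outgroup") {
  structure(list(id = id, seq = toupper(seq)), class = "outgroup")
}

# ---------------------------------------------------------------------------
# Site-table TSV I/O
# Layout: header "pos\t<p1>\t<p2>...", rows "hapID\t<count>\t<alleles>..."
# (emulates a haplotype-by-site supplementary table).
# ---------------------------------------------------------------------------

#' Read a haplotype-by-site table
#'
#' Reads a TSV whose header row is `pos` followed by 1-based site positions
#' and whose data rows are `hapID`, a multiplicity count, then one allele per
#' site. Returns both a sites-only alignment (columns = the listed positions,
#' in order) and the corresponding [site_table()]. Monomorphic columns are
#' rejected: every listed column must segregate.
#'
#' @param path TSV file path.
#' @return list with elements `aln` (a `hap_alignment` whose
#'   `attr(,"frame_positions")` records the original positions) and `sites`.
#' @export
read_site_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("site table needs a header and at least one row")
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (hdr[1L] != "pos") stop("site table header must start with 'pos'")
  positions <- suppressWarnings(as.integer(hdr[-1L]))
  if (anyNA(positions)) stop("non-integer position in header")
  if (anyDuplicated(positions)) stop("duplicate positions in site table header")
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(vapply(rows, length, integer(1)) != length(positions) + 2L))
    stop("row width does not match header")
  ids <- vapply(rows, `[`, character(1), 1L)
  counts <- as.integer(vapply(rows, `[`, character(1), 2L))
  allele_mat <- do.call(rbind, lapply(rows, function(r) toupper(r[-(1:2)])))
  if (any(!allele_mat %in% c("A", "C", "G", "T", "-")))
    stop("site table alleles must be A/C/G/T or '-'")
  o <- order(positions)
  positions <- positions[o]
  allele_mat <- allele_mat[, o, drop = FALSE]
  aln <- hap_alignment(apply(allele_mat, 1L, paste, collapse = ""),
                       ids = ids, counts = counts)
  attr(aln, "frame_positions") <- positions
  n <- sum(counts)
  ac <- lapply(seq_along(positions), function(j) {
    tab <- tapply(counts, allele_mat[, j], sum)
    stats::setNames(as.integer(tab), names(tab))
  })
  mono <- vapply(ac, length, integer(1)) < 2L
  if (any(mono))
    stop("monomorphic column(s) at position(s): ",
         paste(positions[mono], collapse = ", "))
  list(aln = aln, sites = site_table(positions, ac, n = n))
}

#' Write a haplotype-by-site table
#' @param aln sites-only `hap_alignment` with `frame_positions` attribute (or
#'   positions supplied explicitly).
#' @param path output TSV path.
#' @param positions 1-based positions of the alignment columns.
#' @export
write_site_table <- function(aln, path,
                             positions = attr(aln, "frame_positions")) {
  if (is.null(positions)) positions <- seq_len(aln$L)
  stopifnot(length(positions) == aln$L)
  m <- aln_matrix(aln)
  lines <- c(paste(c("pos", positions), collapse = "\t"),
             vapply(seq_along(aln$ids), function(i)
               paste(c(aln$ids[i], aln$counts[i], m[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Operations
# ---------------------------------------------------------------------------

#' Collapse an alignment to its haplotype spectrum
#'
#' @param aln a `hap_alignment`.
#' @return data frame `(seq, count)` of distinct haplotypes sorted by count
#'   (decreasing) then sequence (lexicographic); counts sum to `n`.
#' @export
collapse_haplotypes <- function(aln) {
  tab <- tapply(aln$counts, aln$seqs, sum)
  d <- data.frame(seq = names(tab), count = as.integer(tab),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$count, d$seq), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Call segregating sites from an alignment
#'
#' Scans alignment columns for polymorphism, applies a minor-allele-frequency
#' cutoff (a site is kept when the non-majority chromosome fraction is at
#' least `maf_threshold`; the boundary case is retained), and handles gapped
#' columns per `gap_policy`. `N` is treated as missing and handled like a gap.
#'
#' @param aln a `hap_alignment` with `n >= 2`.
#' @param maf_threshold fraction in `[0, 0.5)`; default 0 (all polymorphic
#'   columns).
#' @param gap_policy `"drop_column"` (default): any column containing `-`/`N`
#'   is excluded from the table; `"ignore"`: gapped chromosomes are dropped
#'   per column (counts then sum to fewer than n, so the default is safer for
#'   downstream statistics and is used throughout the packaged analyses).
#' @param regions optional `region_map` used to label sites.
#' @return a [site_table()].
#' @export
call_segregating_sites <- function(aln, maf_threshold = 0,
                                   gap_policy = c("drop_column", "ignore"),
                                   regions = NULL) {
  gap_policy <- match.arg(gap_policy)
  n <- n_chromosomes(aln)
  if (n < 2L) stop("need at least 2 chromosomes to call segregating sites")
  if (maf_threshold < 0 || maf_threshold >= 0.5)
    stop("maf_threshold must lie in [0, 0.5)")
  m <- aln_matrix(aln)
  keep_pos <- integer(0); acc <- list()
  for (j in seq_len(aln$L)) {
    col <- m[, j]
    cnt <- aln$counts
    if (any(col %in% c("-", "N"))) {
      if (gap_policy == "drop_column") next
      keep <- !(col %in% c("-", "N"))
      col <- col[keep]; cnt <- cnt[keep]
      if (length(col) == 0L) next
    }
    tab <- tapply(cnt, col, sum)
    if (length(tab) < 2L) next
    tot <- sum(tab)
    if ((tot - max(tab)) / tot < maf_threshold) next
    keep_pos <- c(keep_pos, j)
    acc[[length(acc) + 1L]] <- stats::setNames(as.integer(tab), names(tab))
  }
  st <- site_table(keep_pos, acc, n = n)
  if (!is.null(regions)) st <- assign_regions(st, regions)
  st
}

#' Polarize segregating sites against an outgroup
#'
#' Sets the ancestral base of each site to the outgroup base when the
#' outgroup carries one of the observed ingroup alleles; the derived count is
#' then the number of chromosomes not carrying the ancestral base. Sites
#' where the outgroup base matches no ingroup allele, or is a gap/N, are
#' flagged `unpolarizable` (kept for folded statistics, excluded from the
#' unfolded spectrum).
#'
#' @param sites a `site_table`.
#' @param og an `outgroup` aligned to the same frame, or a plain sequence
#'   string.
#' @return the site table with `ancestral`, `derived_count`, `unpolarizable`
#'   filled in.
#' @export
polarize_sites <- function(sites, og) {
  seq <- if (inherits(og, "outgroup")) og$seq else toupper(og)
  n <- site_table_n(sites)
  bases <- substring(seq, sites$position, sites$position)
  for (i in seq_len(nrow(sites))) {
    ac <- sites$allele_counts[[i]]
    b <- bases[i]
    if (b %in% names(ac)) {
      sites$ancestral[i] <- b
      sites$derived_count[i] <- as.integer(sum(ac) - ac[[b]])
      sites$unpolarizable[i] <- FALSE
    } else {
      sites$ancestral[i] <- NA_character_
      sites$derived_count[i] <- NA_integer_
      sites$unpolarizable[i] <- TRUE
    }
  }
  sites
}

# normalize an interval spec to a two-column integer matrix
as_intervals <- function(intervals) {
  if (is.null(intervals) || (is.data.frame(intervals) && nrow(intervals) == 0L) ||
      length(intervals) == 0L)
    return(cbind(start = integer(0), end = integer(0)))
  if (is.data.frame(intervals))
    return(cbind(start = as.integer(intervals$start),
                 end = as.integer(intervals$end)))
  if (is.matrix(intervals))
    return(cbind(start = as.integer(intervals[, 1L]),
                 end = as.integer(intervals[, 2L])))
  # single c(start, end)
  cbind(start = as.integer(intervals[1L]), end = as.integer(intervals[2L]))
}

#' Keep or drop alignment columns by interval
#'
#' @param aln a `hap_alignment`.
#' @param intervals a data frame / matrix of `(start, end)` 1-based closed
#'   intervals, or a single `c(start, end)`; empty = no columns.
#' @param mode `"keep"` returns the concatenated interval columns in
#'   coordinate order; `"drop"` removes them.
#' @return a `hap_alignment` whose `attr(,"frame_positions")` records the
#'   original frame position of each retained column.
#' @export
subset_columns <- function(aln, intervals, mode = c("keep", "drop")) {
  mode <- match.arg(mode)
  iv <- as_intervals(intervals)
  pos0 <- attr(aln, "frame_positions")
  if (is.null(pos0)) pos0 <- seq_len(aln$L)
  if (nrow(iv) && (any(iv[, 1L] < 1L) || any(iv[, 2L] > max(pos0)) ||
                   any(iv[, 2L] < iv[, 1L])))
    stop("interval out of range [1, ", max(pos0), "]")
  inside <- rep(FALSE, aln$L)
  for (r in seq_len(nrow(iv)))
    inside <- inside | (pos0 >= iv[r, 1L] & pos0 <= iv[r, 2L])
  keep <- if (mode == "keep") which(inside) else which(!inside)
  m <- aln_matrix(aln)[, keep, drop = FALSE]
  out <- hap_alignment(apply(m, 1L, paste, collapse = ""),
                       ids = aln$ids, counts = aln$counts,
                       frame_offset = aln$frame_offset)
  attr(out, "frame_positions") <- pos0[keep]
  out
}

#' Drop site-table rows falling inside tract intervals
#' @param sites a `site_table`.
#' @param tracts intervals as in [subset_columns()].
#' @return the reduced site table.
#' @export
drop_sites_in_tracts <- function(sites, tracts) {
  iv <- as_intervals(tracts)
  inside <- rep(FALSE, nrow(sites))
  for (r in seq_len(nrow(iv)))
    inside <- inside | (sites$position >= iv[r, 1L] & sites$position <= iv[r, 2L])
  st_rows(sites, !inside)
}

#' Read / write conversion-tract intervals (TSV: start, end, label)
#' @param path file path.
#' @rdname tract_io
#' @export
read_tracts <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d[, c("start", "end", intersect("label", names(d)))]
}

#' @param tracts data frame with `start`, `end` and optional `label`.
#' @rdname tract_io
#' @export
write_tracts <- function(tracts, path) {
  if (is.null(tracts$label)) tracts$label <- paste0("tract", seq_len(nrow(tracts)))
  utils::write.table(tracts[, c("start", "end", "label")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged minimum conversion tracts for the emulated gene
#'
#' The two statistically evident non-allelic conversion tracts carried as
#' masking defaults: an intron-2 tract spanning sites 624-634 and a 3'-UTR
#' tract spanning site 3080 plus sites 3102-3186.
#' @return data frame of `(start, end, label)` intervals.
#' @export
default_conversion_tracts <- function() {
  data.frame(start = c(624L, 3080L, 3102L),
             end = c(634L, 3080L, 3186L),
             label = c("intron2_tract", "utr3_tract", "utr3_tract"),
             stringsAsFactors = FALSE)
}
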