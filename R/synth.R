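# ---------------------------------------------------------------------------
# Synthetic-data generator emulating the statistical structure of the
# studied duplicated gene (a 3357-bp functional gene vs its pseudogene):
# region-structured fixed/shared/specific site counts, a conversion-
# suppressed intron, neutral or sweep-skewed frequency spectra, and a
# 33-variant / 64-chromosome haplotype structure. Class counts are planted
# directly; the coalescent module supplies mechanistic neutral nulls.
# ---------------------------------------------------------------------------

#' Packaged gene region layout
#'
#' A synthetic 3357-bp gene layout with a 10-exon coding sequence totalling
#' 1488 bp, a 282-bp intron 2, and 5'/3' flanking plus remaining intronic
#' sequence totalling 1587 bp. The per-label totals match the studied gene;
#' the exon boundaries themselves are approximate (the source data prints
#' only the totals) and are placed so that the packaged conversion tracts
#' (624-634; 3080 and 3102-3186) fall in intron 2 and the 3' UTR
#' respectively.
#'
#' @return a [region_map()] over `L = 3357` with labels `cds`, `intron2`,
#'   `noncds`.
#' @export
default_gene_regions <- function() {
  exon_start <- c(121L, 396L, 778L, 1103L, 1398L, 1733L, 2038L, 2353L, 2678L, 2878L)
  exon_len   <- c(110L, 100L, 160L, 130L, 170L, 140L, 150L, 160L, 180L, 188L)
  starts <- c(1L, exon_start[1L:2L], 496L, exon_start[3L:10L],
              231L, 938L, 1233L, 1568L, 1873L, 2188L, 2513L, 2858L, 3066L)
  ends <- c(120L, exon_start[1L:2L] + exon_len[1L:2L] - 1L, 777L,
            exon_start[3L:10L] + exon_len[3L:10L] - 1L,
            395L, 1102L, 1397L, 1732L, 2037L, 2352L, 2677L, 2877L, 3357L)
  labels <- c("noncds", "cds", "cds", "intron2", rep("cds", 8L),
              rep("noncds", 9L))
  region_map(labels, starts, ends, L = 3357L)
}

# ordered cds positions (concatenated exons)
cds_positions <- function(regions) {
  r <- regions[regions$label == "cds", , drop = FALSE]
  unlist(lapply(seq_len(nrow(r)), function(i) r$start[i]:r$end[i]))
}

#' Synthetic-dataset configuration
#'
#' Defaults reproduce the studied structure: 64 sampled chromosomes of a
#' 3357-bp gene collapsing to 33 distinct haplotypes, with per-region
#' fixed/shared/gene-A-specific site targets equal to the published
#' per-region class counts (intron 2: 17/1/11; other non-coding: 5/3/18;
#' cds: 5/6/5). Pseudogene-side sample size and specific-site targets are
#' not published; the defaults (n_B = 64; specific_B 3/8/5) are package
#' choices.
#'
#' @param L frame length.
#' @param regions a `region_map`.
#' @param n_A,n_B chromosome sample sizes of gene and pseudogene.
#' @param targets data frame with columns `region`, `fixed`, `shared`,
#'   `specific_A`, `specific_B`.
#' @param conversion_suppressed_region region label in which shared
#'   (conversion-proxy) sites are rare and where the sweep-skewed spectrum
#'   is applied.
#' @param sfs_mode `"neutral"` (`P(i) ~ 1/i`) or `"sweep_skewed"` (mixture
#'   with mass near `n-1` inside the suppressed region).
#' @param distinct_haplotype_target distinct gene-A haplotypes (default 33).
#' @param og_syn_codons,og_nonsyn_codons,og_noncds_subs outgroup-private
#'   divergence: numbers of synonymous / nonsynonymous codon substitutions
#'   and of non-coding substitutions carried only by the outgroup (placed at
#'   positions with no planted site, so polarization stays exact). The
#'   synonymous-biased defaults emulate purifying-selection-dominated
#'   interspecies divergence (`Ka/Ks < 1`).
#' @param seed RNG seed (mandatory for reproducibility).
#' @export
synth_config <- function(L = 3357L, regions = default_gene_regions(),
                         n_A = 64L, n_B = 64L,
                         targets = default_class_targets(),
                         conversion_suppressed_region = "intron2",
                         sfs_mode = c("neutral", "sweep_skewed"),
                         distinct_haplotype_target = 33L,
                         og_syn_codons = 30L, og_nonsyn_codons = 10L,
                         og_noncds_subs = 40L,
                         seed = 1L) {
  sfs_mode <- match.arg(sfs_mode)
  stopifnot(all(c("region", "fixed", "shared", "specific_A", "specific_B")
                %in% names(targets)))
  if (any(as.matrix(targets[, -1L]) < 0)) stop("targets must be non-negative")
  rl <- region_lengths(regions)
  need <- tapply(rowSums(targets[, -1L]), targets$region, sum)
  if (any(need > rl[names(need)]))
    stop("class targets exceed region capacity")
  structure(list(L = as.integer(L), regions = regions,
                 n_A = as.integer(n_A), n_B = as.integer(n_B),
                 targets = targets,
                 conversion_suppressed_region = conversion_suppressed_region,
                 sfs_mode = sfs_mode,
                 distinct_haplotype_target = as.integer(distinct_haplotype_target),
                 og_syn_codons = as.integer(og_syn_codons),
                 og_nonsyn_codons = as.integer(og_nonsyn_codons),
                 og_noncds_subs = as.integer(og_noncds_subs),
                 seed = seed),
            class = "synth_config")
}

#' Default per-region class-count targets
#' @return data frame of targets matching the published per-region counts.
#' @export
default_class_targets <- function() {
  data.frame(region = c("intron2", "noncds", "cds"),
             fixed = c(17L, 5L, 5L),
             shared = c(1L, 3L, 6L),
             specific_A = c(11L, 18L, 5L),
             specific_B = c(3L, 8L, 5L),
             stringsAsFactors = FALSE)
}

# draw a derived-allele count from the configured spectrum
draw_derived_count <- function(n, mode) {
  i <- seq_len(n - 1L)
  if (mode == "neutral") {
    sample(i, 1L, prob = 1 / i)
  } else {
    if (stats::runif(1) < 0.7) {
      hi <- max(n - 8L, 2L):(n - 1L)
      sample(hi, 1L)
    } else sample(i, 1L, prob = 1 / i)
  }
}

# multiplicities of k distinct classes summing to n, skewed like real
# haplotype spectra (a few common variants, many singletons)
draw_multiplicities <- function(n, k) {
  counts <- rep(1L, k)
  extra <- n - k
  if (extra > 0L) {
    add <- sample.int(k, extra, replace = TRUE, prob = 1 / seq_len(k))
    tab <- tabulate(add, nbins = k)
    counts <- counts + tab
  }
  sort(counts, decreasing = TRUE)
}

# pick a carrier subset of classes approximating derived chromosome count d
# (greedy over a random class order; with many singleton classes the
# achieved count matches the draw closely)
pick_carriers <- function(mult, d) {
  k <- length(mult)
  ord <- sample.int(k)
  sel <- logical(k)
  tot <- 0L
  for (j in ord) {
    if (tot + mult[j] <= d) {
      sel[j] <- TRUE
      tot <- tot + mult[j]
    }
  }
  if (!any(sel)) {
    smallest <- ord[which.min(mult[ord])]
    sel[smallest] <- TRUE
  }
  if (all(sel)) sel[ord[k]] <- FALSE  # keep the site polymorphic
  sel
}

# codon-design tables for planting cds sites without creating stops
.syn_codons <- c("GGT", "GCT", "GTT", "CTT", "TCT", "CCT", "ACT", "CGT")

other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Generate a paralogue-pair dataset with known truth
#'
#' Plants fixed differences between the two paralogue consensuses, gene-
#' specific polymorphisms with derived counts drawn from the configured
#' spectrum, and shared polymorphisms (identical alleles in both genes), at
#' the per-region target counts; no two events share a position, so the
#' downstream classifier can recover the truth exactly. Coding-region sites
#' are placed inside designed codons: seven of the eleven gene-A cds sites
#' are synonymous third-position changes and four are nonsynonymous, with
#' carrier sets arranged so the sample translates to exactly six protein
#' variants. The outgroup carries the ancestral allele at every planted site
#' (keeping polarization exact) plus its own private substitutions at
#' otherwise-invariant positions, giving realistic synonymous-biased
#' interspecies divergence for the Ka/Ks and McDonald-Kreitman paths. Four
#' gene-A sites are pinned at positions 624/628/630/634 (the intron-2
#' conversion tract) and six at 3080/3102/.../3186 (the 3'-UTR tract) so
#' the packaged masking defaults hit exactly the published site counts.
#'
#' @param cfg a [synth_config()].
#' @return list: `aln_A`, `aln_B` (hap_alignments), `outgroup`, `truth`
#'   (data frame `position`, `class`, `region`, `derived_count_A`),
#'   `regions`, `consensus_A`, `consensus_B`, `cfg`.
#' @export
generate_paralogue_dataset <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  L <- cfg$L
  n_A <- cfg$n_A; n_B <- cfg$n_B
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)

  cdsp <- cds_positions(cfg$regions)
  ncod <- length(cdsp) %/% 3L
  # codon-aware ancestral coding sequence (no stops)
  map <- codon_aa()
  good <- names(map)[map != "*"]
  anc_codons <- sample(good, ncod, replace = TRUE)
  anc[cdsp] <- unlist(strsplit(anc_codons, ""))

  # --- choose site positions per region/class ------------------------------
  tg <- cfg$targets
  used <- logical(L)
  pinned_A <- list(intron2 = c(624L, 628L, 630L, 634L),
                   noncds = c(3080L, 3102L, 3120L, 3140L, 3160L, 3186L))
  # keep the packaged conversion-tract intervals free of random sites so
  # masking them removes exactly the pinned sites
  for (r in seq_len(nrow(default_conversion_tracts()))) {
    tr <- default_conversion_tracts()[r, ]
    if (tr$end <= L) used[tr$start:tr$end] <- TRUE
  }
  region_pos <- lapply(stats::setNames(tg$region, tg$region), function(rg) {
    p <- which(region_of(seq_len(L), cfg$regions) == rg)
    p
  })
  plan <- list()  # rows: position, class, region, meta
  reserve <- function(pos) { used[pos] <<- TRUE; pos }

  # cds planting works at codon granularity
  cds_codon_pool <- sample(seq_len(ncod))
  take_codon <- function() {
    cd <- cds_codon_pool[1L]
    cds_codon_pool <<- cds_codon_pool[-1L]
    cd
  }
  # designed cds polymorphic sites for gene A: 4 nonsynonymous + rest
  # synonymous; shared/specific split follows the targets
  n_cds_polyA <- tg$shared[tg$region == "cds"] + tg$specific_A[tg$region == "cds"]
  ns_slots <- if (n_cds_polyA >= 4L) sample(seq_len(n_cds_polyA), 4L) else integer(0)

  plant_cds_site <- function(is_ns) {
    cd <- take_codon()
    if (is_ns) {
      # lysine AAA -> arginine AGA at codon position 2
      anc[cdsp[(cd - 1L) * 3L + 1:3]] <<- c("A", "A", "A")
      pos <- cdsp[(cd - 1L) * 3L + 2L]
      derived <- "G"
    } else {
      fam <- sample(.syn_codons, 1L)
      third <- sample(bases, 1L)
      anc[cdsp[(cd - 1L) * 3L + 1:3]] <<- c(substr(fam, 1, 1), substr(fam, 2, 2), third)
      pos <- cdsp[(cd - 1L) * 3L + 3L]
      derived <- sample(setdiff(bases, third), 1L)
    }
    list(pos = reserve(pos), derived = derived)
  }

  cds_poly_counter <- 0L
  for (rg in tg$region) {
    for (klass in c("FIXED", "SHARED", "SPECIFIC_A", "SPECIFIC_B")) {
      cnt <- switch(klass, FIXED = tg$fixed, SHARED = tg$shared,
                    SPECIFIC_A = tg$specific_A, SPECIFIC_B = tg$specific_B)
      cnt <- cnt[tg$region == rg]
      if (cnt == 0L) next
      pins <- if (klass == "SPECIFIC_A" && !is.null(pinned_A[[rg]]))
        pinned_A[[rg]] else integer(0)
      for (s in seq_len(cnt)) {
        if (rg == "cds") {
          if (klass %in% c("SHARED", "SPECIFIC_A")) {
            cds_poly_counter <- cds_poly_counter + 1L
            site <- plant_cds_site(cds_poly_counter %in% ns_slots)
            pos <- site$pos; derived <- site$derived
            is_ns <- cds_poly_counter %in% ns_slots
          } else {
            # fixed or B-specific: synonymous-style third-position change
            site <- plant_cds_site(FALSE)
            pos <- site$pos; derived <- site$derived
            is_ns <- FALSE
          }
        } else {
          if (s <= length(pins)) {
            pos <- reserve(pins[s])
          } else {
            free <- region_pos[[rg]][!used[region_pos[[rg]]]]
            pos <- reserve(free[sample.int(length(free), 1L)])
          }
          derived <- other_base(anc[pos])
          is_ns <- FALSE
        }
        plan[[length(plan) + 1L]] <-
          list(position = pos, class = klass, region = rg,
               derived = derived, ns = is_ns)
      }
    }
  }
  plan_df <- if (length(plan)) {
    do.call(rbind, lapply(plan, function(x)
      data.frame(position = x$position, class = x$class, region = x$region,
                 derived = x$derived, ns = x$ns, stringsAsFactors = FALSE)))
  } else {
    data.frame(position = integer(0), class = character(0),
               region = character(0), derived = character(0),
               ns = logical(0), stringsAsFactors = FALSE)
  }
  plan_df <- plan_df[order(plan_df$position), , drop = FALSE]

  # --- outgroup-private divergence (positions free of planted sites) -------
  og_pos <- integer(0); og_base <- character(0)
  for (s in seq_len(cfg$og_syn_codons)) {
    cd <- take_codon()
    fam <- sample(.syn_codons, 1L)
    third <- sample(bases, 1L)
    anc[cdsp[(cd - 1L) * 3L + 1:3]] <- c(substr(fam, 1, 1), substr(fam, 2, 2), third)
    og_pos <- c(og_pos, cdsp[(cd - 1L) * 3L + 3L])
    og_base <- c(og_base, sample(setdiff(bases, third), 1L))
  }
  for (s in seq_len(cfg$og_nonsyn_codons)) {
    cd <- take_codon()
    anc[cdsp[(cd - 1L) * 3L + 1:3]] <- c("A", "A", "A")   # Lys
    og_pos <- c(og_pos, cdsp[(cd - 1L) * 3L + 2L])
    og_base <- c(og_base, "G")                            # Arg
  }
  if (cfg$og_noncds_subs > 0L) {
    pool <- which(!used & region_of(seq_len(L), cfg$regions) != "cds")
    pos <- sample(pool, min(cfg$og_noncds_subs, length(pool)))
    og_pos <- c(og_pos, pos)
    og_base <- c(og_base, vapply(pos, function(p) other_base(anc[p]),
                                 character(1)))
  }
  og_seq <- anc
  og_seq[og_pos] <- og_base

  # --- consensus sequences -------------------------------------------------
  cons_A <- anc
  cons_B <- anc
  fx <- plan_df$position[plan_df$class == "FIXED"]
  cons_B[fx] <- plan_df$derived[plan_df$class == "FIXED"]

  # --- gene A haplotype classes --------------------------------------------
  polyA <- plan_df[plan_df$class %in% c("SHARED", "SPECIFIC_A"), , drop = FALSE]
  kA <- cfg$distinct_haplotype_target
  if (nrow(polyA) == 0L) kA <- 1L  # no polymorphism: a single variant exists
  if (kA > n_A) stop("distinct_haplotype_target cannot exceed n_A")
  if (kA > 2^nrow(polyA) && nrow(polyA) > 0L)
    stop("too few polymorphic sites to realize the haplotype target")
  multA <- draw_multiplicities(n_A, kA)
  # protein groups: 6 variants via structured carriers on the 4 ns sites
  grp <- rep(1L, kA)
  if (kA >= 6L) grp[(kA - 4L):kA] <- 2:6 else grp <- seq_len(kA)
  ns_rows <- which(polyA$ns)
  ns_groups <- list(c(2L, 3L), c(3L, 4L), 5L, 6L)

  build_carriers <- function() {
    carA <- matrix(FALSE, kA, nrow(polyA))
    mode_of <- function(rg) {
      if (cfg$sfs_mode == "sweep_skewed" &&
          rg == cfg$conversion_suppressed_region) "sweep_skewed" else "neutral"
    }
    for (j in seq_len(nrow(polyA))) {
      if (j %in% ns_rows) {
        gset <- ns_groups[[match(j, ns_rows)]]
        carA[, j] <- grp %in% gset
      } else {
        d <- draw_derived_count(n_A, mode_of(polyA$region[j]))
        carA[, j] <- pick_carriers(multA, d)
      }
    }
    carA
  }
  carA <- build_carriers()
  for (try in seq_len(200L)) {
    sigs <- apply(carA, 1L, paste, collapse = "")
    if (!anyDuplicated(sigs)) break
    dup <- which(duplicated(sigs))[1L]
    j <- sample(setdiff(seq_len(nrow(polyA)), ns_rows), 1L)
    carA[dup, j] <- !carA[dup, j]
    if (sum(multA[carA[, j]]) %in% c(0L, n_A)) carA[dup, j] <- !carA[dup, j]
  }
  if (anyDuplicated(apply(carA, 1L, paste, collapse = "")))
    stop("could not make haplotype classes distinct; try another seed")

  seqs_A <- vapply(seq_len(kA), function(h) {
    s <- cons_A
    hit <- which(carA[h, ])
    s[polyA$position[hit]] <- polyA$derived[hit]
    paste(s, collapse = "")
  }, character(1))
  aln_A <- hap_alignment(seqs_A, ids = sprintf("hapA%02d", seq_len(kA)),
                         counts = multA)

  # --- gene B haplotype classes --------------------------------------------
  kB <- min(20L, n_B)
  multB <- draw_multiplicities(n_B, kB)
  polyB <- plan_df[plan_df$class %in% c("SHARED", "SPECIFIC_B"), , drop = FALSE]
  carB <- matrix(FALSE, kB, nrow(polyB))
  for (j in seq_len(nrow(polyB))) {
    d <- draw_derived_count(n_B, "neutral")
    carB[, j] <- pick_carriers(multB, d)
  }
  seqs_B <- vapply(seq_len(kB), function(h) {
    s <- cons_B
    hit <- which(carB[h, ])
    s[polyB$position[hit]] <- polyB$derived[hit]
    paste(s, collapse = "")
  }, character(1))
  aln_B <- hap_alignment(seqs_B, ids = sprintf("hapB%02d", seq_len(kB)),
                         counts = multB)

  derived_A <- rep(NA_integer_, nrow(plan_df))
  ia <- match(polyA$position, plan_df$position)
  derived_A[ia] <- vapply(seq_len(nrow(polyA)), function(j)
    sum(multA[carA[, j]]), integer(1))

  truth <- data.frame(position = plan_df$position, class = plan_df$class,
                      region = plan_df$region,
                      derived_count_A = derived_A,
                      nonsynonymous = plan_df$ns,
                      stringsAsFactors = FALSE)
  list(aln_A = aln_A, aln_B = aln_B,
       outgroup = outgroup(paste(og_seq, collapse = ""), id = "synthetic_outgroup"),
       truth = truth, regions = cfg$regions,
       consensus_A = paste(cons_A, collapse = ""),
       consensus_B = paste(cons_B, collapse = ""),
       cfg = cfg)
}

#' Majority-consensus sequence of an alignment
#' @param aln a `hap_alignment`.
#' @return consensus string (multiplicity-weighted majority base per column;
#'   ties broken alphabetically).
#' @export
consensus_seq <- function(aln) {
  m <- aln_matrix(aln)
  paste(apply(m, 2L, function(col) {
    tab <- tapply(aln$counts, col, sum)
    names(tab)[which.max(tab)]
  }), collapse = "")
}

#' Generate a neutral coalescent dataset as sequences
#'
#' Simulates one genealogy under the demography, drops `S` mutations, and
#' materializes the sample as sequences on a random `L`-bp frame with
#' uniformly placed segregating sites; the returned outgroup carries the
#' ancestral allele everywhere.
#'
#' @param n sample size; @param S segregating sites; @param demography a
#'   `demography_model`; @param seed RNG seed; @param L frame length.
#' @return list `aln` (one row per distinct haplotype, multiplicities set),
#'   `outgroup`, `positions`.
#' @export
generate_neutral_dataset <- function(n, S, demography = constant_demography(),
                                     seed = 1L, L = 3357L) {
  set.seed(seed)
  tree <- simulate_genealogy(n, demography)
  branches <- which(tree$parent > 0L)
  hit <- branches[sample.int(length(branches), S, replace = TRUE,
                             prob = tree$branch_length[branches])]
  positions <- sort(sample.int(L, S))
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  derived <- vapply(positions, function(p) other_base(anc[p]), character(1))
  mutated_nodes <- unique(hit)
  carries <- matrix(FALSE, n, S)
  for (l in seq_len(n)) {
    v <- l
    while (tree$parent[v] > 0L) {
      if (v %in% mutated_nodes) carries[l, which(hit == v)] <- TRUE
      v <- tree$parent[v]
    }
  }
  seqs <- vapply(seq_len(n), function(l) {
    s <- anc
    s[positions[carries[l, ]]] <- derived[carries[l, ]]
    paste(s, collapse = "")
  }, character(1))
  tab <- table(seqs)
  aln <- hap_alignment(names(tab), ids = sprintf("sim%02d", seq_along(tab)),
                       counts = as.integer(tab))
  list(aln = aln, outgroup = outgroup(paste(anc, collapse = ""), "ancestor"),
       positions = positions)
}

#' Compare recovered classification against generator truth
#'
#' @param truth truth table from [generate_paralogue_dataset()].
#' @param cls a `site_classification` on the same frame.
#' @return list: `confusion` (truth x recovered count matrix over the
#'   planted positions), `exact_match` (`TRUE` iff every planted site is
#'   recovered with its generated class and no extra non-invariant call
#'   appears elsewhere).
#' @export
recovery_report <- function(truth, cls) {
  if (nrow(truth) == 0L)
    return(list(confusion = matrix(0L, 0L, 0L), exact_match = TRUE))
  rec <- cls$class[match(truth$position, cls$position)]
  confusion <- table(truth = truth$class, recovered = rec)
  extra <- setdiff(cls$position[cls$class != "INVARIANT"], truth$position)
  exact <- all(truth$class == rec) && length(extra) == 0L
  list(confusion = confusion, exact_match = exact)
}
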