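# ---------------------------------------------------------------------------
# End-to-end orchestration: per-region summary block (a Table-1-shaped
# report), window tracks, class-count contrasts, rejection probabilities.
# ---------------------------------------------------------------------------

#' Analysis configuration
#'
#' @param aln_A gene-A `hap_alignment` (or FASTA path).
#' @param sites_B_table pseudogene data: a `site_table`, or a path to a
#'   haplotype-by-site TSV.
#' @param consensus_B pseudogene consensus sequence (required when
#'   `sites_B_table` is a bare site table).
#' @param og outgroup (object or FASTA path); `NULL` skips polarization (H
#'   and nH then undefined).
#' @param regions a `region_map` (or TSV path).
#' @param tracts conversion tracts (data frame or TSV path); `NULL` skips
#'   the masked rerun.
#' @param wspec a [window_spec()].
#' @param demography a `demography_model`.
#' @param replicates simulation replicates per null model.
#' @param seed seed for all randomness (mandatory when simulations run).
#' @param maf_threshold minor-allele-frequency cutoff applied to both genes.
#' @param ew_reps Monte-Carlo replicates for the Ewens-Watterson test.
#' @export
analysis_config <- function(aln_A, sites_B_table, consensus_B = NULL,
                            og = NULL, regions, tracts = NULL,
                            wspec = window_spec(),
                            demography = european_demography(),
                            replicates = 2000L, seed = 1L,
                            maf_threshold = 0.01, ew_reps = 1000L) {
  structure(list(aln_A = aln_A, sites_B_table = sites_B_table,
                 consensus_B = consensus_B, og = og, regions = regions,
                 tracts = tracts, wspec = wspec, demography = demography,
                 replicates = as.integer(replicates), seed = seed,
                 maf_threshold = maf_threshold,
                 ew_reps = as.integer(ew_reps)),
            class = "analysis_config")
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE))
}

#' Run the full paralogue analysis
#'
#' Calls segregating sites on the gene alignment, polarizes against the
#' outgroup, classifies sites against the pseudogene, and produces: a
#' per-region summary block (diversity + neutrality statistics + class
#' counts), pairwise region chi-square contrasts, sliding-window tracks,
#' rejection probabilities under neutral and demographic nulls, and a
#' conversion-masked rerun. All outputs are returned and, when `out_dir` is
#' given, written as TSV.
#'
#' @param cfg an [analysis_config()].
#' @param out_dir optional output directory.
#' @return list of class `analysis_report` with components `summary`,
#'   `class_counts`, `chi2_contrasts`, `windows`, `rejections`, `masked`,
#'   `seed`.
#' @export
run_full_analysis <- function(cfg, out_dir = NULL) {
  aln <- stage("input", {
    if (is.character(cfg$aln_A)) read_fasta_alignment(cfg$aln_A,
                                                      counts_from_header = TRUE)
    else cfg$aln_A
  })
  regions <- stage("regions", {
    if (is.null(cfg$regions)) stop("config field 'regions' is missing")
    if (is.character(cfg$regions)) read_region_map(cfg$regions, L = aln$L)
    else cfg$regions
  })
  og <- stage("outgroup", {
    if (is.character(cfg$og)) read_outgroup(cfg$og) else cfg$og
  })
  bdat <- stage("paralogue_b", {
    st <- if (is.character(cfg$sites_B_table))
      read_site_table(cfg$sites_B_table)$sites else cfg$sites_B_table
    if (is.null(cfg$consensus_B))
      stop("config field 'consensus_B' is missing (needed for fixed-site calls)")
    list(sites = st, consensus = cfg$consensus_B)
  })
  tracts <- stage("tracts", {
    if (is.character(cfg$tracts)) read_tracts(cfg$tracts) else cfg$tracts
  })

  sites <- stage("segregating_sites", {
    s <- call_segregating_sites(aln, maf_threshold = cfg$maf_threshold,
                                regions = regions)
    if (!is.null(og)) s <- polarize_sites(s, og) else s
  })
  cls <- stage("classification",
               classify_paralogue_sites(sites, consensus_seq(aln),
                                        bdat$sites, bdat$consensus,
                                        maf_threshold = cfg$maf_threshold))
  class_counts <- count_classes_by_region(cls, regions)

  # per-region summary block
  labs <- unique(regions$label)
  summary_rows <- lapply(c("full", labs), function(lab) {
    if (lab == "full") {
      sub_aln <- aln; sub_sites <- sites
    } else {
      iv <- regions[regions$label == lab, c("start", "end")]
      sub_aln <- subset_columns(aln, iv, mode = "keep")
      sub_sites <- st_rows(sites, sites$region == lab)
    }
    ds <- diversity_summary(sub_aln, sub_sites)
    ns <- neutrality_stats(sub_aln, sub_sites, ew_reps = cfg$ew_reps,
                           ew_seed = seed_offset(cfg$seed, match(lab, c("full", labs))))
    data.frame(region = lab, length = sub_aln$L, S = ds$S, k = ds$k,
               HHe = ds$HHe, HHe_sd = ds$HHe_sd, pi = ds$pi,
               theta_w = ds$theta_w, D = ns$D, Fs = ns$Fs, H = ns$H,
               nH = ns$nH, EW = ns$EW_F, EW_p = ns$EW_p,
               stringsAsFactors = FALSE)
  })
  summary_df <- do.call(rbind, summary_rows)

  # pairwise region chi-square contrasts on (fixed, shared, specific_A)
  chi_rows <- list()
  cc <- class_counts[class_counts$region %in% labs, , drop = FALSE]
  tot <- class_counts[class_counts$region == "total", , drop = FALSE]
  take <- function(row) as.numeric(row[, c("fixed", "shared", "specific_A")])
  for (i in seq_along(labs)) {
    rest <- take(tot) - take(cc[i, ])
    if (all(take(cc[i, ]) + rest > 0)) {
      ct <- stage("chi2", pearson_chi2(rbind(take(cc[i, ]), rest)))
      chi_rows[[length(chi_rows) + 1L]] <-
        data.frame(contrast = paste0(labs[i], "_vs_rest"),
                   chi2 = ct$chi2, df = ct$df, p = ct$p)
    }
    if (i < length(labs)) for (j in (i + 1L):length(labs)) {
      ct <- stage("chi2", pearson_chi2(rbind(take(cc[i, ]), take(cc[j, ]))))
      chi_rows[[length(chi_rows) + 1L]] <-
        data.frame(contrast = paste0(labs[i], "_vs_", labs[j]),
                   chi2 = ct$chi2, df = ct$df, p = ct$p)
    }
  }
  chi_df <- do.call(rbind, chi_rows)

  windows <- stage("windows",
                   window_track(aln, sites, cls, spec = cfg$wspec))

  rejections <- stage("rejection",
                      rejection_report(aln, sites, cfg$demography,
                                       replicates = cfg$replicates,
                                       seed = seed_offset(cfg$seed, 100L)))
  masked <- NULL
  if (!is.null(tracts))
    masked <- stage("masked_rerun",
                    masked_rerun(aln, sites, tracts, cfg$demography,
                                 replicates = cfg$replicates,
                                 seed = seed_offset(cfg$seed, 200L)))

  rep_out <- structure(list(summary = summary_df, class_counts = class_counts,
                            chi2_contrasts = chi_df, windows = windows,
                            rejections = rejections, masked = masked,
                            seed = cfg$seed),
                       class = "analysis_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE, na = "")
    w(summary_df, "summary.tsv")
    w(class_counts, "class_counts.tsv")
    w(chi_df, "chi2_contrasts.tsv")
    w(windows, "windows.tsv")
    w(rejections, "rejections.tsv")
    if (!is.null(masked)) w(masked$report, "masked_rejections.tsv")
    writeLines(c(sprintf("paraldiv %s", as.character(utils::packageVersion("paraldiv"))),
                 sprintf("R %s", R.version.string),
                 sprintf("seed %s", format(cfg$seed)),
                 sprintf("replicates %d", cfg$replicates),
                 sprintf("maf_threshold %g", cfg$maf_threshold)),
               file.path(out_dir, "run_log.txt"))
  }
  rep_out
}

# derive a distinct but reproducible sub-seed (kept below 2^31)
seed_offset <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}
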