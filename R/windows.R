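# ---------------------------------------------------------------------------
# Sliding-window engine. Window coordinates refer to the alignment frame
# (nucleotide positions), not to segregating-site indices.
# ---------------------------------------------------------------------------

#' Sliding-window specification
#' @param width window width in bp (default 300).
#' @param step step in bp (default 30); `0 < step <= width`.
#' @param edge_rule `"drop_partial"` (default): only full-width windows;
#'   `"truncate_last"`: append a final short window covering the tail.
#' @export
window_spec <- function(width = 300L, step = 30L,
                        edge_rule = c("drop_partial", "truncate_last")) {
  edge_rule <- match.arg(edge_rule)
  if (step <= 0 || step > width) stop("need 0 < step <= width")
  structure(list(width = as.integer(width), step = as.integer(step),
                 edge_rule = edge_rule), class = "window_spec")
}

#' Enumerate window intervals over a frame
#' @param L frame length (`L >= width`).
#' @param spec a [window_spec()].
#' @return data frame `(start, end, midpoint)`.
#' @export
make_windows <- function(L, spec = window_spec()) {
  if (L < spec$width) stop("L must be at least the window width")
  starts <- seq(1L, L - spec$width + 1L, by = spec$step)
  ends <- starts + spec$width - 1L
  if (spec$edge_rule == "truncate_last" && max(ends) < L) {
    starts <- c(starts, max(starts) + spec$step)
    ends <- c(ends, L)
  }
  data.frame(start = starts, end = ends, midpoint = (starts + ends) / 2)
}

#' Sliding-window statistic track
#'
#' Restricts the site table (and optionally the paralogue site
#' classification) to each window and computes the requested statistics
#' through the diversity/neutrality code. Windows without segregating sites
#' report `S = 0`, `pi = 0` and `NA` for D and H (undefined, not zero).
#'
#' @param aln a `hap_alignment` (for `n` and window length bookkeeping).
#' @param sites a (polarized, if H is requested) `site_table`.
#' @param classification optional `site_classification` for per-window class
#'   counts.
#' @param spec a [window_spec()].
#' @param which statistics to compute, subset of
#'   `c("S", "pi", "D", "H", "classes")`.
#' @return data frame, one row per window: `start`, `end`, `midpoint`, plus
#'   requested columns (`pi` is per site within the window).
#' @export
window_track <- function(aln, sites, classification = NULL,
                         spec = window_spec(),
                         which = c("S", "pi", "D", "H", "classes")) {
  which <- match.arg(which, several.ok = TRUE)
  win <- make_windows(aln$L, spec)
  n <- n_chromosomes(aln)
  rows <- lapply(seq_len(nrow(win)), function(i) {
    a <- win$start[i]; b <- win$end[i]
    inw <- sites$position >= a & sites$position <= b
    sw <- st_rows(sites, inw)
    S <- nrow(sw)
    out <- list()
    if ("S" %in% which) out$S <- S
    if ("pi" %in% which) out$pi <- theta_pi_total(sw) / (b - a + 1)
    if ("D" %in% which)
      out$D <- if (S >= 1L) tajimas_d(S, theta_pi_total(sw), n)$D else NA_real_
    if ("H" %in% which) {
      sp <- sfs_from_sites(sw, n = n)
      out$H <- if (sp$S >= 1L) fay_wu_h(sp)$H else NA_real_
    }
    if ("classes" %in% which && !is.null(classification)) {
      cw <- classification$class[classification$position >= a &
                                   classification$position <= b]
      out$fixed <- sum(cw == "FIXED")
      out$shared <- sum(cw == "SHARED")
      out$specific_A <- sum(cw == "SPECIFIC_A")
      out$specific_B <- sum(cw == "SPECIFIC_B")
    }
    out
  })
  cbind(win, do.call(rbind, lapply(rows, as.data.frame)))
}

#' Write a window track as TSV (undefined values as empty fields)
#' @param track output of [window_track()] or [bootscan_signal()].
#' @param path output path.
#' @export
write_window_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
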