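# ---------------------------------------------------------------------------
# Coalescent simulation under piecewise demography, simulation-based
# rejection probabilities, and conversion-masked reruns.
# Time runs backward in generations; Ne is the diploid effective size, so a
# pair of lineages coalesces at rate 1/(2 Ne(t)) per generation.
# ---------------------------------------------------------------------------

#' Construct a piecewise demography model
#'
#' Epochs are contiguous intervals of backward time `[t0, t1)` in
#' generations. Within an epoch the population size either stays constant at
#' `Ne_start` or moves exponentially from `Ne_start` (at `t0`, the recent
#' boundary) to `Ne_end` (at `t1`). The final epoch must be constant and
#' extend to infinity.
#'
#' @param epochs data frame with columns `t0`, `t1`, `Ne_start`, `Ne_end`.
#' @param generation_time_years used only for annotation/config round-trips.
#' @return object of class `demography_model`.
#' @export
demography_model <- function(epochs, generation_time_years = 25) {
  stopifnot(all(c("t0", "t1", "Ne_start", "Ne_end") %in% names(epochs)))
  epochs <- epochs[order(epochs$t0), , drop = FALSE]
  if (epochs$t0[1L] != 0) stop("first epoch must start at 0")
  if (!all(abs(epochs$t0[-1L] - epochs$t1[-nrow(epochs)]) < 1e-9))
    stop("epochs must be contiguous")
  if (is.finite(epochs$t1[nrow(epochs)]))
    stop("last epoch must extend to infinity")
  if (epochs$Ne_start[nrow(epochs)] != epochs$Ne_end[nrow(epochs)])
    stop("last epoch must be constant")
  if (any(epochs$Ne_start <= 0 | epochs$Ne_end <= 0)) stop("Ne must be > 0")
  structure(list(epochs = epochs,
                 generation_time_years = generation_time_years),
            class = "demography_model")
}

#' Constant-size demography
#' @param Ne diploid effective size.
#' @export
constant_demography <- function(Ne = 10000) {
  demography_model(data.frame(t0 = 0, t1 = Inf, Ne_start = Ne, Ne_end = Ne))
}

#' European bottleneck-and-expansion demography
#'
#' The preset carries a bottleneck at effective size 1861 between 51 and 21
#' thousand years before present, exponential regrowth from the bottleneck
#' size back to the present-day size over the last 21 thousand years, and a
#' constant ancestral population before the bottleneck. Published European
#' demographic models of this family state only the bottleneck size and
#' dates; the ancestral and present-day sizes (10,000) and the 25-year
#' generation time are package defaults consistent with that demographic
#' literature, and all four are arguments.
#'
#' @param Ne_present diploid size at time 0 (default 10000).
#' @param Ne_bottleneck bottleneck size (default 1861).
#' @param Ne_ancestral pre-bottleneck size (default 10000).
#' @param t_expansion_years,t_bottleneck_years epoch boundaries in years
#'   before present (defaults 21000 and 51000).
#' @param generation_time_years years per generation (default 25, giving
#'   epoch boundaries at 840 and 2040 generations).
#' @return a `demography_model`.
#' @export
european_demography <- function(Ne_present = 10000, Ne_bottleneck = 1861,
                                Ne_ancestral = 10000,
                                t_expansion_years = 21000,
                                t_bottleneck_years = 51000,
                                generation_time_years = 25) {
  g1 <- t_expansion_years / generation_time_years
  g2 <- t_bottleneck_years / generation_time_years
  demography_model(data.frame(
    t0 = c(0, g1, g2), t1 = c(g1, g2, Inf),
    Ne_start = c(Ne_present, Ne_bottleneck, Ne_ancestral),
    Ne_end = c(Ne_bottleneck, Ne_bottleneck, Ne_ancestral)),
    generation_time_years = generation_time_years)
}

#' Read / write a demography configuration (key-value text)
#'
#' Format: one `key<TAB>value` pair per line with keys
#' `epoch.<i>.t0_years`, `epoch.<i>.t1_years`, `epoch.<i>.Ne_start`,
#' `epoch.<i>.Ne_end`, plus `generation_time_years`; the single value
#' `preset<TAB>european_default` selects [european_demography()].
#' @param path file path.
#' @rdname demography_io
#' @export
read_demography <- function(path) {
  kv <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("key", "value"))
  vals <- stats::setNames(kv$value, kv$key)
  if (!is.na(vals["preset"]) && vals[["preset"]] == "european_default")
    return(european_demography())
  gt <- as.numeric(vals[["generation_time_years"]])
  idx <- sort(unique(as.integer(sub("^epoch\\.(\\d+)\\..*$", "\\1",
                                    grep("^epoch\\.", names(vals), value = TRUE)))))
  ep <- do.call(rbind, lapply(idx, function(i) {
    g <- function(f) as.numeric(vals[[paste0("epoch.", i, ".", f)]])
    data.frame(t0 = g("t0_years") / gt, t1 = g("t1_years") / gt,
               Ne_start = g("Ne_start"), Ne_end = g("Ne_end"))
  }))
  demography_model(ep, generation_time_years = gt)
}

# pair coalescent intensity accumulated across [t, t + dt] and its inverse.
# epoch-local: u measured from epoch t0; Ne(u) = Ne_start * exp(g u).
epoch_growth_rate <- function(ep) {
  if (ep$Ne_start == ep$Ne_end || !is.finite(ep$t1)) return(0)
  log(ep$Ne_end / ep$Ne_start) / (ep$t1 - ep$t0)
}

epoch_intensity <- function(ep, u1, u2) {
  g <- epoch_growth_rate(ep)
  if (g == 0) return((u2 - u1) / (2 * ep$Ne_start))
  (exp(-g * u1) - exp(-g * u2)) / (2 * ep$Ne_start * g)
}

epoch_invert <- function(ep, u1, x) {
  g <- epoch_growth_rate(ep)
  if (g == 0) return(u1 + 2 * ep$Ne_start * x)
  -log(exp(-g * u1) - 2 * ep$Ne_start * g * x) / g
}

# advance backward time from t by pair-intensity x under the demography
advance_time <- function(dem, t, x) {
  ep <- dem$epochs
  for (i in seq_len(nrow(ep))) {
    row <- ep[i, ]
    if (t >= row$t1) next
    u1 <- max(t - row$t0, 0)
    u2 <- row$t1 - row$t0
    avail <- if (is.finite(row$t1)) epoch_intensity(row, u1, u2) else Inf
    if (x <= avail) return(row$t0 + epoch_invert(row, u1, x))
    x <- x - avail
    t <- row$t1
  }
  stop("demography does not cover requested time")  # unreachable
}

#' Simulate one coalescent genealogy
#'
#' Standard n-coalescent with piecewise population-size rescaling;
#' exponential epochs are integrated in closed form. Uses the current RNG
#' state (seed upstream).
#'
#' @param n sample size (tips).
#' @param demography a `demography_model`.
#' @return list of class `coal_tree`: `n`, `parent` (length `2n-1`, 0 at the
#'   root), `node_time` (coalescence times, generations), `branch_length`
#'   per node (to its parent), `leaf_count` per node, `total_length`.
#' @export
simulate_genealogy <- function(n, demography) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  leaf_count <- c(rep(1L, n), integer(n - 1L))
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  for (j in seq(n, 2L)) {
    x <- stats::rexp(1) / (j * (j - 1) / 2)
    t <- advance_time(demography, t, x)
    pick <- sample.int(length(active), 2L)
    ch <- active[pick]
    parent[ch] <- nxt
    node_time[nxt] <- t
    leaf_count[nxt] <- sum(leaf_count[ch])
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  branch_length <- numeric(n_nodes)
  has_parent <- parent > 0L
  branch_length[has_parent] <- node_time[parent[has_parent]] -
    node_time[has_parent]
  structure(list(n = n, parent = parent, node_time = node_time,
                 branch_length = branch_length, leaf_count = leaf_count,
                 total_length = sum(branch_length)),
            class = "coal_tree")
}

#' Drop mutations on a genealogy
#'
#' Infinite-sites mutation: each of `S` mutations falls on a branch with
#' probability proportional to branch length; the derived allele is carried
#' by the branch's descendant leaves (the root state is ancestral, so the
#' spectrum is unfolded).
#'
#' @param tree a `coal_tree`.
#' @param S number of mutations (fixed-S conditioning).
#' @return list: `xi` (unfolded SFS counts, length `n-1`), `S`, `k` (distinct
#'   haplotypes), `hap_counts` (multiplicities of the distinct haplotypes).
#' @export
mutate_fixed_s <- function(tree, S) {
  n <- tree$n
  if (S == 0L)
    return(list(xi = integer(n - 1L), S = 0L, k = 1L, hap_counts = n))
  branches <- which(tree$parent > 0L)
  hit <- branches[sample.int(length(branches), S, replace = TRUE,
                             prob = tree$branch_length[branches])]
  xi <- tabulate(tree$leaf_count[hit], nbins = n - 1L)
  mutated <- logical(2L * n - 1L)
  mutated[hit] <- TRUE
  sig <- character(n)
  for (l in seq_len(n)) {
    v <- l
    path <- integer(0)
    while (tree$parent[v] > 0L) {
      if (mutated[v]) path <- c(path, v)
      v <- tree$parent[v]
    }
    sig[l] <- paste(path, collapse = ",")
  }
  tab <- table(sig)
  list(xi = xi, S = as.integer(S), k = length(tab),
       hap_counts = as.integer(tab))
}

#' Simulation configuration
#'
#' @param n sample size; @param replicates replicate count; @param seed RNG
#'   seed (mandatory).
#' @param S fixed mutation count per replicate (fixed-S conditioning,
#'   the default null used throughout) or `NULL` to use `theta`.
#' @param theta scaled mutation parameter `4 Ne u` per locus for Poisson
#'   mutation numbers (calibration mode); `Ne` is the present-day size.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n, replicates, seed, S = NULL, theta = NULL) {
  if (is.null(S) == is.null(theta))
    stop("exactly one of S or theta must be given")
  if (n < 2L) stop("n must be >= 2")
  structure(list(n = as.integer(n), replicates = as.integer(replicates),
                 seed = seed, S = S, theta = theta),
            class = "sim_config")
}

#' Simulate replicate neutrality statistics
#'
#' Runs `replicates` genealogy-plus-mutation draws and computes Tajima's D,
#' Fu's Fs, Fay and Wu's H, normalized H, theta-pi and the haplotype count
#' per replicate via the same statistic code used on observed data.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param demography a `demography_model`.
#' @return data frame with one row per replicate: `S`, `k`, `theta_pi`, `D`,
#'   `Fs`, `H`, `nH`, `tmrca`, `total_length`.
#' @export
simulate_replicates <- function(config, demography) {
  set.seed(config$seed)
  n <- config$n
  R <- config$replicates
  u_rate <- if (!is.null(config$theta))
    config$theta / (4 * demography$epochs$Ne_start[1L]) else NULL
  if (n >= 4L) log_stirling1(n)  # warm the cache outside the loop
  out <- vector("list", R)
  for (r in seq_len(R)) {
    tree <- simulate_genealogy(n, demography)
    S_r <- if (!is.null(config$S)) config$S
    else stats::rpois(1, u_rate * tree$total_length)
    mt <- mutate_fixed_s(tree, S_r)
    sp <- sfs(mt$xi, n = n)
    tp <- sfs_theta_pi(sp)
    D <- if (n >= 4L && S_r >= 1L) tajimas_d(S_r, tp, n)$D else NA_real_
    Fs <- if (tp > 0) fus_fs(n, mt$k, tp)$Fs else NA_real_
    h <- fay_wu_h(sp)
    nh <- zeng_nh(sp)
    out[[r]] <- c(S = S_r, k = mt$k, theta_pi = tp, D = D, Fs = Fs,
                  H = h$H, nH = nh$nH,
                  tmrca = max(tree$node_time),
                  total_length = tree$total_length)
  }
  as.data.frame(do.call(rbind, out))
}

#' One-tailed simulation rejection probability
#'
#' Add-one estimator `p = (1 + #{replicates <= observed}) / (R + 1)` for the
#' lower tail (symmetric for the upper), so p is never exactly zero.
#'
#' @param observed observed statistic value.
#' @param replicate_values statistic values from [simulate_replicates()]
#'   (non-finite values are dropped).
#' @param tail `"lower"` (default; rejection for small values, the
#'   convention for D, Fs, H, nH) or `"upper"`.
#' @return p in (0, 1].
#' @export
rejection_probability <- function(observed, replicate_values,
                                  tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  v <- replicate_values[is.finite(replicate_values)]
  R <- length(v)
  if (R < 1L) stop("no finite replicate values")
  hits <- if (tail == "lower") sum(v <= observed) else sum(v >= observed)
  (1 + hits) / (R + 1)
}

# observed statistics + rejection probabilities against one simulated null
rejection_block <- function(stats_obs, reps, model_label) {
  grab <- function(name) {
    obs <- stats_obs[[name]]
    if (!is.finite(obs)) return(c(observed = obs, p = NA_real_))
    c(observed = obs,
      p = rejection_probability(obs, reps[[name]], tail = "lower"))
  }
  m <- t(vapply(c("D", "Fs", "H", "nH"), grab, numeric(2)))
  data.frame(statistic = rownames(m), m, model = model_label,
             replicates = nrow(reps), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rejection report for one dataset under one or more null models
#'
#' @param aln,sites observed data (polarized site table).
#' @param demography a `demography_model` for the demographic null.
#' @param replicates replicate count per model.
#' @param seed RNG seed.
#' @param models character subset of `c("neutral", "demography")`.
#' @param Ne_neutral constant size used for the neutral model (the fixed-S
#'   statistics are invariant to it; default 10000).
#' @return data frame: statistic, observed, p, model, replicates.
#' @export
rejection_report <- function(aln, sites, demography,
                             replicates = 2000L, seed = 1L,
                             models = c("neutral", "demography"),
                             Ne_neutral = 10000) {
  n <- n_chromosomes(aln)
  obs <- neutrality_stats(aln, sites)
  S <- nrow(sites)
  out <- list()
  if ("neutral" %in% models) {
    reps <- simulate_replicates(sim_config(n, replicates, seed, S = S),
                                constant_demography(Ne_neutral))
    out[[length(out) + 1L]] <- rejection_block(obs, reps, "neutral")
  }
  if ("demography" %in% models) {
    reps <- simulate_replicates(sim_config(n, replicates, seed + 1L, S = S),
                                demography)
    out[[length(out) + 1L]] <- rejection_block(obs, reps, "demography")
  }
  do.call(rbind, out)
}

#' Conversion-masked rerun
#'
#' Drops segregating sites inside the supplied minimum-conversion-tract
#' intervals, recomputes the observed statistics on the reduced data, and
#' re-simulates the null(s) conditioning on the reduced S. Reports masked
#' and unmasked blocks side by side.
#'
#' @param aln,sites observed data.
#' @param tracts intervals as in [drop_sites_in_tracts()]; defaults to the
#'   packaged tracts ([default_conversion_tracts()]).
#' @param demography demographic null model.
#' @param replicates,seed,models as in [rejection_report()].
#' @return list: `report` (combined data frame; masked models labelled
#'   `*+masked`), `S_unmasked`, `S_masked`, `sites_masked`.
#' @export
masked_rerun <- function(aln, sites, tracts = default_conversion_tracts(),
                         demography = european_demography(),
                         replicates = 2000L, seed = 1L,
                         models = c("neutral", "demography")) {
  iv <- as_intervals(tracts)
  if (nrow(iv) && (any(iv[, 1L] < 1L) || any(iv[, 2L] > aln$L)))
    stop("tract outside the alignment frame [1, ", aln$L, "]")
  full <- rejection_report(aln, sites, demography, replicates, seed, models)
  masked_sites <- drop_sites_in_tracts(sites, tracts)
  masked <- rejection_report(aln, masked_sites, demography, replicates,
                             seed + 1000L, models)
  masked$model <- paste0(masked$model, "+masked")
  list(report = rbind(full, masked),
       S_unmasked = nrow(sites), S_masked = nrow(masked_sites),
       sites_masked = nrow(sites) - nrow(masked_sites))
}

#' Write an ms-like haplotype block for interoperability
#'
#' Emits the `//` / `segsites:` / `positions:` record format for one
#' simulated replicate.
#' @param mt output of [mutate_fixed_s()] plus a positions vector.
#' @param positions site positions scaled to (0, 1).
#' @param con connection or path.
#' @keywords internal
write_ms_block <- function(mt, positions, con) {
  lines <- c("//", paste0("segsites: ", mt$S),
             paste("positions:", paste(sprintf("%.5f", positions), collapse = " ")))
  writeLines(lines, con)
  invisible(NULL)
}
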