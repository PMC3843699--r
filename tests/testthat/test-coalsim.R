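test_that("demography models validate their epoch structure", {
  expect_error(demography_model(data.frame(t0 = 0, t1 = 100,
                                           Ne_start = 1e4, Ne_end = 1e4)),
               "infinity")
  expect_error(demography_model(data.frame(t0 = c(0, 200), t1 = c(100, Inf),
                                           Ne_start = c(1, 1), Ne_end = c(1, 1))),
               "contiguous")
  eur <- european_demography()
  expect_equal(eur$epochs$t1[1], 840)
  expect_equal(eur$epochs$t0[3], 2040)
  expect_equal(eur$epochs$Ne_start[2], 1861)
})

test_that("demography config files round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("preset\teuropean_default", f)
  expect_equal(read_demography(f)$epochs, european_demography()$epochs)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("generation_time_years\t25",
               "epoch.1.t0_years\t0", "epoch.1.t1_years\t25000",
               "epoch.1.Ne_start\t5000", "epoch.1.Ne_end\t5000",
               "epoch.2.t0_years\t25000", "epoch.2.t1_years\tInf",
               "epoch.2.Ne_start\t12000", "epoch.2.Ne_end\t12000"), f2)
  d2 <- read_demography(f2)
  expect_equal(d2$epochs$t1[1], 1000)
  expect_equal(d2$epochs$Ne_start[2], 12000)
})

test_that("pairwise TMRCA matches the analytic constant-size expectation", {
  reps <- simulate_replicates(sim_config(2, 4000, seed = 7, S = 1),
                              constant_demography(1000))
  se <- sd(reps$tmrca) / sqrt(nrow(reps))
  expect_lt(abs(mean(reps$tmrca) - 2000), 3 * se)
})

test_that("total tree length matches 4 Ne a1 for n = 10", {
  reps <- simulate_replicates(sim_config(10, 3000, seed = 9, S = 1),
                              constant_demography(1000))
  expected <- 4 * 1000 * sum(1 / (1:9))
  se <- sd(reps$total_length) / sqrt(nrow(reps))
  expect_lt(abs(mean(reps$total_length) - expected), 3 * se)
})

test_that("theta mode reproduces E[S] = theta a1 and E[pi] = theta for n = 2", {
  reps <- simulate_replicates(sim_config(2, 4000, seed = 13, theta = 4),
                              constant_demography(5000))
  se_s <- sd(reps$S) / sqrt(nrow(reps))
  expect_lt(abs(mean(reps$S) - 4 * 1), 3 * se_s)  # a1 = 1 for n = 2
  se_p <- sd(reps$theta_pi) / sqrt(nrow(reps))
  expect_lt(abs(mean(reps$theta_pi) - 4), 3 * se_p)
})

test_that("fixed-S mutation placement conserves counts and edge cases", {
  set.seed(3)
  dem <- constant_demography(1000)
  tree <- simulate_genealogy(8, dem)
  m0 <- mutate_fixed_s(tree, 0)
  expect_equal(m0$S, 0L)
  expect_equal(m0$k, 1L)
  for (S in c(1, 5, 40)) {
    m <- mutate_fixed_s(tree, S)
    expect_equal(sum(m$xi), S)
    expect_equal(sum(m$hap_counts), 8L)
    expect_true(m$k <= S + 1)
  }
  # n = 2: every mutation is a singleton class
  t2 <- simulate_genealogy(2, dem)
  m2 <- mutate_fixed_s(t2, 7)
  expect_equal(m2$xi[1], 7L)
})

test_that("replicate tables are deterministic given the seed", {
  a <- simulate_replicates(sim_config(10, 50, seed = 5, S = 7),
                           european_demography())
  b <- simulate_replicates(sim_config(10, 50, seed = 5, S = 7),
                           european_demography())
  expect_identical(a, b)
  c <- simulate_replicates(sim_config(10, 50, seed = 6, S = 7),
                           european_demography())
  expect_false(identical(a$D, c$D))
})

test_that("rejection probability estimator has add-one bounds and monotonicity", {
  v <- c(-2, -1, 0, 1, 2)
  expect_equal(rejection_probability(-10, v), 1 / 6)
  expect_equal(rejection_probability(0, v), 4 / 6)
  expect_equal(rejection_probability(10, v, tail = "upper"), 1 / 6)
  p <- vapply(seq(-3, 3, by = 0.5), rejection_probability,
              numeric(1), replicate_values = v)
  expect_true(all(diff(p) >= 0))
  # median observed scores near one half
  set.seed(2)
  z <- rnorm(999)
  expect_equal(rejection_probability(median(z), z), 0.5, tolerance = 0.01)
})

test_that("self-scored rejection rate sits at the nominal level", {
  reps <- simulate_replicates(sim_config(20, 1500, seed = 21, S = 15),
                              constant_demography(10000))
  D <- reps$D[is.finite(reps$D)]
  R <- length(D)
  pvals <- rank(D, ties.method = "max") / R  # lower-tail empirical p
  rate <- mean(pvals <= 0.05)
  expect_lt(abs(rate - 0.05), 0.012)
})

test_that("the bottleneck-and-expansion preset reshapes the D distribution", {
  # verified behavior (independently cross-checked against msprime): the
  # long Ne=1861 bottleneck dominates the short expansion and shifts the
  # fixed-S mean of D upward relative to the constant-size null
  neutral <- simulate_replicates(sim_config(30, 800, seed = 31, S = 30),
                                 constant_demography(10000))
  eur <- simulate_replicates(sim_config(30, 800, seed = 32, S = 30),
                             european_demography())
  expect_gt(mean(eur$D), mean(neutral$D) + 0.2)
})

test_that("replicate SFS under a two-epoch model agrees with msprime", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  n <- 12L; S <- 10L; R <- 1500L
  # two-epoch model: small recent size, tenfold larger ancestral size
  dem <- demography_model(data.frame(t0 = c(0, 500), t1 = c(500, Inf),
                                     Ne_start = c(2000, 20000),
                                     Ne_end = c(2000, 20000)))
  set.seed(17)
  xi_sum <- numeric(n - 1)
  for (r in seq_len(R)) {
    tr <- simulate_genealogy(n, dem)
    xi_sum <- xi_sum + mutate_fixed_s(tr, S)$xi
  }
  mine <- xi_sum / (R * S)
  py <- sprintf('
import msprime, numpy as np
n, S, R = %d, %d, %d
dem = msprime.Demography()
dem.add_population(initial_size=2000)
dem.add_population_parameters_change(time=500, initial_size=20000)
rng = np.random.default_rng(11)
xi = np.zeros(n - 1)
for ts in msprime.sim_ancestry(samples=n // 2, demography=dem, ploidy=2,
                               num_replicates=R, random_seed=7):
    t = ts.first()
    nodes = [u for u in t.nodes() if t.parent(u) != -1]
    lens = np.array([t.branch_length(u) for u in nodes])
    sz = np.array([t.num_samples(u) for u in nodes])
    hit = rng.choice(len(nodes), size=S, p=lens / lens.sum())
    xi += np.bincount(sz[hit], minlength=n)[1:n]
print(" ".join(str(v) for v in xi / (R * S)))
', n, S, R)
  f <- withr::local_tempfile(fileext = ".py")
  writeLines(py, f)
  out <- system2("python", f, stdout = TRUE)
  theirs <- as.numeric(strsplit(out[length(out)], " ")[[1]])
  expect_equal(length(theirs), n - 1L)
  # binomial-ish Monte-Carlo error per class on R*S placements
  se <- sqrt(pmax(mine * (1 - mine), 1e-6) / (R * S)) * 2  # correlated draws
  expect_true(all(abs(mine - theirs) < 6 * se + 0.01))
})

test_that("masked reruns reduce S, feed the null, and survive edge cases", {
  fx <- synth_fixture()
  mr <- masked_rerun(fx$aln_A, fx$sitesA, tracts = c(624, 634),
                     demography = european_demography(),
                     replicates = 150, seed = 4, models = "demography")
  expect_equal(mr$sites_masked, 4L)
  expect_equal(mr$S_masked, 40L)
  expect_true(all(c("demography", "demography+masked") %in% mr$report$model))
  expect_true(all(mr$report$p > 0 & mr$report$p <= 1, na.rm = TRUE))
  # a tract with no segregating sites changes nothing
  mr0 <- masked_rerun(fx$aln_A, fx$sitesA, tracts = c(1, 2),
                      replicates = 100, seed = 4, models = "neutral")
  expect_equal(mr0$sites_masked, 0L)
  obs_cols <- c("statistic", "observed")
  expect_equal(mr0$report[mr0$report$model == "neutral", obs_cols],
               mr0$report[mr0$report$model == "neutral+masked", obs_cols],
               ignore_attr = TRUE)
  # masking every site flags statistics but does not crash
  mrall <- masked_rerun(fx$aln_A, fx$sitesA, tracts = c(1, 3357),
                        replicates = 50, seed = 4, models = "neutral")
  expect_equal(mrall$S_masked, 0L)
  expect_true(all(is.na(mrall$report$p[mrall$report$model == "neutral+masked"])))
  expect_error(masked_rerun(fx$aln_A, fx$sitesA, tracts = c(100, 4000)),
               "frame")
})
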