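test_that("coverage histogram counts per-position depths including zero", {
  one <- fixture_table(c(s1 = 1000L), data.frame(
    read = "r1", ref = "s1", pos1 = 101L, len = 100L, nm = 0L))
  h <- coverage_histogram(one, "s1")
  expect_equal(h$counts, c("0" = 900, "1" = 100))
  expect_equal(h$genome_length, 1000)

  stacked <- fixture_table(c(s1 = 1000L), data.frame(
    read = c("r1", "r2"), ref = "s1", pos1 = 101L, len = 100L, nm = 0L))
  h2 <- coverage_histogram(stacked, "s1")
  expect_equal(h2$counts, c("0" = 900, "2" = 100))

  expect_error(coverage_histogram(one, "nope"), "unknown organism")
})

test_that("simulated coverage at 5x has the expected mean depth", {
  res <- one_ref_community(depth = 5, shared_fraction = 1, divergence = 0,
                           genome_length = 5e4, seed = 3L)
  tab <- parse_sam(res$sam, read_grouping_tsv(res$grouping))
  h <- coverage_histogram(tab, "ref")
  x <- as.numeric(names(h$counts))
  m <- sum(x * h$counts) / sum(h$counts)
  se <- sqrt(5 / (5e4 / 100))  # depth variance across ~L/readlen indep. units
  expect_lt(abs(m - 5), 3 * se)
})

test_that("Poisson-tail mixture recovers pure and zero-inflated Poisson", {
  set.seed(101)
  pois <- table(rpois(1e6, 3))
  fit <- fit_poisson_tail_mixture(
    make_cov_hist(stats::setNames(as.numeric(pois), names(pois))))
  expect_true(fit$converged)
  expect_lte(fit$alpha[1], 0.02)
  expect_lt(abs(fit$lam - 3), 0.05)

  set.seed(102)
  n_zero <- 4e5
  mix <- c(rep(0, n_zero), rpois(6e5, 5))
  tb <- table(mix)
  fit2 <- fit_poisson_tail_mixture(
    make_cov_hist(stats::setNames(as.numeric(tb), names(tb))))
  expect_lt(abs(fit2$alpha[1] - 0.40), 0.02)
  expect_lt(abs(fit2$lam - 5), 0.1)

  expect_error(fit_poisson_tail_mixture(make_cov_hist(c("0" = 1e6))),
               "no coverage evidence")
})

test_that("EM log-likelihood is monotone and beats a dense grid-search oracle", {
  grid_oracle <- function(x, n) {
    mean_nz <- sum(x * n) / max(sum(n[x > 0]), 1)
    lams <- seq(0.1, max(2 * mean_nz, 0.2), by = 0.05)
    a1s <- seq(0, 1, by = 0.01)
    ss <- seq(0, 1, by = 0.02)  # split of the non-zero mass on Poisson vs tail
    W <- cbind(rep(a1s, each = length(ss)),
               rep(1 - a1s, each = length(ss)) * ss,
               rep(1 - a1s, each = length(ss)) * (1 - ss))
    best <- -Inf
    for (lam in lams) {
      dens <- rbind(as.numeric(x == 0), dpois(x, lam),
                    gdvprofile:::poisson_tail_pmf(x, lam))
      mixmat <- W %*% dens  # one row per weight triple
      lls <- colSums(t(log(pmax(mixmat, 1e-300))) * n)
      best <- max(best, max(lls))
    }
    best
  }

  set.seed(200)
  for (rep in 1:20) {
    lam_true <- runif(1, 0.5, 8)
    zfrac <- runif(1, 0, 0.6)
    npos <- 5000L
    v <- c(rep(0L, round(zfrac * npos)),
           rpois(npos - round(zfrac * npos), lam_true))
    tb <- table(v)
    counts <- stats::setNames(as.numeric(tb), names(tb))
    fit <- fit_poisson_tail_mixture(make_cov_hist(counts))
    expect_true(all(diff(fit$loglik_trace) >= -1e-9))
    x <- as.integer(names(counts))
    expect_gte(fit$loglik, grid_oracle(x, as.numeric(counts)) - 1e-3)
  }
})

test_that("fitted mixture density is normalized", {
  set.seed(103)
  tb <- table(rpois(1e4, 4))
  fit <- fit_poisson_tail_mixture(
    make_cov_hist(stats::setNames(as.numeric(tb), names(tb))))
  xs <- 0:500
  dens <- fit$alpha[1] * as.numeric(xs == 0) +
    fit$alpha[2] * dpois(xs, fit$lam) +
    fit$alpha[3] * gdvprofile:::poisson_tail_pmf(xs, fit$lam)
  expect_lt(abs(sum(dens) - 1), 1e-6)
  expect_lt(abs(sum(fit$alpha) - 1), 1e-9)
})

test_that("geometric mixture recovers a single spacing regime", {
  set.seed(104)
  d <- rgeom(1e5, 0.01) + 1L
  fit <- fit_geometric_mixture(make_sdh(d, genome_length = 1e7))
  mom <- 1 / mean(d)  # method-of-moments oracle
  expect_lt(abs(fit$p_shared - mom), 5e-4)
  expect_gt(fit$shared_weight, 0.95)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))

  expect_error(fit_geometric_mixture(make_sdh(c(5, 9, 13), 1000)),
               "insufficient reads")
  expect_error(fit_geometric_mixture(make_sdh(integer(0), 1000)),
               "insufficient reads")
})

test_that("GDV is one minus the zero weight, with band thresholds", {
  fake <- function(a1) gdvprofile:::new_mixture_fit(
    alpha = c(a1, (1 - a1) * 0.9, (1 - a1) * 0.1), lam = 5,
    variant = "poisson_tail", converged = TRUE, n_iter = 10L,
    genome_length = 1e5)
  expect_equal(estimate_gdv(fake(0.2)), 0.8)
  expect_equal(estimate_gdv(fake(1)), 0)
  expect_equal(estimate_gdv(fake(0)), 1)

  bad <- fake(0.5)
  bad$converged <- FALSE
  bad$n_iter <- 77L
  expect_error(estimate_gdv(bad), "77")

  expect_equal(gdvprofile:::quality_band(0.85), "high")
  expect_equal(gdvprofile:::quality_band(0.5), "informative")
  expect_equal(gdvprofile:::quality_band(0.1), "caution")
})

test_that("KS homogeneity accepts uniform placements and rejects stacks", {
  set.seed(105)
  pvals <- vapply(1:20, function(i) {
    rows <- data.frame(read = sprintf("r%05d", 1:2000), ref = "s1",
                       pos1 = sample.int(9900L, 2000L, replace = TRUE),
                       len = 100L, nm = 0L)
    ks_homogeneity(fixture_table(c(s1 = 10000L), rows), "s1")
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.95)

  stack <- fixture_table(c(s1 = 10000L), data.frame(
    read = sprintf("r%03d", 1:200), ref = "s1", pos1 = 500L, len = 100L,
    nm = 0L))
  expect_lt(ks_homogeneity(stack, "s1"), 1e-6)

  two <- fixture_table(c(s1 = 1000L), data.frame(
    read = c("a", "b"), ref = "s1", pos1 = c(100L, 600L), len = 100L,
    nm = 0L))
  expect_true(is.finite(ks_homogeneity(two, "s1")))

  one <- fixture_table(c(s1 = 1000L), data.frame(
    read = "a", ref = "s1", pos1 = 100L, len = 100L, nm = 0L))
  expect_true(is.na(ks_homogeneity(one, "s1")))  # < 2 reads: not testable
})

test_that("profile dispatches on naive depth and recovers parameters", {
  hi <- one_ref_community(depth = 10, shared_fraction = 0.8,
                          genome_length = 2e5, seed = 21L)
  tab <- parse_sam(hi$sam, read_grouping_tsv(hi$grouping))
  p <- estimate_profile(tab, "ref")
  expect_equal(p$variant, "poisson_tail")
  expect_lt(abs(p$gdv - 0.8), 0.05)
  expect_lt(abs(p$depth - 10), 0.5)
  expect_equal(p$quality_band, gdvprofile:::quality_band(p$gdv))

  lo <- one_ref_community(depth = 0.5, shared_fraction = 1,
                          genome_length = 2e5, seed = 22L)
  tab2 <- parse_sam(lo$sam, read_grouping_tsv(lo$grouping))
  p2 <- estimate_profile(tab2, "ref")
  expect_equal(p2$variant, "geometric")
  expect_lt(abs(p2$depth - 0.5), 0.1)
  expect_gt(p2$gdv, 0.8)
})

test_that("estimated GDV is monotone in the true shared fraction", {
  gdvs <- vapply(c(0.2, 0.5, 0.8, 1.0), function(f) {
    res <- one_ref_community(depth = 5, shared_fraction = f,
                             genome_length = 2e5, seed = 31L)
    tab <- parse_sam(res$sam, read_grouping_tsv(res$grouping))
    estimate_profile(tab, "ref")$gdv
  }, numeric(1))
  expect_true(all(diff(gdvs) >= 0))
})
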