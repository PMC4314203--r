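# minimal profile stand-ins for clustering unit tests
fake_profiles <- function(orgs, depths) {
  stats::setNames(lapply(seq_along(orgs), function(i) {
    structure(list(organism_id = orgs[i], depth = depths[i], gdv = 0.9,
                   n_reads = 10L, n_unique_reads = 5L, error_rate = 0.01,
                   ks_p = 0.5, quality_band = "high", fit_failed = FALSE),
              class = "reference_profile")
  }), orgs)
}

# build a table + CR set from explicit read -> organisms memberships
membership_fixture <- function(memb) {
  orgs <- unique(unlist(memb))
  sq <- stats::setNames(rep(1000L, length(orgs)), orgs)
  rows <- do.call(rbind, lapply(names(memb), function(r)
    data.frame(read = r, ref = memb[[r]], pos1 = 1L, len = 50L, nm = 0L)))
  tab <- fixture_table(sq, rows)
  profiles <- fake_profiles(orgs, rep(5, length(orgs)))
  cr <- extract_core_reads(tab, stats::setNames(rep(5, length(orgs)), orgs),
                           t = 0.2)
  list(table = tab, profiles = profiles, cr = cr)
}

test_that("greedy clustering follows the CR-overlap then shared-read rules", {
  # identical CR sets: one cluster of two members
  fx <- membership_fixture(lapply(
    stats::setNames(nm = sprintf("r%02d", 1:20)),
    function(r) c("g1", "g2")))
  cl <- greedy_cluster(fx$profiles, fx$cr, fx$table)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$members$organism, c("g1", "g2"))

  # disjoint read sets: one cluster each
  memb <- c(lapply(stats::setNames(nm = sprintf("a%02d", 1:15)),
                   function(r) "g1"),
            lapply(stats::setNames(nm = sprintf("b%02d", 1:10)),
                   function(r) "g2"))
  fx2 <- membership_fixture(memb)
  cl2 <- greedy_cluster(fx2$profiles, fx2$cr, fx2$table)
  expect_length(cl2, 2L)

  # 100 CR, 30 shared with the seed cluster: 0.30 >= 0.20 joins
  memb3 <- c(
    lapply(stats::setNames(nm = sprintf("s%03d", 1:200)), function(r) "seed"),
    lapply(stats::setNames(nm = sprintf("x%03d", 1:30)),
           function(r) c("seed", "g")),
    lapply(stats::setNames(nm = sprintf("y%03d", 1:70)), function(r) "g")
  )
  fx3 <- membership_fixture(memb3)
  expect_length(greedy_cluster(fx3$profiles, fx3$cr, fx3$table,
                               min_cr_overlap = 0.2), 1L)
  # requiring more overlap than is present splits them (stage ii fails too:
  # only 30 of 100 reads shared)
  expect_length(greedy_cluster(fx3$profiles, fx3$cr, fx3$table,
                               min_cr_overlap = 0.5), 2L)
})

test_that("clusters partition the organisms and are deterministic", {
  set.seed(9)
  memb <- lapply(stats::setNames(nm = sprintf("r%03d", 1:150)), function(r)
    sample(paste0("g", 1:5), sample.int(2L, 1L)))
  fx <- membership_fixture(memb)
  cl <- greedy_cluster(fx$profiles, fx$cr, fx$table)
  members <- unlist(lapply(cl, function(x) x$members$organism))
  expect_setequal(members, paste0("g", 1:5))
  expect_equal(anyDuplicated(members), 0L)

  cl_again <- greedy_cluster(fx$profiles, fx$cr, fx$table)
  expect_identical(
    lapply(cl, function(x) x$members$organism),
    lapply(cl_again, function(x) x$members$organism))

  # lowering the CR-overlap threshold never increases the cluster count
  counts <- vapply(c(0.8, 0.4, 0.2, 0.1, 0.0),
                   function(th) length(greedy_cluster(
                     fx$profiles, fx$cr, fx$table, min_cr_overlap = th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("LCA matches identity, species collapse and ancestor-path oracle", {
  tax <- toy_taxonomy()
  expect_equal(lca("x1", tax), "x1")
  expect_equal(lca(c("x1", "x2"), tax), "speciesX")
  expect_equal(lca(c("x1", "y1"), tax), "root")
  expect_error(lca("nosuch", tax), "nosuch")

  for (seed in 1:5) {
    tax_r <- random_taxonomy(25L, seed)
    set.seed(seed + 100)
    for (k in c(1L, 2L, 4L)) {
      members <- sample(names(tax_r$parent), k)
      expect_equal(lca(members, tax_r), lca_oracle(members, tax_r))
    }
  }
})

test_that("abundances are depth proportions over candidates", {
  mk <- function(depths) {
    structure(lapply(seq_along(depths), function(i)
      list(cluster_id = sprintf("c%d", i),
           members = data.table::data.table(organism = sprintf("g%d", i)),
           n_reads = 10L, n_cr = 5L, depth = depths[i],
           lca_taxon = "unclassified", abundance = NA_real_)),
      class = "candidate_set")
  }
  one <- estimate_abundances(mk(7))
  expect_equal(one[[1]]$abundance, 1.0)

  two <- estimate_abundances(mk(c(10, 10)))
  expect_equal(vapply(two, function(x) x$abundance, numeric(1)), c(0.5, 0.5))

  expect_warning(z <- estimate_abundances(mk(c(0, 0))), "uniform")
  expect_equal(vapply(z, function(x) x$abundance, numeric(1)), c(0.5, 0.5))
})

test_that("staggered three-organism community resolves into three clusters", {
  spec <- three_org_spec(seed = 7L)
  res <- simulate_community(spec, tempfile("sim3"), write_fasta = FALSE)
  tab <- parse_sam(res$sam, read_grouping_tsv(res$grouping))
  tab <- filter_low_support_refs(filter_promiscuous_reads(tab))
  profiles <- estimate_profiles(tab)
  cr <- extract_core_reads(tab, profiles)
  cl <- estimate_abundances(greedy_cluster(profiles, cr, tab))

  expect_length(cl, 3L)
  got <- lapply(cl, function(x) sort(x$members$organism))
  for (org in paste0("org", 1:3)) {
    expected <- paste0(org, c("_refA", "_refB"))
    expect_true(any(vapply(got, identical, logical(1), expected)))
  }
  expect_lt(abs(sum(vapply(cl, function(x) x$abundance, numeric(1))) - 1),
            1e-9)

  # depth-based abundance recovery: truth 8 : 2 : 0.5
  depths <- vapply(cl, function(x) x$depth, numeric(1))
  truth <- sort(c(8, 2, 0.5) / 10.5, decreasing = TRUE)
  est <- sort(vapply(cl, function(x) x$abundance, numeric(1)),
              decreasing = TRUE)
  expect_true(all(abs(est - truth) / truth < 0.1))
})

test_that("taxonomy hint does not change clustering results", {
  spec <- three_org_spec(seed = 13L)
  res <- simulate_community(spec, tempfile("simh"), write_fasta = FALSE)
  tab <- parse_sam(res$sam, read_grouping_tsv(res$grouping))
  tab <- filter_low_support_refs(filter_promiscuous_reads(tab))
  profiles <- estimate_profiles(tab)
  cr <- extract_core_reads(tab, profiles)

  tax <- taxonomy_table(parent = c(
    root = "root", org1 = "root", org2 = "root", org3 = "root",
    org1_refA = "org1", org1_refB = "org1", org2_refA = "org2",
    org2_refB = "org2", org3_refA = "org3", org3_refB = "org3"))

  plain <- greedy_cluster(profiles, cr, tab, taxonomy = tax)
  hinted <- greedy_cluster(profiles, cr, tab, taxonomy = tax,
                           taxonomy_hint = TRUE)
  expect_identical(lapply(plain, function(x) sort(x$members$organism)),
                   lapply(hinted, function(x) sort(x$members$organism)))
  # two strains under one organism node collapse to that node's name
  expect_setequal(vapply(plain, function(x) x$lca_taxon, character(1)),
                  c("org1", "org2", "org3"))
})
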