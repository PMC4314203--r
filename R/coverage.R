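#' Coverage-depth histogram for one organism
#'
#' Per-position sequencing depth is computed from alignment intervals over all
#' of the organism's member sequences and tabulated into a histogram of depth
#' values (including depth 0).
#'
#' @param table an `alignment_table`.
#' @param organism organism id.
#' @return object of class `coverage_histogram`: list with `counts` (named
#'   numeric vector, names are depth values, entries are numbers of genome
#'   positions) and `genome_length` (bases).
#' @export
coverage_histogram <- function(table, organism) {
  seqs <- names(table$grouping$seq_to_organism)[
    table$grouping$seq_to_organism == organism]
  if (length(seqs) == 0L) stop("unknown organism: ", organism)
  a <- org_alns(table, organism)
  if (nrow(a) == 0L) stop("organism has no alignments: ", organism)
  acc <- new.env(parent = emptyenv())
  add <- function(depth, n) {
    key <- as.character(depth)
    for (i in seq_along(key)) {
      prev <- if (is.null(acc[[key[i]]])) 0 else acc[[key[i]]]
      acc[[key[i]]] <- prev + n[i]
    }
  }
  for (s in seqs) {
    len <- as.integer(table$ref_lengths[[s]])
    ai <- a[a$ref_id == s]
    if (nrow(ai) == 0L) {
      add(0L, len)
      next
    }
    cov <- IRanges::coverage(
      IRanges::IRanges(start = ai$pos + 1L, width = ai$aln_len), width = len)
    add(S4Vectors::runValue(cov), S4Vectors::runLength(cov))
  }
  keys <- sort(as.integer(ls(acc)))
  counts <- setNames(vapply(as.character(keys), function(k) acc[[k]], numeric(1)),
                     as.character(keys))
  structure(
    list(counts = counts,
         genome_length = sum(table$ref_lengths[seqs])),
    class = "coverage_histogram"
  )
}

#' Read-start spacing histogram for one organism
#'
#' For depths below 1x the coverage histogram is nearly all zeros and ones and
#' carries little signal; the spacing between consecutive read start positions
#' does. Starts are sorted within each member sequence; consecutive
#' differences are pooled across sequences (never across a sequence
#' boundary). Duplicate starts contribute a spacing of 1 (the smallest value
#' the spacing distribution supports).
#'
#' @param table an `alignment_table`.
#' @param organism organism id.
#' @return object of class `start_distance_histogram`: `counts` (named
#'   numeric, names are spacings in bases), `n_reads`, `genome_length`,
#'   `mean_read_len`.
#' @export
start_distance_histogram <- function(table, organism) {
  a <- org_alns(table, organism)
  if (nrow(a) == 0L) stop("organism has no alignments: ", organism)
  dists <- unlist(lapply(split(a$pos, a$ref_id), function(p) {
    if (length(p) < 2L) return(integer(0))
    diff(sort(p))
  }), use.names = FALSE)
  dists <- pmax(dists, 1L)
  tab <- table(dists)
  seqs <- names(table$grouping$seq_to_organism)[
    table$grouping$seq_to_organism == organism]
  structure(
    list(counts = setNames(as.numeric(tab), names(tab)),
         n_reads = length(unique(a$read_id)),
         genome_length = sum(table$ref_lengths[seqs]),
         mean_read_len = mean(a$aln_len)),
    class = "start_distance_histogram"
  )
}

# normalized Poisson tail mass: T_lambda(x) = Pr(Poisson(lambda) >= x) / lambda
# for x >= 1 and 0 at x = 0. The normalizer is exact:
# sum_{x>=1} Pr(X >= x) = E[X] = lambda.
poisson_tail_pmf <- function(x, lambda) {
  out <- ppois(x - 1, lambda, lower.tail = FALSE) / lambda
  out[x < 1] <- 0
  out
}

new_mixture_fit <- function(...) structure(list(...), class = "mixture_fit")

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit>", x$variant,
      "alpha =", paste(sprintf("%.4f", x$alpha), collapse = ", "),
      if (x$variant == "poisson_tail") sprintf("lambda = %.4f", x$lam)
      else sprintf("p = %s", paste(sprintf("%.3g", x$p), collapse = ", ")),
      sprintf("loglik = %.4f (%d it, %s)", x$loglik, x$n_iter,
              if (isTRUE(x$converged)) "converged" else "NOT converged"), "\n")
  invisible(x)
}

#' Fit the zero-inflated Poisson mixture with tail to a coverage histogram
#'
#' The per-position depth x is modelled as a three-component mixture
#' f(x) = a1 z(x) + a2 Pois(x | lambda) + a3 T_lambda(x): a point mass at zero
#' for genome regions absent from the sample, a Poisson for regions shared
#' between reference and sample organism, and a normalized Poisson
#' survival-mass tail absorbing right-skew from repeats and reference
#' divergence. Fitted by EM; the M-step for lambda maximizes the expected
#' complete-data log-likelihood of the Poisson and tail components jointly by
#' 1-d numerical optimization, so the observed log-likelihood is
#' non-decreasing at every iteration.
#'
#' Depth bins above the 99.9th percentile of nonzero-depth positions are
#' pooled into the top bin so that extreme repeat pileups cannot dominate the
#' fit.
#'
#' @param hist a `coverage_histogram`.
#' @param max_iter maximum EM iterations (default 5000).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return a `mixture_fit` with fields `alpha` (length 3, sums to 1), `lam`,
#'   `variant = "poisson_tail"`, `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `genome_length`.
#' @export
fit_poisson_tail_mixture <- function(hist, max_iter = 5000L, tol = 1e-8) {
  stopifnot(inherits(hist, "coverage_histogram"))
  x <- as.integer(names(hist$counts))
  n <- as.numeric(hist$counts)
  if (sum(n[x > 0]) == 0) stop("no coverage evidence: all positions depth 0")

  # pool the extreme right tail (repeat pileups) into the top retained bin
  nz <- x > 0
  ord <- order(x[nz])
  cum <- cumsum(n[nz][ord]) / sum(n[nz])
  cap <- x[nz][ord][which(cum >= 0.999)[1L]]
  if (any(x > cap)) {
    pooled <- sum(n[x > cap])
    keep <- x <= cap
    x <- x[keep]; n <- n[keep]
    n[x == cap] <- n[x == cap] + pooled
  }

  ntot <- sum(n)
  zero_frac <- sum(n[x == 0]) / ntot
  alpha <- c(zero_frac, (1 - zero_frac) / 2, (1 - zero_frac) / 2)
  lam <- sum(x * n) / max(sum(n[x > 0]), 1)  # mean of nonzero depths
  lam <- max(lam, 1e-3)

  comp_dens <- function(lam) {
    rbind(as.numeric(x == 0), dpois(x, lam), poisson_tail_pmf(x, lam))
  }
  loglik_of <- function(alpha, dens) {
    mix <- colSums(alpha * dens)
    sum(n * log(pmax(mix, 1e-300)))
  }

  dens <- comp_dens(lam)
  ll <- loglik_of(alpha, dens)
  trace <- ll
  converged <- FALSE
  it <- 0L
  upper <- max(2 * lam, max(x) + 1)
  for (it in seq_len(max_iter)) {
    # E-step
    num <- alpha * dens
    mix <- colSums(num)
    gamma <- sweep(num, 2, pmax(mix, 1e-300), "/")
    # M-step
    alpha_new <- rowSums(sweep(gamma, 2, n, "*")) / ntot
    g2 <- gamma[2, ] * n
    g3 <- gamma[3, ] * n
    qfun <- function(l) {
      d2 <- dpois(x, l)
      d3 <- poisson_tail_pmf(x, l)
      sum(g2 * log(pmax(d2, 1e-300))) + sum(g3 * log(pmax(d3, 1e-300)))
    }
    lam_new <- optimize(qfun, interval = c(1e-6, upper), maximum = TRUE,
                        tol = 1e-10)$maximum
    dens_new <- comp_dens(lam_new)
    ll_new <- loglik_of(alpha_new, dens_new)
    if (ll_new + 1e-12 >= ll) {  # accept (generalized EM step)
      alpha <- alpha_new; lam <- lam_new; dens <- dens_new
    } else {
      ll_new <- ll
    }
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) <= tol * (abs(ll) + 1e-12)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  new_mixture_fit(
    alpha = alpha, lam = lam, variant = "poisson_tail",
    loglik = ll, loglik_trace = trace, n_iter = it, converged = converged,
    genome_length = hist$genome_length
  )
}

# order components by decreasing success probability and compute merged
# "shared-region" statistics. The within-shared spacing regime is anchored at
# the highest-weight component -- within-block spacings always outnumber the
# one-per-block gap jumps -- and every component at least as tight as
# merge_factor times its mean is pooled with it: EM can split one true regime
# across near-identical components, or hive off a small chance cluster of
# close read starts, and neither artifact may masquerade as the gap regime.
geom_shared_stats <- function(w, p, d, n, merge_factor = 5) {
  ord <- order(p, decreasing = TRUE)
  w <- w[ord]; p <- p[ord]
  means <- 1 / p
  anchor <- which.max(w)
  shared <- means <= merge_factor * means[anchor]
  dens <- vapply(seq_along(p), function(k) w[k] * dgeom(d - 1, p[k]),
                 numeric(length(d)))
  dens <- matrix(dens, nrow = length(d))
  mix <- rowSums(dens)
  gamma_shared <- rowSums(dens[, shared, drop = FALSE]) / pmax(mix, 1e-300)
  n_shared <- sum(n * gamma_shared)
  span <- sum(n * d * gamma_shared)
  list(order = ord, w = w, p = p, shared = shared,
       shared_weight = sum(w[shared]),
       shared_span = span,
       p_shared = if (span > 0) n_shared / span else p[1L])
}

#' Fit a three-component geometric mixture to read-start spacings
#'
#' At depths below 1x, spacings between consecutive read starts within
#' genome regions shared with the sample organism are geometric with success
#' probability close to the per-base read-start rate; spacings that jump
#' across unshared regions are much longer. A three-component geometric
#' mixture separates these regimes by EM. Components are ordered by
#' decreasing success probability, so component 1 is the within-shared-region
#' spacing regime.
#'
#' @param hist a `start_distance_histogram` with at least 10 spacings.
#' @param max_iter,tol EM controls as in [fit_poisson_tail_mixture()].
#' @param merge_factor components whose mean spacing is within this factor of
#'   the tightest component's mean are pooled when deriving shared-region
#'   statistics (guards against EM splitting one regime in two).
#' @return a `mixture_fit` with `alpha`, `p` (success probabilities, ordered
#'   decreasing), `lam` (per-base read-start rate in shared regions,
#'   `-log(1 - p_shared)`), `shared_span` (estimated total bases of shared
#'   regions), `variant = "geometric"`.
#' @export
fit_geometric_mixture <- function(hist, max_iter = 5000L, tol = 1e-8,
                                  merge_factor = 5) {
  stopifnot(inherits(hist, "start_distance_histogram"))
  d <- as.numeric(names(hist$counts))
  n <- as.numeric(hist$counts)
  ndist <- sum(n)
  if (ndist < 10) stop("insufficient reads for low-coverage model (",
                       ndist, " spacings < 10)")

  qs <- cumsum(n[order(d)]) / ndist
  dq <- function(q) d[order(d)][which(qs >= q)[1L]]
  p <- pmin(0.99, pmax(1e-9, 1 / c(dq(0.25), dq(0.5), dq(0.9))))
  if (length(unique(p)) < 3L) p <- p * c(1, 0.5, 0.1)
  w <- rep(1 / 3, 3)

  dens_fun <- function(w, p)
    vapply(1:3, function(k) w[k] * dgeom(d - 1, p[k]), numeric(length(d)))
  ll_of <- function(dens) sum(n * log(pmax(rowSums(dens), 1e-300)))

  dens <- matrix(dens_fun(w, p), nrow = length(d))
  ll <- ll_of(dens)
  trace <- ll
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    gamma <- sweep(dens, 1, pmax(rowSums(dens), 1e-300), "/")
    Nk <- colSums(n * gamma)
    w <- Nk / ndist
    sums_d <- colSums(n * d * gamma)
    p <- pmin(1 - 1e-12, pmax(1e-12, Nk / pmax(sums_d, 1e-300)))
    dens <- matrix(dens_fun(w, p), nrow = length(d))
    ll_new <- ll_of(dens)
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) <= tol * (abs(ll) + 1e-12)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  st <- geom_shared_stats(w, p, d, n, merge_factor)
  new_mixture_fit(
    alpha = st$w, p = st$p, lam = -log1p(-st$p_shared),
    variant = "geometric",
    shared_span = st$shared_span, shared_weight = st$shared_weight,
    p_shared = st$p_shared,
    loglik = ll, loglik_trace = trace, n_iter = it, converged = converged,
    genome_length = hist$genome_length, n_dist = ndist
  )
}

#' Genome-dataset validity from a fitted mixture
#'
#' The GDV is the fraction of the reference genome for which the read set
#' provides evidence. For the coverage-histogram (Poisson-tail) fit it is one
#' minus the weight of the zero component. For the spacing (geometric) fit it
#' is the estimated total span of shared regions -- number of
#' within-shared-regime spacings times their mean -- over the genome length.
#'
#' @param fit a converged `mixture_fit`.
#' @return GDV in \[0, 1\].
#' @export
estimate_gdv <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (!isTRUE(fit$converged)) {
    stop("mixture fit did not converge after ", fit$n_iter, " iterations")
  }
  if (fit$variant == "poisson_tail") {
    max(0, min(1, 1 - fit$alpha[1L]))
  } else {
    max(0, min(1, fit$shared_span / fit$genome_length))
  }
}

#' Kolmogorov-Smirnov homogeneity test of read placement
#'
#' Tests whether read start positions are uniform within the covered part of
#' the genome (reads can only start in regions the reference shares with the
#' sample organism, so uniformity is assessed in the coordinate system of the
#' concatenated covered intervals). A large p-value is consistent with
#' homogeneous sequencing; a small one flags clumped placements such as
#' spurious hits to a single conserved locus.
#'
#' @param table an `alignment_table`.
#' @param organism organism id with at least 2 distinct mapped reads.
#' @return p-value, or `NA_real_` when fewer than 2 reads ("not testable").
#' @export
ks_homogeneity <- function(table, organism) {
  a <- org_alns(table, organism)
  if (nrow(a) == 0L) stop("unknown organism or no alignments: ", organism)
  if (length(unique(a$read_id)) < 2L) return(NA_real_)
  offset <- 0
  u <- numeric(0)
  for (s in unique(a$ref_id)) {
    ai <- a[a$ref_id == s]
    cov <- IRanges::reduce(IRanges::IRanges(start = ai$pos + 1L,
                                            width = ai$aln_len))
    cumlen <- c(0, cumsum(IRanges::width(cov)))
    idx <- findInterval(ai$pos + 1L, IRanges::start(cov))
    u <- c(u, offset + cumlen[idx] + (ai$pos + 1L - IRanges::start(cov)[idx]))
    offset <- offset + sum(IRanges::width(cov))
  }
  if (offset <= 1) return(NA_real_)
  suppressWarnings(ks.test(u / offset, "punif")$p.value)
}

quality_band <- function(gdv) {
  if (gdv > 0.8) "high" else if (gdv >= 0.2) "informative" else "caution"
}

#' Per-reference depth, GDV and quality profile
#'
#' Computes the naive depth (total aligned bases over genome length) and
#' dispatches: at naive depth >= 1x the coverage histogram is fitted with the
#' zero-inflated Poisson-with-tail mixture; below 1x the read-start spacing
#' histogram is fitted with the geometric mixture, and depth is the per-base
#' start rate in shared regions times the mean read length. GDV quality
#' bands: > 0.8 "high" (almost always a highly relevant reference), 0.2-0.8
#' "informative", < 0.2 "caution" (distant relation or spurious mappings).
#'
#' @param table an `alignment_table` (after filtering).
#' @param organism organism id.
#' @return object of class `reference_profile`: list with `organism_id`,
#'   `depth` (x-coverage in shared regions), `gdv`, `n_reads`,
#'   `n_unique_reads`, `error_rate`, `ks_p`, `quality_band`, `variant`,
#'   `fit_failed`, and the underlying `fit` (NULL when failed).
#' @export
estimate_profile <- function(table, organism) {
  a <- org_alns(table, organism)
  if (nrow(a) == 0L) stop("unknown organism or no alignments: ", organism)
  glen <- table$grouping$organism_length[[organism]]
  naive_depth <- sum(a$aln_len) / glen
  ucnt <- unique_read_counts(table)

  fit <- NULL
  failed <- FALSE
  depth <- naive_depth
  gdv <- 0
  variant <- NA_character_
  res <- tryCatch({
    if (naive_depth >= 1) {
      fit <- fit_poisson_tail_mixture(coverage_histogram(table, organism))
      list(depth = fit$lam, gdv = estimate_gdv(fit))
    } else {
      h <- start_distance_histogram(table, organism)
      fit <- fit_geometric_mixture(h)
      list(depth = fit$lam * h$mean_read_len, gdv = estimate_gdv(fit))
    }
  }, error = function(e) e)
  if (inherits(res, "error")) {
    failed <- TRUE
    fit <- NULL
  } else {
    depth <- res$depth
    gdv <- res$gdv
    variant <- fit$variant
  }

  structure(
    list(
      organism_id = organism,
      depth = depth,
      gdv = gdv,
      n_reads = length(unique(a$read_id)),
      n_unique_reads = unname(ucnt[organism]),
      error_rate = mean(a$edit_distance / a$aln_len),
      ks_p = ks_homogeneity(table, organism),
      quality_band = quality_band(gdv),
      variant = variant,
      fit_failed = failed,
      fit = fit
    ),
    class = "reference_profile"
  )
}

#' Profiles for every organism in an alignment table
#'
#' @param table an `alignment_table` (after filtering).
#' @return named list of `reference_profile` objects, one per organism.
#' @export
estimate_profiles <- function(table) {
  orgs <- organisms(table)
  setNames(lapply(orgs, function(o) estimate_profile(table, o)), orgs)
}

#' Flatten reference profiles into a data.table
#' @param profiles list of `reference_profile` objects.
#' @return data.table with one row per organism.
#' @export
profiles_table <- function(profiles) {
  rbindlist(lapply(profiles, function(p) {
    data.table::data.table(
      organism = p$organism_id, depth = p$depth, gdv = p$gdv,
      n_reads = p$n_reads, n_unique_reads = p$n_unique_reads,
      error_rate = p$error_rate, ks_p = p$ks_p,
      quality_band = p$quality_band, variant = p$variant,
      fit_failed = p$fit_failed
    )
  }))
}
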