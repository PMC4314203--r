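#' Read a taxonomy table from TSV
#'
#' Four tab-separated columns, no header: taxon_id, parent_id, rank, name.
#' The root node is the one whose parent is itself (or empty). Reference
#' organism ids appear as leaf taxon ids.
#'
#' @param path path to a TSV file.
#' @return object of class `taxonomy_table`: list with named character
#'   vectors `parent`, `rank`, `name`, and `root`.
#' @export
read_taxonomy_tsv <- function(path) {
  tx <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(tx) < 4L) stop("taxonomy file must have 4 tab-separated columns")
  taxonomy_table(setNames(tx[[2L]], tx[[1L]]),
                 setNames(tx[[3L]], tx[[1L]]),
                 setNames(tx[[4L]], tx[[1L]]))
}

#' Construct a taxonomy table
#' @param parent named character vector taxon -> parent taxon; the root
#'   points to itself or to "".
#' @param rank,name optional named character vectors.
#' @return a `taxonomy_table`.
#' @export
taxonomy_table <- function(parent, rank = NULL, name = NULL) {
  roots <- names(parent)[parent == names(parent) | parent == "" |
                           is.na(parent)]
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root, found: ",
         paste(roots, collapse = ", "))
  }
  if (is.null(name)) name <- setNames(names(parent), names(parent))
  if (is.null(rank)) rank <- setNames(rep("no rank", length(parent)),
                                      names(parent))
  # verify acyclicity / reachability of root
  for (tx in names(parent)) {
    seen <- character(0)
    node <- tx
    while (node != roots) {
      if (node %in% seen) stop("taxonomy cycle at taxon: ", node)
      seen <- c(seen, node)
      nxt <- parent[[node]]
      if (is.na(nxt) || !nzchar(nxt) || !(nxt %in% names(parent))) {
        if (node == tx && !(tx %in% names(parent)))
          stop("unknown taxon: ", tx)
        if (is.na(nxt) || !nzchar(nxt)) break
        stop("parent of taxon ", node, " not in taxonomy: ", nxt)
      }
      node <- nxt
    }
  }
  structure(list(parent = parent, rank = rank, name = name, root = roots),
            class = "taxonomy_table")
}

# path from a taxon up to (and including) the root
ancestor_path <- function(taxon, tax) {
  if (!(taxon %in% names(tax$parent))) stop("unknown taxon: ", taxon)
  path <- taxon
  node <- taxon
  while (node != tax$root) {
    node <- tax$parent[[node]]
    path <- c(path, node)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is an ancestor-or-self of every member. Used to name
#' a candidate organism from its supporting reference genomes.
#'
#' @param members non-empty character vector of taxon ids.
#' @param tax a `taxonomy_table`.
#' @return a taxon id.
#' @export
lca <- function(members, tax) {
  stopifnot(length(members) >= 1L, inherits(tax, "taxonomy_table"))
  paths <- lapply(unique(members), ancestor_path, tax = tax)
  first <- paths[[1L]]
  for (node in first) {
    if (all(vapply(paths, function(p) node %in% p, logical(1)))) return(node)
  }
  tax$root
}

#' Greedily cluster reference genomes into candidate organisms
#'
#' Each cluster of reference genomes represents one organism in the sample.
#' Genomes are processed in order of decreasing total mapped reads (ties
#' broken lexicographically by id) so that well-supported genomes seed
#' clusters. Each genome is compared against all existing clusters:
#' (i) if the fraction of its core reads shared with a cluster,
#' |CR_g intersect CR_c| / |CR_g|, reaches `min_cr_overlap`, it joins the
#' cluster with the highest CR overlap; (ii) otherwise, if the fraction of
#' its reads shared with a cluster reaches `min_shared_reads`, it joins the
#' best such cluster (shared reads are less discriminative than shared CR,
#' hence the higher default); (iii) otherwise it founds a new cluster.
#' Cluster CR/read sets are unions over members. Genomes with no CR go
#' directly to stage (ii). Ties between equally good clusters go to the
#' earliest-created cluster.
#'
#' @param profiles named list of `reference_profile` objects.
#' @param cr a `core_read_set` from [extract_core_reads()].
#' @param table the `alignment_table` the profiles were computed from.
#' @param min_cr_overlap minimum fraction of a genome's CR shared with a
#'   cluster for stage (i) (default 0.2).
#' @param min_shared_reads minimum fraction of a genome's reads shared with a
#'   cluster for stage (ii) (default 0.6).
#' @param taxonomy optional `taxonomy_table`; when supplied, each candidate
#'   is named by the LCA of its member organism ids, otherwise
#'   "unclassified".
#' @param taxonomy_hint when TRUE and a taxonomy is available, clusters
#'   containing taxonomic relatives of the genome are scanned first. Since
#'   every cluster is still scanned and the best match taken, results are
#'   identical with the hint on or off; it exists as a scan-order hook for
#'   large reference collections.
#' @return object of class `candidate_set`: list of candidates, each a list
#'   with `cluster_id`, `members` (data.table: organism, gdv, depth,
#'   n_reads, n_unique_reads, quality_band), `n_reads`, `n_cr`, `depth`
#'   (read-count-weighted mean member depth), `lca_taxon`, `abundance`
#'   (filled by [estimate_abundances()]).
#' @export
greedy_cluster <- function(profiles, cr, table,
                           min_cr_overlap = 0.2, min_shared_reads = 0.6,
                           taxonomy = NULL, taxonomy_hint = FALSE) {
  stopifnot(min_cr_overlap >= 0, min_shared_reads >= 0)
  tg <- read_targets(table)
  reads_of <- lapply(split(tg$read_id, tg$organism), unique)
  orgs <- names(profiles)
  orgs <- orgs[orgs %in% names(reads_of)]
  n_reads_of <- vapply(reads_of[orgs], length, integer(1))
  orgs <- orgs[order(-n_reads_of, orgs)]  # C1: support-descending, then id

  clusters <- list()  # each: list(members, cr, reads)
  for (g in orgs) {
    g_cr <- cr$per_organism_cr[[g]]
    g_reads <- reads_of[[g]]
    scan <- seq_along(clusters)
    if (isTRUE(taxonomy_hint) && !is.null(taxonomy) &&
        g %in% names(taxonomy$parent) && length(scan) > 1L) {
      related <- vapply(clusters, function(cl) {
        any(vapply(cl$members, function(m)
          m %in% names(taxonomy$parent) &&
            taxonomy$parent[[m]] == taxonomy$parent[[g]], logical(1)))
      }, logical(1))
      scan <- c(scan[related], scan[!related])
    }
    assigned <- 0L
    # stage (i): CR overlap
    if (length(g_cr) > 0L && length(clusters) > 0L) {
      ov <- vapply(scan, function(i)
        length(intersect(g_cr, clusters[[i]]$cr)) / length(g_cr), numeric(1))
      best <- which(ov >= min_cr_overlap & ov == max(ov))
      if (length(best) > 0L && max(ov) >= min_cr_overlap) {
        cand <- scan[best]
        assigned <- min(cand)  # C3: earliest-created cluster wins
      }
    }
    # stage (ii): shared reads
    if (assigned == 0L && length(clusters) > 0L) {
      ov <- vapply(scan, function(i)
        length(intersect(g_reads, clusters[[i]]$reads)) / length(g_reads),
        numeric(1))
      best <- which(ov >= min_shared_reads & ov == max(ov))
      if (length(best) > 0L && max(ov) >= min_shared_reads) {
        cand <- scan[best]
        assigned <- min(cand)
      }
    }
    if (assigned > 0L) {
      cl <- clusters[[assigned]]
      cl$members <- c(cl$members, g)
      cl$cr <- union(cl$cr, g_cr)
      cl$reads <- union(cl$reads, g_reads)
      clusters[[assigned]] <- cl
    } else {
      clusters[[length(clusters) + 1L]] <-
        list(members = g, cr = g_cr, reads = g_reads)
    }
  }

  cands <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    mem <- rbindlist(lapply(cl$members, function(m) {
      p <- profiles[[m]]
      data.table::data.table(
        organism = m, gdv = p$gdv, depth = p$depth, n_reads = p$n_reads,
        n_unique_reads = p$n_unique_reads, error_rate = p$error_rate,
        ks_p = p$ks_p, quality_band = p$quality_band
      )
    }))
    # C4: members are hypothesized to describe one organism; weight member
    # depths by their read support
    w <- mem$n_reads / sum(mem$n_reads)
    lt <- if (is.null(taxonomy)) "unclassified" else {
      id <- lca(cl$members, taxonomy)
      unname(taxonomy$name[[id]])
    }
    list(cluster_id = sprintf("candidate_%03d", i), members = mem,
         n_reads = length(cl$reads), n_cr = length(cl$cr),
         depth = sum(w * mem$depth), lca_taxon = lt, abundance = NA_real_)
  })
  structure(cands, class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set>", length(x), "candidate organisms\n")
  for (cand in x) {
    cat(sprintf("  %s  %s: %d member(s), %d reads, %d CR, depth %.3g%s\n",
                cand$cluster_id, cand$lca_taxon, nrow(cand$members),
                cand$n_reads, cand$n_cr, cand$depth,
                if (is.na(cand$abundance)) ""
                else sprintf(", abundance %.3g", cand$abundance)))
  }
  invisible(x)
}

#' Estimate relative abundances of candidate organisms
#'
#' Read counts are proportional to genome length times cell abundance; the
#' sequencing depth already normalizes genome length out, so the relative
#' organism (cell-count) abundance is each candidate's depth over the total
#' depth. Read counts remain available per candidate for read-fraction
#' reporting.
#'
#' @param candidates a `candidate_set`.
#' @return the `candidate_set` with `abundance` filled in (sums to 1).
#' @export
estimate_abundances <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (length(candidates) == 0L) return(candidates)
  depths <- vapply(candidates, function(cand) cand$depth, numeric(1))
  tot <- sum(depths)
  if (tot <= 0) {
    warning("all candidate depths are zero; reporting uniform abundances")
    ab <- rep(1 / length(depths), length(depths))
  } else {
    ab <- depths / tot
  }
  for (i in seq_along(candidates)) candidates[[i]]$abundance <- ab[i]
  candidates
}

#' Flatten a candidate set into report tables
#'
#' @param candidates a `candidate_set` (abundances estimated).
#' @return list of two data.tables: `candidates` (one row per candidate,
#'   sorted by abundance descending) and `supports` (one row per supporting
#'   reference genome).
#' @export
candidate_tables <- function(candidates) {
  cand_dt <- rbindlist(lapply(candidates, function(cand) {
    data.table::data.table(
      cluster_id = cand$cluster_id, lca_taxon = cand$lca_taxon,
      n_reads = cand$n_reads, n_cr = cand$n_cr, depth = cand$depth,
      abundance = cand$abundance, n_members = nrow(cand$members)
    )
  }))
  sup_dt <- rbindlist(lapply(candidates, function(cand) {
    data.table::data.table(cluster_id = cand$cluster_id, cand$members)
  }))
  if (nrow(cand_dt) > 0L) {
    setorder(cand_dt, -abundance, cluster_id)
    sup_dt <- sup_dt[order(match(cluster_id, cand_dt$cluster_id), -gdv)]
  }
  list(candidates = cand_dt, supports = sup_dt)
}
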