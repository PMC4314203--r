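#' Run configuration with field-standard defaults
#'
#' Thresholds: reads mapping to more than `max_targets` organisms are
#' discarded (conserved-region filter, default 50); organisms need
#' `min_unique_reads` uniquely mapping reads (default 10); core-read relative
#' depth spread `t` (default 0.2); greedy clustering CR overlap
#' `min_cr_overlap` (default 0.2) and shared-read fraction
#' `min_shared_reads` (default 0.6); `ks_alpha` for flagging inhomogeneous
#' read placement (default 0.05).
#'
#' @param max_targets,min_unique_reads,t,min_cr_overlap,min_shared_reads,ks_alpha
#'   thresholds (see description).
#' @param seed RNG seed recorded in the run summary.
#' @param verbose emit per-stage messages (default TRUE).
#' @return object of class `run_config`.
#' @export
run_config <- function(max_targets = 50L, min_unique_reads = 10L, t = 0.2,
                       min_cr_overlap = 0.2, min_shared_reads = 0.6,
                       ks_alpha = 0.05, seed = 1L, verbose = TRUE) {
  stopifnot(max_targets >= 1, min_unique_reads >= 0, t >= 0,
            min_cr_overlap >= 0, min_cr_overlap <= 1,
            min_shared_reads >= 0, min_shared_reads <= 1,
            ks_alpha > 0, ks_alpha < 1)
  structure(list(max_targets = as.integer(max_targets),
                 min_unique_reads = as.integer(min_unique_reads), t = t,
                 min_cr_overlap = min_cr_overlap,
                 min_shared_reads = min_shared_reads, ks_alpha = ks_alpha,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

say <- function(config, ...) if (config$verbose) message(...)

#' Profile a metagenomic sample from SAM alignments
#'
#' Runs the full pipeline: parse alignments and group sequences into
#' organisms; drop promiscuous reads and weakly supported references;
#' estimate per-reference depth and GDV; extract core reads; cluster
#' references into candidate organisms; estimate abundances. Writes
#' `candidates.tsv` (one row per candidate, sorted by abundance descending),
#' `supports.tsv` (one row per supporting reference genome) and
#' `summary.json` (machine-readable run summary with per-stage counts).
#'
#' @param sam path to SAM/BAM alignments.
#' @param out_dir output directory (created if missing).
#' @param grouping optional path to a 2-column grouping TSV (sequence id,
#'   organism id); absent means each sequence is its own organism.
#' @param taxonomy optional path to a 4-column taxonomy TSV; absent means
#'   every candidate is "unclassified".
#' @param config a [run_config()].
#' @return invisibly, a list with `candidates`, `supports` (data.tables),
#'   `profiles`, `core`, `summary` and the output paths.
#' @export
run_profile <- function(sam, out_dir, grouping = NULL, taxonomy = NULL,
                        config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grp <- if (!is.null(grouping)) read_grouping_tsv(grouping) else NULL
  tax <- if (!is.null(taxonomy)) read_taxonomy_tsv(taxonomy) else NULL

  table <- parse_sam(sam, grp)
  n0_reads <- length(unique(table$aln$read_id))
  n0_orgs <- length(organisms(table))
  say(config, "parsed ", nrow(table$aln), " alignments: ", n0_reads,
      " reads over ", n0_orgs, " organisms")

  table <- filter_promiscuous_reads(table, config$max_targets)
  n1_reads <- length(unique(table$aln$read_id))
  say(config, "promiscuous-read filter (> ", config$max_targets,
      " targets): discarded ", n0_reads - n1_reads, " reads")

  table <- filter_low_support_refs(table, config$min_unique_reads)
  n2_orgs <- length(organisms(table))
  n2_reads <- length(unique(table$aln$read_id))
  say(config, "low-support filter (< ", config$min_unique_reads,
      " unique reads): dropped ", n0_orgs - n2_orgs, " organisms")

  empty <- nrow(table$aln) == 0L
  if (empty) {
    warning("no alignments survive filtering; writing empty report")
    cand_tabs <- list(
      candidates = data.table::data.table(
        cluster_id = character(0), lca_taxon = character(0),
        n_reads = integer(0), n_cr = integer(0), depth = numeric(0),
        abundance = numeric(0), n_members = integer(0)),
      supports = data.table::data.table(
        cluster_id = character(0), organism = character(0),
        gdv = numeric(0), depth = numeric(0), n_reads = integer(0),
        n_unique_reads = integer(0), error_rate = numeric(0),
        ks_p = numeric(0), quality_band = character(0))
    )
    profiles <- list(); core <- NULL; n_cr <- 0L; n_cand <- 0L
  } else {
    profiles <- estimate_profiles(table)
    say(config, "profiled ", length(profiles), " organisms (",
        sum(vapply(profiles, function(p) p$fit_failed, logical(1))),
        " fit failures)")
    core <- extract_core_reads(table, profiles, t = config$t)
    n_cr <- length(core$core)
    say(config, "extracted ", n_cr, " core reads (t = ", config$t, ")")
    cands <- greedy_cluster(profiles, core, table,
                            min_cr_overlap = config$min_cr_overlap,
                            min_shared_reads = config$min_shared_reads,
                            taxonomy = tax)
    cands <- estimate_abundances(cands)
    n_cand <- length(cands)
    say(config, "clustered into ", n_cand, " candidate organisms")
    cand_tabs <- candidate_tables(cands)
  }

  cand_path <- file.path(out_dir, "candidates.tsv")
  sup_path <- file.path(out_dir, "supports.tsv")
  sum_path <- file.path(out_dir, "summary.json")
  fwrite_stable(cand_tabs$candidates, cand_path)
  fwrite_stable(cand_tabs$supports, sup_path)
  summary <- list(
    n_alignments_parsed = nrow(table$aln),
    n_reads_input = n0_reads, n_organisms_input = n0_orgs,
    n_reads_after_promiscuous_filter = n1_reads,
    n_reads_after_support_filter = n2_reads,
    n_organisms_after_filters = if (empty) 0L else length(profiles),
    n_core_reads = n_cr, n_candidates = n_cand,
    config = unclass(config)
  )
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), sum_path)
  invisible(list(candidates = cand_tabs$candidates,
                 supports = cand_tabs$supports,
                 profiles = if (empty) list() else profiles,
                 core = core, summary = summary,
                 paths = c(candidates = cand_path, supports = sup_path,
                           summary = sum_path)))
}

# deterministic TSV writing (fixed number formatting, no scientific notation
# surprises across machines)
fwrite_stable <- function(dt, path) {
  dt <- data.table::copy(dt)
  if (nrow(dt) > 0L) {
    num <- vapply(dt, is.double, logical(1))
    for (cn in names(dt)[num]) {
      data.table::set(dt, j = cn, value = sprintf("%.6g", dt[[cn]]))
    }
  }
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
}

#' Read a community specification from JSON
#'
#' Expected shape: `{"seed": 1, "n_blocks": 10, "min_overlap_fraction": 0.9,
#' "organisms": [...], "references": [...]}` with the organism and reference
#' fields of [community_spec()].
#'
#' @param path JSON file path.
#' @return a `community_spec`.
#' @export
read_community_spec <- function(path) {
  js <- jsonlite::fromJSON(path)
  if (is.null(js$organisms) || is.null(js$references)) {
    stop("community spec must contain 'organisms' and 'references'")
  }
  community_spec(
    organisms = js$organisms, references = js$references,
    n_blocks = if (is.null(js$n_blocks)) 10L else js$n_blocks,
    min_overlap_fraction = if (is.null(js$min_overlap_fraction)) 0.9
                           else js$min_overlap_fraction,
    seed = if (is.null(js$seed)) 1L else js$seed
  )
}

#' Simulate a community from a JSON spec file
#'
#' @param spec_file path to a JSON community spec ([read_community_spec()]).
#' @param out_dir output directory.
#' @return invisibly, the [simulate_community()] result; prints the truth
#'   table path.
#' @export
run_simulate <- function(spec_file, out_dir) {
  spec <- read_community_spec(spec_file)
  res <- simulate_community(spec, out_dir)
  message("truth table: ", res$truth_path)
  invisible(res)
}
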