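#' Is a read a core read?
#'
#' A read is a core read (CR) when all reference genomes it maps to have
#' near-identical local sequencing depth: (max(D) - min(D)) / mean(D) <= t,
#' where D are the depths of the read's target genomes. Such reads likely
#' originate from a genomic region unique to one organism in the sample --
#' if the region were shared between sample organisms, the targets would
#' typically differ in depth. A single-target read passes trivially.
#'
#' @param depths non-empty numeric vector of local sequencing depths (> 0) of
#'   the read's target organisms.
#' @param t relative spread threshold (> 0; default 0.2).
#' @return logical.
#' @export
is_core_read <- function(depths, t = 0.2) {
  if (length(depths) == 0L) stop("empty depth list")
  stopifnot(t >= 0, all(depths > 0))
  (max(depths) - min(depths)) / mean(depths) <= t
}

#' Extract the core-read set
#'
#' Applies the core-read criterion to every read in the table, using the
#' per-organism depth estimates from [estimate_profiles()]. Reads targeting
#' any organism whose mixture fit failed (no depth estimate exists) are
#' excluded: the CR criterion is a depth comparison.
#'
#' @param table an `alignment_table` (after filtering).
#' @param profiles named list of `reference_profile` objects, or a named
#'   numeric vector of depths per organism.
#' @param t relative spread threshold (default 0.2). Higher values classify
#'   more reads as CR, tolerating less accurate depth estimates.
#' @return object of class `core_read_set`: list with `core` (character
#'   vector of read ids) and `per_organism_cr` (named list: organism id to
#'   its CR read ids).
#' @export
extract_core_reads <- function(table, profiles, t = 0.2) {
  stopifnot(t >= 0)
  if (is.list(profiles)) {
    ok <- !vapply(profiles, function(p) isTRUE(p$fit_failed), logical(1))
    depth_of <- vapply(profiles[ok], function(p) p$depth, numeric(1))
  } else {
    depth_of <- profiles[!is.na(profiles)]
  }
  tg <- read_targets(table)
  tg[, depth := depth_of[organism]]
  crit <- tg[, list(
    usable = !anyNA(depth),
    rel_spread = if (anyNA(depth)) NA_real_
                 else (max(depth) - min(depth)) / mean(depth)
  ), by = read_id]
  core <- crit[crit$usable & crit$rel_spread <= t, read_id]
  cr_tg <- tg[read_id %chin% core]
  per_org <- lapply(split(cr_tg$read_id, cr_tg$organism), unique)
  structure(list(core = core, per_organism_cr = per_org),
            class = "core_read_set")
}

#' @export
print.core_read_set <- function(x, ...) {
  cat("<core_read_set>", length(x$core), "core reads over",
      length(x$per_organism_cr), "organisms\n")
  invisible(x)
}
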