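#' Build an organism grouping for reference sequences
#'
#' Multiple reference sequences (chromosomes, plasmids) belonging to the same
#' assembly are analysed as one organism. A grouping maps each reference
#' sequence id to an organism id; the organism length is the sum of its member
#' sequence lengths.
#'
#' @param seq_to_organism named character vector: names are reference sequence
#'   ids, values are organism ids.
#' @param seq_lengths named integer/numeric vector of sequence lengths in
#'   bases, with names matching `seq_to_organism`.
#' @return An object of class `organism_grouping`: a list with
#'   `seq_to_organism` and `organism_length` (named numeric, bases).
#' @export
organism_grouping <- function(seq_to_organism, seq_lengths) {
  stopifnot(is.character(seq_to_organism), !is.null(names(seq_to_organism)))
  missing_len <- setdiff(names(seq_to_organism), names(seq_lengths))
  if (length(missing_len) > 0L) {
    stop("no length available for reference sequence(s): ",
         paste(missing_len, collapse = ", "))
  }
  lens <- as.numeric(seq_lengths[names(seq_to_organism)])
  org_len <- tapply(lens, seq_to_organism, sum)
  structure(
    list(
      seq_to_organism = seq_to_organism,
      organism_length = setNames(as.numeric(org_len), names(org_len))
    ),
    class = "organism_grouping"
  )
}

#' Read a sequence-to-organism grouping file
#'
#' Two-column TSV (no header): reference sequence id, organism id. Lengths are
#' taken from the SAM header at parse time.
#'
#' @param path path to a TSV file.
#' @return named character vector mapping sequence id to organism id.
#' @export
read_grouping_tsv <- function(path) {
  g <- data.table::fread(path, header = FALSE, sep = "\t",
                         colClasses = "character")
  if (ncol(g) < 2L) stop("grouping file must have 2 tab-separated columns")
  setNames(g[[2L]], g[[1L]])
}

new_alignment_table <- function(aln, ref_lengths, grouping) {
  stopifnot(data.table::is.data.table(aln))
  bad <- setdiff(unique(aln$ref_id), names(ref_lengths))
  if (length(bad) > 0L) {
    stop("alignments refer to sequence(s) without length: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(aln = aln, ref_lengths = ref_lengths, grouping = grouping),
    class = "alignment_table"
  )
}

#' @export
print.alignment_table <- function(x, ...) {
  cat("<alignment_table>", nrow(x$aln), "alignments,",
      length(unique(x$aln$read_id)), "reads,",
      length(unique(x$aln$organism)), "organisms,",
      length(x$ref_lengths), "reference sequences\n")
  invisible(x)
}

# subset alignments of one organism (plain-vector comparison: an argument
# named like a column must never be resolved inside a data.table frame)
org_alns <- function(table, org_id) {
  sel <- table$aln$organism == org_id
  table$aln[sel]
}

# distinct (read, organism) target pairs
read_targets <- function(table) {
  unique(table$aln[, list(read_id, organism)])
}

#' Organisms present in an alignment table
#' @param table an `alignment_table`.
#' @return character vector of organism ids with at least one alignment.
#' @export
organisms <- function(table) {
  sort(unique(table$aln$organism))
}

# edit distance fallback when the NM tag is missing: mismatch ops in an
# extended CIGAR (X) plus inserted/deleted bases; all-M CIGARs carry no
# mismatch information and yield 0.
edit_from_cigar <- function(cigar) {
  tab <- GenomicAlignments::cigarOpTable(cigar)
  as.integer(tab[, "X"] + tab[, "I"] + tab[, "D"])
}

# htslib only warns and truncates on a bad SAM line; cross-check that every
# alignment line survived conversion and name the first offending line
assert_sam_complete <- function(sam_path, bam_path) {
  lines <- readLines(sam_path)
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  n_records <- Rsamtools::countBam(Rsamtools::BamFile(bam_path))$records
  if (n_records == length(body)) return(invisible(TRUE))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    ok <- length(f) >= 11L && !is.na(suppressWarnings(as.integer(f[2L]))) &&
      !is.na(suppressWarnings(as.integer(f[4L])))
    if (!ok) stop("malformed SAM line ", i, " in '", sam_path, "'",
                  call. = FALSE)
  }
  stop("malformed SAM input '", sam_path, "': ", length(body) - n_records,
       " line(s) rejected during parsing", call. = FALSE)
}

#' Parse SAM alignments into an alignment table
#'
#' Reads a SAM (or BAM) file of metagenomic reads mapped against a collection
#' of reference genomes, keeping all mappings of multi-mapping reads
#' (secondary and supplementary alignments included: every placement of a read
#' is evidence). Unmapped records are dropped. Positions are stored 0-based.
#' Per-alignment edit distances come from the NM tag when present, otherwise
#' from mismatch/indel operations of an extended CIGAR, otherwise 0 (with a
#' warning).
#'
#' @param path path to a SAM or BAM file with `@SQ` header lines.
#' @param grouping optional named character vector (sequence id to organism
#'   id, as from [read_grouping_tsv()]) or an `organism_grouping`. When
#'   absent, each reference sequence is its own organism.
#' @return An `alignment_table`: alignments (`read_id`, `ref_id`, `organism`,
#'   `pos` 0-based, `aln_len` reference bases, `edit_distance`), per-sequence
#'   lengths, and the organism grouping.
#' @export
parse_sam <- function(path, grouping = NULL) {
  if (!file.exists(path)) stop("no such alignment file: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("malformed SAM input '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  if (bam != path) assert_sam_complete(path, bam)
  param <- Rsamtools::ScanBamParam(
    what = "qname", tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  gal <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  seq_lens <- GenomeInfoDb::seqlengths(gal)
  if (anyNA(seq_lens)) {
    stop("SAM header lacks @SQ length for: ",
         paste(names(seq_lens)[is.na(seq_lens)], collapse = ", "))
  }

  if (is.null(grouping)) {
    seq_to_org <- setNames(names(seq_lens), names(seq_lens))
  } else if (inherits(grouping, "organism_grouping")) {
    seq_to_org <- grouping$seq_to_organism
  } else {
    seq_to_org <- grouping
  }
  missing_grp <- setdiff(names(seq_lens), names(seq_to_org))
  if (length(missing_grp) > 0L) {
    # header sequences the grouping does not mention become their own organism
    seq_to_org <- c(seq_to_org, setNames(missing_grp, missing_grp))
  }
  grp <- organism_grouping(seq_to_org[names(seq_lens)], seq_lens)
  if (inherits(grouping, "organism_grouping")) {
    common <- intersect(names(grouping$organism_length),
                        names(grp$organism_length))
    if (any(grouping$organism_length[common] != grp$organism_length[common])) {
      stop("organism lengths in grouping conflict with SAM @SQ lengths")
    }
  }

  nm <- S4Vectors::mcols(gal)$NM
  ed <- as.integer(nm)
  if (anyNA(ed)) {
    miss <- is.na(ed)
    cig_ed <- edit_from_cigar(GenomicAlignments::cigar(gal)[miss])
    no_info <- !grepl("[XID]", GenomicAlignments::cigar(gal)[miss])
    if (any(no_info)) {
      warning(sum(no_info), " alignment(s) without NM tag or extended CIGAR; ",
              "edit distance recorded as 0")
    }
    ed[miss] <- cig_ed
  }

  rid <- as.character(GenomeInfoDb::seqnames(gal))
  aln <- data.table::data.table(
    read_id = S4Vectors::mcols(gal)$qname,
    ref_id = rid,
    organism = unname(seq_to_org[rid]),
    pos = GenomicAlignments::start(gal) - 1L,
    aln_len = GenomicAlignments::width(gal),
    edit_distance = ed
  )
  new_alignment_table(aln, seq_lens, grp)
}

#' Discard reads from highly conserved regions
#'
#' Reads mapping to many distinct organisms (e.g. 16S rRNA reads) carry no
#' information about which organism they came from and can drown out the
#' signal of rare community members; all alignments of any read with more than
#' `max_targets` distinct organism targets are removed.
#'
#' @param table an `alignment_table`.
#' @param max_targets maximum number of distinct organism targets a read may
#'   have (default 50).
#' @return filtered `alignment_table`.
#' @export
filter_promiscuous_reads <- function(table, max_targets = 50L) {
  stopifnot(inherits(table, "alignment_table"), max_targets >= 1L)
  tg <- read_targets(table)[, list(n_targets = .N), by = read_id]
  keep <- tg[n_targets <= max_targets, read_id]
  aln <- table$aln[read_id %chin% keep]
  new_alignment_table(aln, table$ref_lengths, table$grouping)
}

# unique-read counts per organism: a read is unique for an organism when that
# organism is its only target in the current table
unique_read_counts <- function(table) {
  tg <- read_targets(table)
  tg[, n_targets := .N, by = read_id]
  cnt <- tg[n_targets == 1L, list(n_unique = .N), by = organism]
  all_org <- unique(table$aln$organism)
  out <- setNames(rep(0L, length(all_org)), all_org)
  out[cnt$organism] <- cnt$n_unique
  out
}

#' Drop reference organisms without sufficient unique-read support
#'
#' Organisms whose alignments could all be explained by other organisms
#' (fewer than `min_unique_reads` reads mapping only to them) are removed
#' together with their alignments; remaining reads' target sets shrink
#' accordingly.
#'
#' @param table an `alignment_table`.
#' @param min_unique_reads minimum number of uniquely mapping reads an
#'   organism needs to be kept (default 10).
#' @return filtered `alignment_table`.
#' @export
filter_low_support_refs <- function(table, min_unique_reads = 10L) {
  stopifnot(inherits(table, "alignment_table"), min_unique_reads >= 0L)
  if (min_unique_reads == 0L) return(table)
  cnt <- unique_read_counts(table)
  keep <- names(cnt)[cnt >= min_unique_reads]
  aln <- table$aln[organism %chin% keep]
  new_alignment_table(aln, table$ref_lengths, table$grouping)
}

#' Mean per-base mapping error rate of an organism's alignments
#'
#' The mean of edit_distance / alignment length over all alignments to the
#' organism. High values (e.g. above 0.1) indicate that the reads diverge
#' strongly from the reference sequence.
#'
#' @param table an `alignment_table`.
#' @param organism organism id.
#' @return fraction in \[0, 1\].
#' @export
mapping_error_rate <- function(table, organism) {
  a <- org_alns(table, organism)
  if (nrow(a) == 0L) stop("unknown organism: ", organism)
  mean(a$edit_distance / a$aln_len)
}
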