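#' Specify a synthetic metagenomic community
#'
#' Defines the ground truth for a simulated experiment: sample organisms with
#' genome length, sequencing depth, read length and base error rate; and
#' reference genomes, each derived from one organism by keeping a chosen
#' fraction of its sequence (the true GDV) with a chosen substitution rate in
#' the kept regions and replacing the rest with unrelated random sequence.
#'
#' @param organisms data.frame with columns `organism`, `genome_length`,
#'   `depth`, `read_length`, `base_error_rate`.
#' @param references data.frame with columns `ref_id`, `organism`,
#'   `shared_fraction` (in (0, 1\]), `divergence` (substitution rate in
#'   shared regions).
#' @param n_blocks number of contiguous shared blocks per reference
#'   (default 10); shared sequence occurs in blocks, as homology does, so
#'   spacing histograms see realistic gap structure.
#' @param min_overlap_fraction fraction of a read's footprint that must fall
#'   in shared blocks for an alignment to be emitted (default 0.9; emulates a
#'   read mapper's tolerance).
#' @param seed RNG seed.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(organisms, references, n_blocks = 10L,
                           min_overlap_fraction = 0.9, seed = 1L) {
  organisms <- as.data.table(organisms)
  references <- as.data.table(references)
  need_o <- c("organism", "genome_length", "depth", "read_length",
              "base_error_rate")
  need_r <- c("ref_id", "organism", "shared_fraction", "divergence")
  if (!all(need_o %in% names(organisms)))
    stop("organisms must have columns: ", paste(need_o, collapse = ", "))
  if (!all(need_r %in% names(references)))
    stop("references must have columns: ", paste(need_r, collapse = ", "))
  stopifnot(all(organisms$depth > 0),
            all(organisms$read_length < organisms$genome_length),
            all(references$shared_fraction > 0),
            all(references$shared_fraction <= 1),
            all(references$divergence >= 0),
            all(references$organism %in% organisms$organism))
  structure(list(organisms = organisms, references = references,
                 n_blocks = as.integer(n_blocks),
                 min_overlap_fraction = min_overlap_fraction,
                 seed = as.integer(seed)),
            class = "community_spec")
}

random_genome <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Generate organism genome sequences
#'
#' I.i.d.-uniform nucleotide sequences per organism; different organisms are
#' independent draws and share no designed homology.
#'
#' @param spec a `community_spec`.
#' @return named character vector of genome sequences, plus the truth-table
#'   skeleton as attribute `truth` (data.table: organism, genome_length,
#'   depth, true_abundance with depth-proportional abundances).
#' @export
make_genomes <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  g <- setNames(
    vapply(spec$organisms$genome_length, random_genome, character(1)),
    spec$organisms$organism
  )
  truth <- data.table::copy(spec$organisms)
  truth[, "true_abundance" := depth / sum(depth)]
  attr(g, "truth") <- truth
  g
}

# shared-block layout: n_blocks of near-equal length totalling floor(f * L)
# bases, separated by gaps whose lengths follow a broken-stick split of the
# unshared remainder (n_blocks + 1 gaps, including the genome ends), so gap
# positions are unstructured -- as homologous segments between genomes are
shared_blocks <- function(genome_length, shared_fraction, n_blocks) {
  L <- genome_length
  total <- floor(shared_fraction * L)
  blk <- floor(total / n_blocks)
  lens <- rep(blk, n_blocks)
  extra <- total - sum(lens)
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  gap_total <- L - total
  cuts <- sort(runif(n_blocks))
  gaps <- floor(diff(c(0, cuts, 1)) * gap_total)
  gaps[1L] <- gaps[1L] + (gap_total - sum(gaps))
  starts <- cumsum(gaps[seq_len(n_blocks)]) +
    c(0, cumsum(lens[-n_blocks])) + 1L  # 1-based
  keep <- lens > 0
  IRanges::IRanges(start = starts[keep], width = lens[keep])
}

#' Derive a reference genome at a chosen shared fraction
#'
#' Builds a reference of the same length as the organism genome: a set of
#' contiguous blocks totalling `floor(shared_fraction * L)` bases is copied
#' from the genome (with i.i.d. substitutions at rate `divergence`); the
#' complement is replaced by fresh random sequence. Blocks are copied in
#' place, so genome and reference share coordinates. The true GDV of the
#' reference equals `shared_fraction`.
#'
#' @param genome organism genome sequence (character scalar).
#' @param shared_fraction fraction of the reference shared with the genome.
#' @param divergence substitution rate within shared blocks.
#' @param n_blocks number of shared blocks (default 10).
#' @param seed RNG seed.
#' @return list with `sequence`, `blocks` (IRanges, 1-based, shared block
#'   layout), `sub_pos` (sorted 1-based positions of planted substitutions),
#'   `shared_bases`.
#' @export
derive_reference <- function(genome, shared_fraction, divergence,
                             n_blocks = 10L, seed = 1L) {
  stopifnot(shared_fraction > 0, shared_fraction <= 1, divergence >= 0)
  set.seed(seed)
  L <- nchar(genome)
  if (shared_fraction == 1 && divergence == 0) {
    return(list(sequence = genome,
                blocks = IRanges::IRanges(1L, L),
                sub_pos = integer(0), shared_bases = L))
  }
  blocks <- shared_blocks(L, shared_fraction, n_blocks)
  chars <- strsplit(random_genome(L), "", fixed = TRUE)[[1L]]
  gchars <- strsplit(genome, "", fixed = TRUE)[[1L]]
  shared_idx <- unlist(lapply(seq_along(blocks), function(i)
    seq.int(IRanges::start(blocks)[i], IRanges::end(blocks)[i])),
    use.names = FALSE)
  chars[shared_idx] <- gchars[shared_idx]
  sub_pos <- integer(0)
  if (divergence > 0) {
    hit <- runif(length(shared_idx)) < divergence
    sub_pos <- sort(shared_idx[hit])
    if (length(sub_pos) > 0L) {
      alt <- c("A", "C", "G", "T")
      repl <- vapply(chars[sub_pos], function(b)
        sample(setdiff(alt, b), 1L), character(1))
      chars[sub_pos] <- repl
    }
  }
  list(sequence = paste(chars, collapse = ""), blocks = blocks,
       sub_pos = sub_pos, shared_bases = sum(IRanges::width(blocks)))
}

#' Sample shotgun reads from a genome at uniform depth
#'
#' The read count is Poisson(depth * L / read_length); start positions are
#' uniform over the genome; per-read substitution error counts are
#' Binomial(read_length, base_error_rate).
#'
#' @param genome_length genome length in bases.
#' @param depth target sequencing depth (x-coverage).
#' @param read_length read length in bases.
#' @param base_error_rate per-base substitution error rate.
#' @param seed RNG seed.
#' @param prefix read-id prefix.
#' @return data.table with `read_id`, `start` (1-based source locus),
#'   `len`, `n_err`.
#' @export
sample_reads <- function(genome_length, depth, read_length, base_error_rate,
                         seed = 1L, prefix = "r") {
  stopifnot(depth > 0, read_length < genome_length)
  set.seed(seed)
  n <- rpois(1L, depth * genome_length / read_length)
  data.table::data.table(
    read_id = sprintf("%s_%06d", prefix, seq_len(n)),
    start = sample.int(genome_length - read_length + 1L, n, replace = TRUE),
    len = read_length,
    n_err = rbinom(n, read_length, base_error_rate)
  )
}

#' Materialize read sequences (with planted errors)
#'
#' @param genome genome sequence.
#' @param reads data.table from [sample_reads()].
#' @param seed RNG seed for error placement.
#' @return character vector of read sequences.
#' @export
read_sequences <- function(genome, reads, seed = 1L) {
  set.seed(seed)
  seqs <- substring(genome, reads$start, reads$start + reads$len - 1L)
  alt <- c("A", "C", "G", "T")
  for (i in which(reads$n_err > 0L)) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    at <- sample.int(length(ch), reads$n_err[i])
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(alt, b), 1L),
                     character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Write multi-mapping alignments as SAM by coordinate bookkeeping
#'
#' Instead of running a read mapper, alignments are derived from the known
#' shared-block layout: a read is emitted as an alignment to every reference
#' whose shared blocks contain at least `min_overlap_fraction` of the read's
#' source footprint, at the coordinate implied by the in-place block copy.
#' The edit distance is the number of planted reference substitutions within
#' the aligned span plus the read's own sequencing errors. The first emitted
#' alignment of a read is primary, further ones carry the secondary flag.
#'
#' @param reads_by_org named list (organism id -> data.table from
#'   [sample_reads()]).
#' @param references named list (ref_id -> list as from [derive_reference()]
#'   plus field `organism`).
#' @param ref_lengths named vector of reference lengths.
#' @param path output SAM path.
#' @param min_overlap_fraction required footprint overlap (default 0.9).
#' @return invisibly, the number of alignment lines written.
#' @export
write_alignments <- function(reads_by_org, references, ref_lengths, path,
                             min_overlap_fraction = 0.9) {
  rows <- list()
  for (rid in names(references)) {
    ref <- references[[rid]]
    reads <- reads_by_org[[ref$organism]]
    if (is.null(reads) || nrow(reads) == 0L) next
    cov <- IRanges::coverage(ref$blocks, width = ref_lengths[[rid]])
    ir <- IRanges::IRanges(start = reads$start, width = reads$len)
    inside <- IRanges::Views(cov, ir)
    ovl <- IRanges::viewSums(inside)
    keep <- ovl >= min_overlap_fraction * reads$len
    if (!any(keep)) next
    kr <- reads[keep]
    planted <- if (length(ref$sub_pos) == 0L) integer(nrow(kr)) else {
      findInterval(kr$start + kr$len - 1L, ref$sub_pos) -
        findInterval(kr$start - 1L, ref$sub_pos)
    }
    rows[[rid]] <- data.table::data.table(
      read_id = kr$read_id, ref_id = rid, pos = kr$start, len = kr$len,
      nm = planted + kr$n_err
    )
  }
  aln <- rbindlist(rows)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  if (nrow(aln) == 0L) {
    writeLines(hdr, path)
    return(invisible(0L))
  }
  setorder(aln, read_id, ref_id)
  aln[, flag := ifelse(duplicated(read_id), 256L, 0L)]
  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                   aln$read_id, aln$flag, aln$ref_id, aln$pos, aln$len,
                   aln$nm)
  writeLines(c(hdr, lines), path)
  invisible(nrow(aln))
}

#' Simulate a complete synthetic community experiment
#'
#' Runs the whole simulator: genomes, references, reads, SAM, grouping and
#' truth table. All randomness derives from `spec$seed`.
#'
#' @param spec a `community_spec`.
#' @param out_dir output directory (created if missing).
#' @param write_fasta also write reference sequences as FASTA (default TRUE).
#' @return list with paths (`sam`, `grouping`, `truth`, optionally `fasta`)
#'   and in-memory objects: `truth` (list of data.tables `organisms`,
#'   `references`), `reads_by_org`, `references`.
#' @export
simulate_community <- function(spec, out_dir, write_fasta = TRUE) {
  stopifnot(inherits(spec, "community_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- make_genomes(spec)
  org_truth <- attr(genomes, "truth")

  refs <- list()
  ref_truth <- list()
  for (i in seq_len(nrow(spec$references))) {
    r <- spec$references[i]
    ref <- derive_reference(
      genomes[[r$organism]], r$shared_fraction, r$divergence,
      n_blocks = spec$n_blocks,
      seed = spec$seed + 1000L + i
    )
    ref$organism <- r$organism
    refs[[r$ref_id]] <- ref
    ref_truth[[i]] <- data.table::data.table(
      ref_id = r$ref_id, organism = r$organism,
      true_gdv = ref$shared_bases / nchar(ref$sequence),
      divergence = r$divergence,
      true_identity = 1 - r$divergence
    )
  }
  ref_lengths <- setNames(
    vapply(refs, function(x) nchar(x$sequence), numeric(1)), names(refs))

  reads_by_org <- list()
  for (i in seq_len(nrow(spec$organisms))) {
    o <- spec$organisms[i]
    reads_by_org[[o$organism]] <- sample_reads(
      o$genome_length, o$depth, o$read_length, o$base_error_rate,
      seed = spec$seed + 2000L + i, prefix = o$organism
    )
  }

  sam <- file.path(out_dir, "alignments.sam")
  write_alignments(reads_by_org, refs, ref_lengths, sam,
                   min_overlap_fraction = spec$min_overlap_fraction)

  grouping <- file.path(out_dir, "grouping.tsv")
  data.table::fwrite(
    data.table::data.table(seq = names(refs), org = names(refs)),
    grouping, sep = "\t", col.names = FALSE)

  truth_path <- file.path(out_dir, "truth.tsv")
  rt <- rbindlist(ref_truth)
  tt <- merge(rt, org_truth, by = "organism", sort = FALSE)
  data.table::fwrite(tt, truth_path, sep = "\t")

  out <- list(sam = sam, grouping = grouping, truth_path = truth_path,
              truth = list(organisms = org_truth, references = rt),
              reads_by_org = reads_by_org, references = refs)
  if (write_fasta) {
    fasta <- file.path(out_dir, "references.fasta")
    seqs <- Biostrings::DNAStringSet(
      setNames(vapply(refs, `[[`, character(1), "sequence"), names(refs)))
    Biostrings::writeXStringSet(seqs, fasta)
    out$fasta <- fasta
  }
  out
}
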