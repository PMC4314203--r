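# fixture builders shared across test files; everything is generated in code

# write a small SAM file from alignment rows
# sq: named integer vector of sequence lengths
# rows: data.frame(read, ref, pos1 (1-based), len, nm); nm = NA omits the tag
write_sam_fixture <- function(sq, rows = NULL, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sq), as.integer(sq)))
  lines <- character(0)
  if (!is.null(rows) && nrow(rows) > 0L) {
    seen <- character(0)
    lines <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      flag <- if (r$read %in% seen) 256L else 0L
      seen <<- c(seen, r$read)
      base <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                      r$read, flag, r$ref, r$pos1, r$len)
      if (!is.na(r$nm)) paste0(base, sprintf("\tNM:i:%d", r$nm)) else base
    }, character(1))
  }
  writeLines(c(hdr, lines), path)
  path
}

# alignment table straight from rows (via the SAM round trip)
fixture_table <- function(sq, rows, grouping = NULL) {
  parse_sam(write_sam_fixture(sq, rows), grouping)
}

# a coverage histogram from an explicit depth -> positions map
make_cov_hist <- function(counts, genome_length = sum(counts)) {
  structure(list(counts = counts, genome_length = genome_length),
            class = "coverage_histogram")
}

# a start-distance histogram from raw spacings
make_sdh <- function(dists, genome_length, n_reads = length(dists) + 1L,
                     mean_read_len = 100) {
  tab <- table(dists)
  structure(list(counts = stats::setNames(as.numeric(tab), names(tab)),
                 n_reads = n_reads, genome_length = genome_length,
                 mean_read_len = mean_read_len),
            class = "start_distance_histogram")
}

# single-organism, single-reference community at given depth / shared fraction
one_ref_community <- function(depth, shared_fraction, genome_length = 1e6,
                              divergence = 0.01, seed = 1L,
                              read_length = 100) {
  spec <- community_spec(
    organisms = data.frame(organism = "org", genome_length = genome_length,
                           depth = depth, read_length = read_length,
                           base_error_rate = 0.005),
    references = data.frame(ref_id = "ref", organism = "org",
                            shared_fraction = shared_fraction,
                            divergence = divergence),
    seed = seed
  )
  simulate_community(spec, tempfile("sim"), write_fasta = FALSE)
}

# three organisms at staggered depths, two similar references each; the two
# references of one organism each share a large but distinct part of the
# organism genome, so both keep unique reads
three_org_spec <- function(seed = 7L, genome_length = 5e5,
                           depths = c(8, 2, 0.5)) {
  orgs <- paste0("org", 1:3)
  community_spec(
    organisms = data.frame(organism = orgs, genome_length = genome_length,
                           depth = depths, read_length = 100,
                           base_error_rate = 0.005),
    references = data.frame(
      ref_id = paste0(rep(orgs, each = 2), c("_refA", "_refB")),
      organism = rep(orgs, each = 2),
      shared_fraction = rep(c(0.97, 0.95), 3),
      divergence = rep(c(0.005, 0.01), 3)
    ),
    seed = seed
  )
}

# toy 7-node taxonomy: root -> bacteria -> (speciesX -> strains x1,x2), archaea
toy_taxonomy <- function() {
  taxonomy_table(
    parent = c(root = "root", bacteria = "root", archaea = "root",
               speciesX = "bacteria", x1 = "speciesX", x2 = "speciesX",
               y1 = "archaea"),
    rank = c(root = "root", bacteria = "domain", archaea = "domain",
             speciesX = "species", x1 = "strain", x2 = "strain",
             y1 = "strain")
  )
}

# random rooted taxonomy: each non-root node gets a random earlier parent
random_taxonomy <- function(n, seed) {
  set.seed(seed)
  ids <- c("root", paste0("t", seq_len(n - 1L)))
  parent <- c("root", vapply(2:n, function(i)
    ids[sample.int(i - 1L, 1L)], character(1)))
  taxonomy_table(stats::setNames(parent, ids))
}

# brute-force LCA oracle: intersect full ancestor paths, take deepest
lca_oracle <- function(members, tax) {
  path <- function(x) {
    p <- x
    while (x != tax$root) {
      x <- tax$parent[[x]]
      p <- c(p, x)
    }
    p
  }
  paths <- lapply(members, path)
  common <- Reduce(intersect, paths)
  depth_of <- function(x) length(path(x))
  common[which.max(vapply(common, depth_of, integer(1)))]
}
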