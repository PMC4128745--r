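#' In silico restriction fingerprinting and genome summaries
#'
#' Restriction-fragment length fingerprints (e.g. HhaI, recognition GCGC,
#' cleaving GCG^C) computed from genome sequences, compared by Dice
#' band-matching with a fragment-size tolerance and a noise floor, and
#' clustered by neighbor joining. Genome-level summary statistics (length,
#' G+C, coding fraction) and a codon-usage / tRNA-match comparison complete
#' the module.
#'
#' @name genotyping
NULL

#' Construct a genome record
#'
#' @param id Sequence identifier.
#' @param sequence DNA string over A, C, G, T, N (lowercase accepted,
#'   uppercased on load).
#' @param topology \code{"linear"} (default) or \code{"circular"}.
#' @return List of class \code{"genome_record"}.
#' @export
genome_record <- function(id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) pc_stop("genome sequence must be non-empty")
  bad <- regmatches(sequence, regexpr("[^ACGTN]", sequence))
  if (length(bad) && nzchar(bad)) {
    pos <- regexpr("[^ACGTN]", sequence)
    pc_stop(sprintf("illegal character '%s' at position %d in record '%s'",
                    bad, pos, id))
  }
  structure(list(id = as.character(id), sequence = sequence, topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s\n", x$id, nchar(x$sequence), x$topology))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' Sequences are uppercased; record ids are the first whitespace-delimited
#' token of each header. Non-ACGTN characters are rejected; 'N' runs are
#' accepted and flagged.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology assigned to every record.
#' @return Named list of \code{\link{genome_record}}s. Records containing
#'   N bases carry attribute \code{has_n = TRUE}.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) pc_stop(sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) pc_stop("FASTA file contains no records")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    rec <- genome_record(ids[i], as.character(set[[i]]), topology = topology)
    if (grepl("N", rec$sequence, fixed = TRUE)) attr(rec, "has_n") <- TRUE
    out[[i]] <- rec
  }
  names(out) <- ids
  out
}

#' In silico restriction digest
#'
#' Finds all occurrences of a recognition motif on the forward strand (the
#' default HhaI site GCGC is its own reverse complement, so one strand
#' suffices) and cuts after \code{cut_offset} bases within each occurrence
#' (GCG^C: offset 3). Overlapping occurrences are all counted. Sites
#' containing N are not matched (and a warning notes the presence of N).
#' For a linear genome the fragment lengths sum to the genome length and
#' number cuts + 1; for a circular genome the count equals the number of
#' cuts (one full-length pseudo-fragment if uncut).
#'
#' @param genome A \code{\link{genome_record}}.
#' @param site Recognition motif (default \code{"GCGC"}).
#' @param cut_offset Cut position within the motif, 0..nchar(site)
#'   (default 3).
#' @return A \code{fingerprint} object: \code{genome_id}, \code{enzyme}
#'   (the motif), \code{fragment_lengths} (descending),
#'   \code{noise_floor_applied = FALSE}.
#' @examples
#' digest(genome_record("toy", "GCGCAAGCGC"))$fragment_lengths  # 6 3 1
#' @export
digest <- function(genome, site = "GCGC", cut_offset = 3) {
  stopifnot(inherits(genome, "genome_record"))
  site <- toupper(site)
  if (nchar(site) < 1L) pc_stop("`site` must have length >= 1")
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    pc_stop("`cut_offset` must lie in 0..nchar(site)")
  }
  seq <- genome$sequence
  L <- nchar(seq)
  if (grepl("N", seq, fixed = TRUE)) {
    pc_warn("sequence contains N: motif occurrences overlapping N are skipped")
  }
  circular <- genome$topology == "circular"
  scan_seq <- if (circular && L > nchar(site)) {
    paste0(seq, substr(seq, 1, nchar(site) - 1L))
  } else {
    seq
  }
  m <- Biostrings::matchPattern(site, Biostrings::DNAString(scan_seq), fixed = TRUE)
  starts <- Biostrings::start(m)
  if (circular) starts <- starts[starts <= L]
  cuts <- starts + cut_offset - 1L          # cut falls after this 1-based position

  if (circular) {
    cuts <- sort(unique(cuts %% L))          # position 0 == cut after base L
    if (!length(cuts)) {
      fragments <- L                         # uncut: full-length pseudo-fragment
    } else {
      fragments <- diff(c(cuts, cuts[1] + L))
    }
  } else {
    cuts <- sort(unique(cuts[cuts >= 1L & cuts < L]))  # cuts at 0 or L cut nothing off
    fragments <- diff(c(0L, cuts, L))
  }
  structure(list(
    genome_id = genome$id,
    enzyme = site,
    fragment_lengths = sort(as.integer(fragments), decreasing = TRUE),
    noise_floor_applied = FALSE
  ), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s / %s: %d fragments (%s)\n",
              x$genome_id, x$enzyme, length(x$fragment_lengths),
              paste(utils::head(x$fragment_lengths, 8), collapse = ", ")))
  invisible(x)
}

# Noise floor: discard bands shorter than `noise_frac` of the profile's
# longest band (small fragments are unreliably sized on a fluorescent trace).
apply_noise_floor <- function(lengths, noise_frac) {
  if (!length(lengths)) return(lengths)
  lengths[lengths >= noise_frac * max(lengths)]
}

# Greedy one-to-one matching of two ascending-sorted band lists within
# `tol` bp; returns the number of matched pairs.
greedy_band_matches <- function(a, b, tol) {
  i <- 1L; j <- 1L; m <- 0L
  na <- length(a); nb <- length(b)
  while (i <= na && j <= nb) {
    d <- a[i] - b[j]
    if (abs(d) <= tol) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  m
}

#' Band-matching similarity of two fingerprints
#'
#' Dice band-matching: after applying the noise floor to each profile
#' (bands shorter than \code{noise_frac} of that profile's longest band
#' are discarded), bands are matched one-to-one in ascending length order,
#' two bands matching when their lengths differ by at most
#' \code{tolerance_bp}. Similarity = 2 M / (n_a + n_b).
#'
#' @param a,b \code{fingerprint} objects from the same enzyme.
#' @param tolerance_bp Band-size matching tolerance in bp (default 1).
#' @param noise_frac Noise floor as a fraction of the longest band
#'   (default 0.05).
#' @return Similarity in [0, 1].
#' @examples
#' fa <- digest(genome_record("a", "GCGCAAGCGC"))
#' fingerprint_similarity(fa, fa)  # 1
#' @export
fingerprint_similarity <- function(a, b, tolerance_bp = 1, noise_frac = 0.05) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (!identical(a$enzyme, b$enzyme)) {
    pc_stop("fingerprints must come from the same enzyme")
  }
  fa <- sort(apply_noise_floor(a$fragment_lengths, noise_frac))
  fb <- sort(apply_noise_floor(b$fragment_lengths, noise_frac))
  if (!length(fa) || !length(fb)) {
    pc_warn("empty fingerprint after noise filtering; similarity set to 0")
    return(0)
  }
  m <- greedy_band_matches(fa, fb, tolerance_bp)
  2 * m / (length(fa) + length(fb))
}

#' Distance matrix from a set of fingerprints
#'
#' Pairwise distance = 1 - band-matching similarity.
#'
#' @param fingerprints List of \code{fingerprint} objects (same enzyme).
#' @inheritParams fingerprint_similarity
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   genome id.
#' @export
fingerprint_distance_matrix <- function(fingerprints, tolerance_bp = 1,
                                        noise_frac = 0.05) {
  n <- length(fingerprints)
  if (n < 2L) pc_stop("need at least 2 fingerprints")
  labels <- vapply(fingerprints, function(f) f$genome_id, character(1))
  if (anyDuplicated(labels)) pc_stop("fingerprint genome ids must be unique")
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- fingerprint_similarity(fingerprints[[i]], fingerprints[[j]],
                                  tolerance_bp = tolerance_bp,
                                  noise_frac = noise_frac)
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \code{\link[ape]{nj}});
#' negative branch lengths are clamped to 0. Taxa are processed in label
#' order so tie-breaking is deterministic.
#'
#' @param d Symmetric non-negative distance matrix with zero diagonal and
#'   row/column labels (or a \code{dist} object).
#' @return Newick text of the unrooted tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) pc_stop("`d` must be a square matrix")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-9) pc_stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) pc_stop("distance matrix diagonal must be zero")
  if (any(d < 0)) pc_stop("distances must be non-negative")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  n <- nrow(d)
  if (n == 1L) return(sprintf("(%s:0);", rownames(d)[1]))
  if (n == 2L) {
    h <- d[1, 2] / 2
    return(sprintf("(%s:%g,%s:%g);", rownames(d)[1], h, rownames(d)[2], h))
  }
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  ape::write.tree(tree)
}

#' Genome summary statistics
#'
#' Length, G+C percentage (Ns excluded from the denominator) and, when CDS
#' intervals are given, the percentage of the genome covered by the union
#' of coding intervals. Intervals are 1-based inclusive; strand is ignored
#' for coverage.
#'
#' @param genome A \code{\link{genome_record}}.
#' @param cds_intervals Optional data frame with \code{start} and
#'   \code{end} columns (1-based inclusive, within the genome).
#' @return List with \code{length_bp}, \code{gc_percent} and
#'   \code{coding_percent} (NA when no intervals are given).
#' @export
genome_stats <- function(genome, cds_intervals = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  dna <- Biostrings::DNAString(genome$sequence)
  counts <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T"))
  acgt <- sum(counts)
  if (acgt == 0L) pc_stop("sequence has no unambiguous bases")
  gc <- 100 * sum(counts[c("C", "G")]) / acgt
  L <- nchar(genome$sequence)
  coding <- NA_real_
  if (!is.null(cds_intervals)) {
    if (!all(c("start", "end") %in% names(cds_intervals))) {
      pc_stop("`cds_intervals` needs `start` and `end` columns")
    }
    s <- as.integer(cds_intervals$start); e <- as.integer(cds_intervals$end)
    if (any(s < 1L) || any(e > L) || any(e < s)) {
      pc_stop("CDS interval out of genome bounds")
    }
    covered <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(s, e))))
    coding <- 100 * covered / L
  }
  list(length_bp = L, gc_percent = gc, coding_percent = coding)
}

#' Read CDS intervals from a tab-separated file
#'
#' Three columns without header: seqid, start, end (1-based inclusive).
#'
#' @param path Path to the file.
#' @return Data frame with \code{seqid}, \code{start}, \code{end}.
#' @export
read_cds_intervals <- function(path) {
  if (!file.exists(path)) pc_stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seqid", "start", "end"),
                          stringsAsFactors = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

# All 64 codons in lexicographic order.
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(third = b, second = b, first = b, stringsAsFactors = FALSE)
  paste0(g$first, g$second, g$third)
}

#' Compare phage codon usage with a host table at tRNA-matched codons
#'
#' Computes phage codon frequencies (per 1000 codons) over a set of CDS
#' sequences, maps each tRNA anticodon to its codon by strict reverse
#' complement (no wobble), and reports, for each matched codon, whether the
#' phage uses it more frequently than the host does.
#'
#' @param phage_cds Character vector (or DNAStringSet) of CDS sequences.
#'   Trailing partial codons are dropped with a warning.
#' @param host_table Named numeric vector of host codon frequencies per
#'   1000 codons (DNA codons).
#' @param trna_anticodons Character vector of anticodon triplets (RNA or
#'   DNA alphabet).
#' @return List with \code{matched} (data frame: anticodon, codon,
#'   phage_freq, host_freq, higher_in_phage), \code{n_higher}, and
#'   \code{full_table} (all 64 codons).
#' @export
codon_usage_compare <- function(phage_cds, host_table, trna_anticodons) {
  phage_cds <- toupper(as.character(phage_cds))
  if (length(phage_cds) == 0L || all(nchar(phage_cds) == 0L)) {
    pc_stop("`phage_cds` must contain at least one non-empty sequence")
  }
  trimmed <- nchar(phage_cds) %% 3L
  if (any(trimmed != 0L)) {
    pc_warn("CDS length(s) not divisible by 3: trailing partial codons dropped")
    phage_cds <- substr(phage_cds, 1L, nchar(phage_cds) - trimmed)
  }
  phage_cds <- phage_cds[nchar(phage_cds) > 0L]
  set <- Biostrings::DNAStringSet(phage_cds)
  counts <- colSums(Biostrings::oligonucleotideFrequency(set, width = 3, step = 3))
  codons <- all_codons()
  counts <- counts[codons]
  counts[is.na(counts)] <- 0
  total <- sum(counts)
  if (total == 0) pc_stop("no complete codons in `phage_cds`")
  phage_freq <- 1000 * counts / total
  names(phage_freq) <- codons

  host <- stats::setNames(rep(0, length(codons)), codons)
  host[names(host_table)] <- as.numeric(host_table)

  anticodons <- toupper(gsub("U", "T", trna_anticodons))
  if (any(!grepl("^[ACGT]{3}$", anticodons))) {
    pc_stop("anticodons must be triplets over A,C,G,T/U")
  }
  matched_codons <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(anticodons))
  )
  matched <- data.frame(
    anticodon = trna_anticodons,
    codon = matched_codons,
    phage_freq = unname(phage_freq[matched_codons]),
    host_freq = unname(host[matched_codons]),
    stringsAsFactors = FALSE
  )
  matched$higher_in_phage <- matched$phage_freq > matched$host_freq
  list(
    matched = matched,
    n_higher = sum(matched$higher_in_phage[!duplicated(matched$codon)]),
    full_table = data.frame(
      codon = codons,
      phage_freq = unname(phage_freq),
      host_freq = unname(host),
      stringsAsFactors = FALSE
    )
  )
}
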