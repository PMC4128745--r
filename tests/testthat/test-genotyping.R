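test_that("digest cuts GCG^C on the forward strand", {
  fp <- digest(genome_record("toy", "GCGCAAGCGC"))
  expect_equal(sort(fp$fragment_lengths), c(1L, 3L, 6L))

  # motif absent: single full-length fragment
  fp2 <- digest(genome_record("none", "ATATATATAT"))
  expect_equal(fp2$fragment_lengths, 10L)

  # overlapping occurrences are both counted (GCGCGC: sites at 1 and 3)
  fp3 <- digest(genome_record("ovl", "GCGCGC"))
  expect_equal(sort(fp3$fragment_lengths), c(1L, 2L, 3L))

  # sites containing N are skipped, with a warning about the Ns
  expect_warning(fpn <- digest(genome_record("n", "GCNCAAGCGC")), "N")
  expect_equal(sort(fpn$fragment_lengths), c(1L, 9L))

  expect_error(genome_record("empty", ""), class = "phagechar_invalid_input")
  expect_error(genome_record("bad", "ACGX"), class = "phagechar_invalid_input")
})

test_that("circular digests wrap around the origin", {
  # linear GCGCAAGCGC: cuts after 3 and 9 -> 3 fragments. Circularized, the
  # junction creates a third site (G9 C10 | G1 C2), so cuts fall after
  # positions 1, 3 and 9 -> fragments 2, 6, 2 (count = number of cuts)
  lin <- digest(genome_record("l", "GCGCAAGCGC", topology = "linear"))
  circ <- digest(genome_record("c", "GCGCAAGCGC", topology = "circular"))
  expect_equal(length(lin$fragment_lengths), 3L)
  expect_equal(length(circ$fragment_lengths), 3L)
  expect_equal(sum(circ$fragment_lengths), 10L)
  expect_equal(sort(circ$fragment_lengths), c(2L, 2L, 6L))

  # site spanning the origin is found
  circ2 <- digest(genome_record("c2", "GCAAAAAAGC", topology = "circular"))
  expect_equal(sum(circ2$fragment_lengths), 10L)
  expect_equal(length(circ2$fragment_lengths), 1L)

  # uncut circle: one full-length pseudo-fragment
  circ3 <- digest(genome_record("c3", "ATATATAT", topology = "circular"))
  expect_equal(circ3$fragment_lengths, 8L)
})

test_that("fragment lengths are conserved on random genomes", {
  genomes <- simulate_genomes(100, 5000, gc = 0.5, seed = 42)
  for (g in genomes) {
    fp <- digest(g)
    expect_equal(sum(fp$fragment_lengths), nchar(g$sequence))
    # linear rule: fragment count = cuts + 1
    expect_gte(length(fp$fragment_lengths), 1L)
  }
})

test_that("band-matching similarity follows the Dice definition", {
  mkfp <- function(lengths, id = "x") {
    structure(list(genome_id = id, enzyme = "GCGC",
                   fragment_lengths = sort(as.integer(lengths), decreasing = TRUE),
                   noise_floor_applied = FALSE), class = "fingerprint")
  }
  # self-similarity
  fa <- digest(genome_record("a", "GCGCAAGCGCTTTT"))
  expect_equal(fingerprint_similarity(fa, fa), 1)

  # one of two bands shared: 2*1/(2+2) = 0.5 (noise floor off to keep all bands)
  expect_equal(fingerprint_similarity(mkfp(c(100, 200)), mkfp(c(100, 300)),
                                      noise_frac = 0), 0.5)

  # 1 bp tolerance boundary
  expect_equal(fingerprint_similarity(mkfp(100), mkfp(101)), 1)
  expect_equal(fingerprint_similarity(mkfp(100), mkfp(101), tolerance_bp = 0), 0)

  # noise floor: a 4 bp band against a 100 bp band is discarded at 5%
  expect_equal(fingerprint_similarity(mkfp(c(100, 4)), mkfp(100)), 1)

  # empty after filtering
  fe <- mkfp(integer(0))
  expect_warning(s0 <- fingerprint_similarity(fe, mkfp(100)), "empty")
  expect_equal(s0, 0)

  # different enzymes cannot be compared
  fb <- mkfp(100); fb$enzyme <- "GGCC"
  expect_error(fingerprint_similarity(mkfp(100), fb),
               class = "phagechar_invalid_input")
})

test_that("similarity is symmetric and bounded on random fingerprints", {
  genomes <- simulate_genomes(6, 8000, gc = 0.4, seed = 9)
  fps <- lapply(genomes, digest)
  for (i in 1:5) for (j in (i + 1):6) {
    sij <- fingerprint_similarity(fps[[i]], fps[[j]])
    sji <- fingerprint_similarity(fps[[j]], fps[[i]])
    expect_equal(sij, sji)
    expect_gte(sij, 0); expect_lte(sij, 1)
  }
  d <- fingerprint_distance_matrix(fps)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- ape::read.tree(text = neighbor_joining(d))
  bl <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 1, 3))
})

test_that("neighbor joining recovers additive trees (n = 4, 5)", {
  set.seed(5)
  for (n in c(4, 5)) {
    for (rep in 1:5) {
      tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
      dd <- ape::cophenetic.phylo(tr)
      rec <- ape::read.tree(text = neighbor_joining(dd))
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
                   ignore_attr = TRUE)
      if (n == 4) {
        # independent oracle: the 4-point condition picks the split with the
        # smallest pairwise-sum; check the recovered tree shows that split
        labs <- rownames(dd)
        sums <- c(dd[labs[1], labs[2]] + dd[labs[3], labs[4]],
                  dd[labs[1], labs[3]] + dd[labs[2], labs[4]],
                  dd[labs[1], labs[4]] + dd[labs[2], labs[3]])
        pairings <- list(c(labs[1], labs[2]), c(labs[1], labs[3]), c(labs[1], labs[4]))
        cherry <- pairings[[which.min(sums)]]
        # the two taxa of the minimal pairing must be sisters in the NJ tree
        mrca_depths <- ape::cophenetic.phylo(rec)
        others <- setdiff(labs, cherry)
        expect_lt(mrca_depths[cherry[1], cherry[2]],
                  min(mrca_depths[cherry[1], others[1]],
                      mrca_depths[cherry[1], others[2]]))
      }
    }
  }
})

test_that("degenerate and invalid distance matrices are handled", {
  # equidistant taxa: deterministic output, repeatable
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4])); diag(d) <- 0
  expect_identical(neighbor_joining(d), neighbor_joining(d))
  # trivial sizes
  expect_match(neighbor_joining(matrix(0, 1, 1, dimnames = list("A", "A"))), "^\\(A")
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_match(neighbor_joining(d2), "A:0.2")
  # asymmetry rejected
  bad <- d; bad[1, 2] <- 0.5
  expect_error(neighbor_joining(bad), class = "phagechar_invalid_input")
})

test_that("clones cluster with their parent, away from unrelated genomes", {
  for (seed in 1:3) {
    genomes <- simulate_genomes(3, 10000, gc = 0.3, site_density = 1e-3,
                                clone_edits = list(list(type = "insert", length = 500)),
                                seed = seed)
    fps <- lapply(genomes, digest)
    d <- fingerprint_distance_matrix(fps)
    expect_lt(d["g1", "g1_clone1"], 0.3)
    expect_gt(d["g1", "g2"], 0.7)
    expect_gt(d["g1", "g3"], 0.7)
    expect_gt(d["g2", "g3"], 0.7)
  }
})

test_that("a single insertion changes at most two bands", {
  genomes <- simulate_genomes(1, 10000, gc = 0.3, site_density = 1e-3,
                              clone_edits = list(list(type = "insert", length = 500)),
                              seed = 4)
  a <- digest(genomes$g1)$fragment_lengths
  b <- digest(genomes$g1_clone1)$fragment_lengths
  expect_equal(length(a), length(b))  # siteless insert preserves band count
  # multiset intersection: all but the stretched band should be shared
  lens <- union(a, b)
  shared <- sum(pmin(tabulate(match(a, lens), nbins = length(lens)),
                     tabulate(match(b, lens), nbins = length(lens))))
  expect_gte(shared, length(a) - 2L)
  expect_equal(sum(b) - sum(a), 500L)
})

test_that("genome statistics: length, GC and coding coverage", {
  expect_equal(genome_stats(genome_record("g", "GGCC"))$gc_percent, 100)
  expect_equal(genome_stats(genome_record("g", "ATAT"))$gc_percent, 0)
  # N excluded from the GC denominator
  expect_equal(genome_stats(genome_record("g", "GCNNAT"))$gc_percent, 50)

  g <- genome_record("g", "ACGTACGTAC")
  st <- genome_stats(g, cds_intervals = data.frame(start = c(1, 4), end = c(5, 8)))
  # union of [1,5] and [4,8] covers 8 of 10 bases
  expect_equal(st$coding_percent, 80)
  expect_equal(st$length_bp, 10)
  expect_error(genome_stats(g, cds_intervals = data.frame(start = 1, end = 11)),
               class = "phagechar_invalid_input")
})

test_that("statistics hold at published genome scale on synthetic surrogates", {
  # synthetic stand-ins with the published lengths and exact compositions;
  # the real deposited sequences are not redistributable here
  gc_count <- 17574                      # 17574/42654 = 41.205% -> 41.2
  seq007 <- exact_composition_sequence(gc = gc_count, at = 42654 - gc_count)
  st <- genome_stats(genome_record("surrogate007", seq007))
  expect_equal(st$length_bp, 42654)
  expect_equal(round_half_up_test(st$gc_percent), 41.2)

  gc004 <- round(0.373 * 99730)
  seq004 <- exact_composition_sequence(gc = gc004, at = 99730 - gc004, seed = 2)
  st4 <- genome_stats(genome_record("surrogate004", seq004))
  expect_equal(st4$length_bp, 99730)
  expect_equal(round_half_up_test(st4$gc_percent), 37.3)
})

test_that("codon usage comparison matches anticodons by reverse complement", {
  res <- codon_usage_compare("ATGATG", host_table = c(ATG = 500), trna_anticodons = "CAU")
  expect_equal(res$matched$codon, "ATG")
  expect_equal(res$matched$phage_freq, 1000)
  expect_true(res$matched$higher_in_phage)

  # trailing partial codon dropped with warning
  expect_warning(res2 <- codon_usage_compare("ATGATGA", c(ATG = 1), "CAU"),
                 "partial")
  expect_equal(res2$matched$phage_freq, 1000)

  # frequencies sum to 1000 over all codons
  expect_equal(sum(res$full_table$phage_freq), 1000)

  expect_error(codon_usage_compare(character(0), c(ATG = 1), "CAU"),
               class = "phagechar_invalid_input")
  expect_error(codon_usage_compare("ATG", c(ATG = 1), "CAZ"),
               class = "phagechar_invalid_input")
})

test_that("a CDS set enriched for 16 of 21 matched codons flags exactly 16", {
  # 21 distinct codons matched by 22 anticodons (one codon served twice);
  # the phage CDS is built to overuse 16 of them relative to the host table
  codons <- c("ATG", "AAA", "GAA", "GAT", "CGT", "CTG", "GGT", "CCG",
              "ACC", "GTT", "TTC", "TAC", "CAT", "CAG", "AGC", "TGG",
              "GCA", "ATT", "CTT", "TCA", "GGA")
  stopifnot(length(codons) == 21)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  anticodons <- c(rc(codons), rc(codons[1]))   # 22 tRNAs
  enriched <- codons[1:16]
  rare <- codons[17:21]
  cds <- paste(c(rep(enriched, each = 10), rare), collapse = "")
  host <- setNames(rep(30, 21), codons)        # host uses each at 30 per 1000
  res <- codon_usage_compare(cds, host, anticodons)
  expect_equal(res$n_higher, 16)
  expect_equal(nrow(res$matched), 22)
})
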