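toy_hits <- function() {
  data.frame(
    qseqid = c("a1", "a1", "a2"), sseqid = c("b1", "b2", "b2"),
    pident = c(90, 70, 85), length = c(200, 180, 150),
    mismatch = 0, gapopen = 0, qstart = 1, qend = 1, sstart = 1, send = 1,
    evalue = c(1e-50, 1e-20, 1e-30), bitscore = c(500, 200, 300),
    stringsAsFactors = FALSE)
}

test_that("tabular hit files round-trip and malformed lines are skipped", {
  hits <- toy_hits()
  f <- tempfile()
  write_hits(hits, f)
  back <- import_hits(f)
  expect_equal(back, hits, ignore_attr = TRUE)
  # E-value in scientific notation parses numerically
  expect_equal(back$evalue[1L], 1e-50)
  cat("broken line with\ttoo few fields\n", file = f, append = TRUE)
  expect_warning(back2 <- import_hits(f), "malformed")
  expect_equal(nrow(back2), 3L)
  empty <- tempfile(); file.create(empty)
  expect_error(import_hits(empty), "no parseable")
})

test_that("reciprocal best hits require mutual best pairs under thresholds", {
  len_a <- c(a1 = 200L, a2 = 180L)
  len_b <- c(b1 = 210L, b2 = 190L, b3 = 150L)
  ab <- toy_hits()
  ba <- data.frame(
    qseqid = c("b1", "b2"), sseqid = c("a1", "a1"),
    pident = c(90, 85), length = c(200, 150),
    mismatch = 0, gapopen = 0, qstart = 1, qend = 1, sstart = 1, send = 1,
    evalue = c(1e-50, 1e-28), bitscore = c(500, 290),
    stringsAsFactors = FALSE)
  pairs <- reciprocal_best_hits(ab, ba, len_a, len_b)
  # a1<->b1 mutual best; a2's best is b2 but b2's best is a1: no a2 pair
  expect_equal(pairs$id_a, "a1")
  expect_equal(pairs$id_b, "b1")
  # identity threshold excludes the pair
  expect_equal(nrow(reciprocal_best_hits(ab, ba, len_a, len_b,
                                         min_identity = 95)), 0L)
  # coverage against the longest protein: 200/210 > 0.6 passes, raise it
  expect_equal(nrow(reciprocal_best_hits(ab, ba, len_a, len_b,
                                         min_coverage = 0.99)), 0L)
  expect_equal(nrow(reciprocal_best_hits(ab, ba, len_a, len_b,
                                         min_length = 205L)), 0L)
})

test_that("RBH is symmetric and recovers planted orthologs among decoys", {
  set.seed(91)
  n <- 8L
  ids_a <- sprintf("A%02d", 1:n)
  ids_b <- sprintf("B%02d", 1:n)
  len_a <- stats::setNames(rep(150L, n), ids_a)
  len_b <- stats::setNames(rep(150L, n), ids_b)
  mk <- function(q, s, bs) data.frame(
    qseqid = q, sseqid = s, pident = 80, length = 150, mismatch = 0,
    gapopen = 0, qstart = 1, qend = 1, sstart = 1, send = 1,
    evalue = 1e-40, bitscore = bs, stringsAsFactors = FALSE)
  # true ortholog hits score 400; decoy (shifted) hits score lower
  ab <- rbind(mk(ids_a, ids_b, 400),
              mk(ids_a, ids_b[c(2:n, 1L)], 250))
  ba <- rbind(mk(ids_b, ids_a, 400),
              mk(ids_b, ids_a[c(3:n, 1:2)], 240))
  pairs <- reciprocal_best_hits(ab, ba, len_a, len_b)
  expect_equal(nrow(pairs), n)
  expect_equal(pairs$id_b, ids_b[match(pairs$id_a, ids_a)])
  # swapping the genomes yields the same unordered pairs
  swapped <- reciprocal_best_hits(ba, ab, len_b, len_a)
  expect_setequal(paste(pairs$id_a, pairs$id_b),
                  paste(swapped$id_b, swapped$id_a))
})

test_that("protein alignment is optimal, deterministic and scored correctly", {
  same <- align_proteins("MKVLA", "MKVLA")
  expect_equal(same$identity, 100)
  expect_false(grepl("-", same$a))
  aln <- align_proteins("ACDE", "ACE")
  expect_equal(nchar(aln$a), 4L)
  expect_equal(sum(strsplit(aln$b, "")[[1L]] == "-"), 1L)
  # returned score equals both the re-scored alignment and the DP optimum
  set.seed(92)
  alphabet <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")
  for (i in 1:5) {
    s1 <- paste(sample(alphabet, sample(8:14, 1L), TRUE), collapse = "")
    s2 <- paste(sample(alphabet, sample(8:14, 1L), TRUE), collapse = "")
    got <- align_proteins(s1, s2)
    expect_equal(got$score, score_alignment_oracle(got$a, got$b))
    expect_equal(got$score, dp_align_score_oracle(s1, s2))
  }
})

test_that("back-translation maps residues to codons and inverts cleanly", {
  code <- genetic_code()
  a <- gene_record("a", c("ATG", "GCT", "GAC", "GAA", "TAA"))
  b <- gene_record("b", c("ATG", "GCC", "GAA", "TAA"))
  aln <- align_proteins(translate_gene(a), translate_gene(b))
  caln <- backtranslate_alignment(aln, a$codons, b$codons)
  expect_length(caln$a, nchar(aln$a))
  expect_equal(caln$a[caln$a != "---"], head(a$codons, -1L))
  expect_equal(caln$b[caln$b != "---"], head(b$codons, -1L))
  expect_equal(sum(caln$b == "---"), 1L)
  # gapless pair: plain concatenation
  same <- backtranslate_alignment(list(a = "MAD", b = "MAD"),
                                  c("ATG", "GCT", "GAC"),
                                  c("ATG", "GCC", "GAT"))
  expect_equal(same$a, c("ATG", "GCT", "GAC"))
  # mismatched codons are a named validation error
  expect_error(backtranslate_alignment(list(a = "MAD", b = "MAD"),
                                       c("ATG", "GCT", "AAA"),
                                       c("ATG", "GCC", "GAT")),
               "residue 3")
})

test_that("NG86 handles the canonical single-codon examples", {
  code <- genetic_code()
  # identical sequences: zero divergence
  aln0 <- list(a = c("ATG", "GAA", "CGC"), b = c("ATG", "GAA", "CGC"))
  kk0 <- kaks_ng86(aln0, code)
  expect_equal(kk0$Ka, 0)
  expect_equal(kk0$Ks, 0)
  # GAA vs GAG: one synonymous difference over 1/3 synonymous sites ->
  # pS = 3, beyond the JC saturation bound, so Ks is marked NA; Ka = 0
  kk1 <- kaks_ng86(list(a = "GAA", b = "GAG"), code)
  expect_equal(kk1$Sd, 1)
  expect_equal(kk1$Nd, 0)
  expect_equal(kk1$S, 1 / 3)
  expect_equal(kk1$Ka, 0)
  expect_true(is.na(kk1$Ks))
  # stop-containing and gapped columns are excluded
  kk2 <- kaks_ng86(list(a = c("TAA", "---", "GCT"),
                        b = c("TAA", "GGG", "GCC")), code)
  expect_equal(kk2$n_codons, 1L)
})

test_that("NG86 is symmetric and conserves total site counts", {
  set.seed(93)
  code <- genetic_code()
  g <- random_gene(80L)
  div <- simulate_ortholog_pair(g, 0.2, omega = 0.3, seed = 7L)$gene
  aln <- list(a = head(g$codons, -1L), b = head(div$codons, -1L))
  ab <- kaks_ng86(aln, code)
  ba <- kaks_ng86(list(a = aln$b, b = aln$a), code)
  expect_equal(ab$Ka, ba$Ka)
  expect_equal(ab$Ks, ba$Ks)
  expect_equal(ab$S + ab$N, 3 * ab$n_codons)
})

test_that("ortholog pair wrapper ties alignment and Ka/Ks together", {
  set.seed(94)
  g <- random_gene(120L, id = "geneA")
  div <- simulate_ortholog_pair(g, 0.15, omega = 0.2, seed = 11L)$gene
  row <- ortholog_pair(g, div)
  expect_equal(row$gene_id_a, "geneA")
  expect_gt(row$identity, 60)
  expect_equal(row$coverage, 1)
  expect_gte(row$Ks, 0)
  expect_true(row$pass_ks_filter)
})

test_that("Ks filtering and divergence correlations behave on planted data", {
  set.seed(95)
  # planted: low-divergence genes get high CAI
  n <- 24L
  ks <- seq(0.05, 1.4, length.out = n)
  pairs <- data.frame(gene_id_a = paste0("g", 1:n),
                      gene_id_b = paste0("h", 1:n),
                      Ka = 0.2 * ks + rnorm(n, 0, 0.01),
                      Ks = ks, stringsAsFactors = FALSE)
  profiles <- data.frame(gene_id = paste0("g", 1:n),
                         CAI = 1 - 0.5 * ks + rnorm(n, 0, 0.02),
                         Fop = 1 - 0.4 * ks + rnorm(n, 0, 0.02),
                         stringsAsFactors = FALSE)
  out <- filter_and_correlate(pairs, profiles, ks_max = 1.0)
  expect_equal(nrow(out$pairs), sum(ks < 1.0))
  r_kscai <- out$correlations$r[out$correlations$x == "Ks" &
                                out$correlations$y == "CAI"]
  expect_lt(r_kscai, 0)
  # all pairs saturated: empty set, undefined correlations
  sat <- pairs; sat$Ks <- 1.5
  out2 <- filter_and_correlate(sat, profiles)
  expect_equal(nrow(out2$pairs), 0L)
  expect_true(all(is.na(out2$correlations$r)))
})
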