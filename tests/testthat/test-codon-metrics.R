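test_that("codon counting excludes the terminal stop and is additive", {
  g <- gene_record("g", c("ATG", "GAA", "GAA", "TAA"))
  tab <- count_codons(g)
  expect_equal(sum(tab), 3L)
  expect_equal(unname(tab["ATG"]), 1L)
  expect_equal(unname(tab["GAA"]), 2L)
  expect_equal(unname(tab["TAA"]), 0L)

  g2 <- random_gene(120L, seed = 2)
  expect_equal(pool_counts(list(count_codons(g), count_codons(g2))),
               count_codons(g) + count_codons(g2))

  # independent 3-mer striding count over the raw string
  s <- paste(g2$codons, collapse = "")
  stride <- table(substring(s, seq(1, nchar(s) - 3, by = 3),
                            seq(3, nchar(s) - 1, by = 3)))
  for (cd in names(stride))
    expect_equal(unname(count_codons(g2)[cd]), unname(as.integer(stride[cd])))
})

test_that("pooling is associative and recovers totals after a random split", {
  set.seed(9)
  tabs <- lapply(1:10, function(i) count_codons(random_gene(110L)))
  whole <- pool_counts(tabs)
  grp <- sample(1:2, 10, replace = TRUE)
  expect_equal(pool_counts(list(pool_counts(tabs[grp == 1]),
                                pool_counts(tabs[grp == 2]))), whole)
  expect_equal(pool_counts(tabs[3]), tabs[[3]])
})

test_that("RSCU matches the published worked values and its invariants", {
  ext <- cglutamicum_extreme_counts()
  r_high <- rscu(ext$high)
  expect_equal(round(r_high[["TTC"]], 2), 1.83)
  expect_equal(round(r_high[["TCC"]], 2), 4.11)
  expect_equal(round(r_high[["CGC"]], 2), 4.11)
  expect_equal(round(r_high[["GGC"]], 2), 2.55)
  expect_equal(round(r_high[["ATC"]], 2), 2.57)
  expect_equal(round(r_high[["TAC"]], 2), 1.93)

  # uniform usage within every family gives RSCU exactly 1
  code <- genetic_code()
  uni <- stats::setNames(rep(0L, 64L), CODON_SET)
  for (fam in codon_families(code)) uni[fam] <- 7L
  expect_true(all(abs(rscu(uni, code) - 1) < 1e-12))

  # family sums equal the degeneracy; family means equal 1
  set.seed(4)
  tab <- count_codons(random_gene(300L))
  r <- rscu(tab, code)
  for (fam in codon_families(code)) {
    if (sum(tab[fam]) == 0) {
      expect_true(all(is.na(r[fam])))
    } else {
      expect_equal(sum(r[fam]), length(fam))
      expect_equal(mean(r[fam]), 1)
    }
  }
  expect_true(all(r >= 0, na.rm = TRUE))
})

test_that("ENC hits the endpoints and matches an independent transcription", {
  code <- genetic_code()
  one <- stats::setNames(rep(0L, 64L), CODON_SET)
  uni <- one
  for (fam in codon_families(code)) {
    one[fam[1L]] <- 100L
    uni[fam] <- 100L
  }
  expect_equal(enc(one, code), 20)
  expect_equal(enc(uni, code), 61)

  set.seed(31)
  for (i in 1:50) {
    tab <- count_codons(random_gene(sample(100:400, 1L)))
    expect_equal(enc(tab, code), wright_enc_oracle(tab), tolerance = 1e-9)
  }
})

test_that("concentrating a family's counts never increases Nc", {
  code <- genetic_code()
  set.seed(14)
  tab <- count_codons(random_gene(400L))
  fam <- codon_families(code)[["A"]]  # Ala, 4-fold
  before <- enc(tab, code)
  concentrated <- tab
  concentrated[fam] <- c(sum(tab[fam]), 0L, 0L, 0L)
  expect_lte(enc(concentrated, code), before)
})

test_that("the expected-Nc curve follows Wright's closed form", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  expect_error(enc_expected(1.2))
})

test_that("third-position composition is restricted to synonymous codons", {
  code <- genetic_code()
  tab <- stats::setNames(rep(0L, 64L), CODON_SET)
  tab[c("GCT", "GCC", "GCA", "GCG")] <- 10L  # equal Ala usage
  comp <- third_position_composition(tab, code)
  expect_equal(comp[["GC3s"]], 0.5)
  expect_equal(comp[["GC3s"]], comp[["G3s"]] + comp[["C3s"]])

  only_met <- stats::setNames(rep(0L, 64L), CODON_SET)
  only_met["ATG"] <- 50L
  expect_true(all(is.na(third_position_composition(only_met, code))))

  # brute-force per-base tally over eligible codons
  set.seed(6)
  rtab <- count_codons(random_gene(250L))
  syn <- synonymous_codons(code)
  n <- sum(rtab[syn])
  for (b in c("A", "T", "G", "C")) {
    direct <- sum(rtab[syn[substr(syn, 3, 3) == b]]) / n
    expect_equal(third_position_composition(rtab, code)[[paste0(b, "3s")]],
                 direct)
  }
})

test_that("CAI reference weights normalise per family with 0.5 pseudo-counts", {
  code <- genetic_code()
  pool <- stats::setNames(rep(0L, 64L), CODON_SET)
  for (fam in codon_families(code)) pool[fam[1L]] <- 40L  # single codon used
  ref <- build_cai_reference(pool, code)
  for (fam in codon_families(code)) {
    expect_equal(unname(ref$weights[fam[1L]]), 1)
    expect_equal(unname(ref$weights[fam[-1L]]),
                 rep(0.5 / 40, length(fam) - 1L))
  }

  # any pool: per-family max weight is exactly 1; hand-computed ratios hold
  set.seed(13)
  tabs <- lapply(1:5, function(i) count_codons(random_gene(200L)))
  ref2 <- build_cai_reference(tabs, code)
  pooled <- pool_counts(tabs)
  for (fam in codon_families(code)) {
    expect_equal(max(ref2$weights[fam]), 1)
    x <- as.numeric(pooled[fam]); x[x == 0] <- 0.5
    expect_equal(unname(ref2$weights[fam]), x / max(x))
  }
  expect_error(build_cai_reference(list(), code), "empty")
})

test_that("CAI is a geometric mean of weights over codon occurrences", {
  code <- genetic_code()
  set.seed(17)
  ref <- build_cai_reference(lapply(1:4, function(i)
    count_codons(random_gene(300L))), code)

  # gene using only per-family maximal-weight codons scores exactly 1
  best <- stats::setNames(rep(0L, 64L), CODON_SET)
  for (fam in codon_families(code))
    best[fam[which.max(ref$weights[fam])]] <- 5L
  expect_equal(cai(best, ref), 1)

  # log-domain loop oracle on a random gene
  g <- random_gene(150L)
  tab <- count_codons(g)
  w <- ref$weights
  logs <- unlist(lapply(names(w), function(cd) rep(log(w[cd]), tab[cd])))
  expect_equal(cai(tab, ref), exp(mean(logs)))
  expect_gt(cai(tab, ref), 0)
  expect_lte(cai(tab, ref), 1)
})

test_that("Fop counts optimal codons over eligible families only", {
  code <- genetic_code()
  optimal <- c("TTC", "GAC")  # Phe and Asp families eligible
  tab <- stats::setNames(rep(0L, 64L), CODON_SET)
  tab[c("TTC", "GAC")] <- c(10L, 5L)
  expect_equal(fop(tab, optimal, code), 1)
  tab["TTT"] <- 15L          # non-optimal Phe codon
  tab["GGG"] <- 100L         # Gly family has no optimal codon: ignored
  expect_equal(fop(tab, optimal, code), 15 / 30)
  expect_true(is.na(fop(tab, character(0), code)))

  set.seed(23)
  rtab <- count_codons(random_gene(200L))
  opt <- default_optimal_codons()
  fams <- codon_families(code)
  eligible <- unlist(fams[vapply(fams, function(f) any(f %in% opt), TRUE)])
  expect_equal(fop(rtab, opt, code),
               sum(rtab[opt]) / sum(rtab[eligible]))
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(gravy("I"), 4.5)
  expect_equal(gravy("IR"), 0)
  expect_error(gravy("IXZ"), "unknown residue")
  set.seed(19)
  kd <- codonbias:::KYTE_DOOLITTLE
  pep <- paste(sample(names(kd), 40, replace = TRUE), collapse = "")
  expect_equal(gravy(pep), mean(kd[strsplit(pep, "")[[1L]]]))
})

test_that("usage_profiles assembles consistent per-gene indices", {
  set.seed(27)
  genes <- lapply(1:12, function(i)
    random_gene(sample(100:200, 1L), id = paste0("g", i),
                product = if (i <= 2) "30S ribosomal protein S4"
                          else "hypothetical protein"))
  prof <- usage_profiles(genes, optimal = default_optimal_codons())
  expect_equal(nrow(prof), 12L)
  expect_true(all(prof$ENC >= 20 & prof$ENC <= 61))
  expect_true(all(prof$CAI > 0 & prof$CAI <= 1))
  expect_equal(prof$GC3s, prof$G3s + prof$C3s)
  expect_equal(sum(prof$is_ribosomal), 2L)
  # spot-check one gene against direct calls
  tab <- count_codons(genes[[5L]])
  expect_equal(prof$ENC[5L], enc(tab))
  expect_equal(prof$GRAVY[5L], gravy(translate_gene(genes[[5L]])))
})
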