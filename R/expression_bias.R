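#' Per-codon chi-square test between expression groups
#'
#' Tests whether one codon is used at a higher relative frequency within its
#' synonymous family in the highly expressed pool than in the lowly
#' expressed pool: a Pearson chi-square (df = 1, no continuity correction by
#' default) on the 2x2 table (codon vs other family codons) x (high vs low).
#' A codon is called optimal when p < alpha \emph{and} its within-family
#' proportion is higher in the high pool — the proportion, not the raw
#' count, since the two pools differ in size.
#'
#' @param high,low pooled 64-entry codon count vectors of the two groups.
#' @param codon the codon to test (DNA or RNA spelling).
#' @param code a \code{\link{genetic_code}}.
#' @param alpha significance level (default 0.01).
#' @param correct apply Yates continuity correction (default FALSE; pooled
#'   counts are large).
#' @return one-row data.frame: codon, aa, n_high, rscu_high, n_low,
#'   rscu_low, chi2, p, is_optimal. When the codon's family is empty in
#'   either pool the test is undefined: chi2/p/is_optimal are \code{NA}.
#' @export
codon_chi_square <- function(high, low, codon, code = genetic_code(),
                             alpha = 0.01, correct = FALSE) {
  codon <- rna_to_dna(codon)
  aa <- code$map[[codon]]
  if (is.na(aa) || aa %in% c("M", "W", "*"))
    stop("codon ", codon, " is not synonymously variable under table ",
         code$table_id)
  fam <- codon_families(code)[[aa]]
  a <- as.numeric(high[codon]); b <- sum(high[fam]) - a
  cc <- as.numeric(low[codon]); d <- sum(low[fam]) - cc
  res <- data.frame(codon = codon, aa = aa,
                    n_high = a, rscu_high = NA_real_,
                    n_low = cc, rscu_low = NA_real_,
                    chi2 = NA_real_, p = NA_real_, is_optimal = NA,
                    stringsAsFactors = FALSE)
  if (a + b > 0) res$rscu_high <- a * length(fam) / (a + b)
  if (cc + d > 0) res$rscu_low <- cc * length(fam) / (cc + d)
  if (a + b == 0 || cc + d == 0) return(res)  # empty family: undefined
  tab <- matrix(c(a, b, cc, d), nrow = 2L)
  if (a + cc == 0 || b + d == 0) {  # degenerate margin: no signal
    res$chi2 <- 0; res$p <- 1; res$is_optimal <- FALSE
    return(res)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  res$chi2 <- unname(ht$statistic)
  res$p <- ht$p.value
  res$is_optimal <- res$p < alpha && (a / (a + b)) > (cc / (cc + d))
  res
}

#' Call translationally optimal codons from two pooled groups
#'
#' Applies \code{\link{codon_chi_square}} to each of the 59 synonymous
#' codons and returns the optimal set — codons significantly (p < alpha)
#' more used, relative to their family, in the highly expressed pool — with
#' the full per-codon results and a tally of the optimal codons' ending
#' bases (a C-rich ending profile is the GC-rich actinobacterial signature).
#'
#' @inheritParams codon_chi_square
#' @return list with \code{optimal} (character vector, DNA spelling),
#'   \code{results} (59-row data.frame), \code{ending_base} (named count of
#'   third bases among the optimal codons), \code{n_amino_acids} (number of
#'   amino acids covered by the optimal set).
#' @export
call_optimal_codons <- function(high, low, code = genetic_code(),
                                alpha = 0.01, correct = FALSE) {
  stopifnot(sum(high) > 0, sum(low) > 0)
  syn <- synonymous_codons(code)
  results <- do.call(rbind, lapply(syn, function(cd)
    codon_chi_square(high, low, cd, code, alpha, correct)))
  optimal <- results$codon[results$is_optimal %in% TRUE]
  ending <- table(factor(substr(optimal, 3L, 3L), levels = c("T", "C", "A", "G")))
  list(optimal = optimal, results = results,
       ending_base = stats::setNames(as.integer(ending), names(ending)),
       n_amino_acids = length(unique(results$aa[results$is_optimal %in% TRUE])))
}

#' Write the optimal-codon table as TSV
#'
#' One row per synonymous codon in the layout of the published extreme-group
#' tables: amino acid, codon, pooled count and RSCU per group (RSCU rounded
#' to 2 decimals alongside full precision), chi-square, p, and the optimal
#' flag.
#'
#' @param opt result of \code{\link{call_optimal_codons}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_optimal_tsv <- function(opt, path) {
  df <- opt$results
  df$rscu_high_2dp <- round(df$rscu_high, 2)
  df$rscu_low_2dp <- round(df$rscu_low, 2)
  df <- df[, c("aa", "codon", "n_high", "rscu_high_2dp", "n_low",
               "rscu_low_2dp", "chi2", "p", "is_optimal",
               "rscu_high", "rscu_low")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pooled codon counts from a TSV
#'
#' Loads a two-group pooled codon count table (columns \code{codon},
#' \code{n_high}, \code{n_low}; codons in DNA or RNA spelling) into the pair
#' of 64-entry vectors \code{\link{call_optimal_codons}} expects, so the
#' optimal-codon analysis can run on a printed table without sequences.
#'
#' @param path TSV with at least columns codon, n_high, n_low.
#' @return list with \code{high} and \code{low} 64-entry count vectors.
#' @export
read_pooled_counts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("codon", "n_high", "n_low") %in% names(df)))
  cd <- rna_to_dna(df$codon)
  stopifnot(!anyDuplicated(cd), all(cd %in% CODONS))
  high <- low <- stats::setNames(rep(0L, 64L), CODONS)
  high[cd] <- as.integer(df$n_high)
  low[cd] <- as.integer(df$n_low)
  list(high = high, low = low)
}

#' Pooled extreme-group codon counts for C. glutamicum
#'
#' The published pooled codon usage of the putatively highly and lowly
#' expressed gene groups of \emph{Corynebacterium glutamicum} ATCC 13032
#' (the extremes of the first codon-usage ordination axis), shipped with
#' the package as a plain-text table. The 22 starred codons are those
#' reported as significantly more used in the highly expressed group.
#'
#' @return list with \code{high}, \code{low} (64-entry count vectors),
#'   \code{table} (the full printed table: aa, codon in RNA spelling,
#'   counts, printed 2-d.p. RSCU per group, starred flag).
#' @export
cglutamicum_extreme_counts <- function() {
  path <- system.file("extdata", "cglutamicum_extreme_group_codon_usage.tsv",
                      package = "codonbias", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  pooled <- read_pooled_counts_tsv(path)
  list(high = pooled$high, low = pooled$low, table = df)
}

#' Leading/lagging strand counts by CAI bin for C. glutamicum
#'
#' The published per-CAI-bin counts of \emph{C. glutamicum} genes on the
#' leading versus lagging replication strand, including the
#' ribosomal-protein row, shipped as a plain-text table.
#'
#' @return data.frame with columns range, total, leading, lagging.
#' @export
cglutamicum_strand_counts <- function() {
  path <- system.file("extdata", "cglutamicum_strand_by_cai.tsv",
                      package = "codonbias", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#")
}
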