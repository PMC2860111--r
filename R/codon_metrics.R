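#' Count codons of a gene
#'
#' Tallies the gene's codons into a fixed-order 64-entry integer vector.
#' The terminal stop codon is excluded, so the total equals
#' \code{length_codons - 1} for a stop-terminated gene; every downstream
#' index works on these counts.
#'
#' @param gene a \code{\link{gene_record}}.
#' @param code a \code{\link{genetic_code}}.
#' @return named integer vector over all 64 codons (\code{CODONS} order).
#' @export
count_codons <- function(gene, code = genetic_code()) {
  cd <- gene$codons
  if (cd[length(cd)] %in% code$stops) cd <- cd[-length(cd)]
  counts <- table(factor(cd, levels = CODONS))
  stats::setNames(as.integer(counts), CODONS)
}

#' Pool codon count tables
#'
#' Elementwise sum of count vectors, e.g. to build the pooled usage of an
#' extreme expression group or of a reference gene set.
#'
#' @param tables list of 64-entry count vectors from
#'   \code{\link{count_codons}} (a single vector is accepted).
#' @return named integer vector over all 64 codons.
#' @export
pool_counts <- function(tables) {
  if (is.numeric(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1L)
  out <- Reduce(`+`, lapply(tables, function(x) {
    stopifnot(length(x) == 64L)
    as.numeric(x[CODONS])
  }))
  stats::setNames(as.integer(round(out)), CODONS)
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c in a synonymous family of degeneracy k with family total
#' N is \code{count(c) * k / N}: the observed count relative to the count
#' expected under equal use of all synonyms. Values above 1 mark codons used
#' more often than expected. Met, Trp and stop codons are not part of the
#' result; families with zero total get \code{NA} (undefined), not 0.
#'
#' @param counts 64-entry codon count vector.
#' @param code a \code{\link{genetic_code}}.
#' @return named numeric vector over the 59 synonymous codons.
#' @export
rscu <- function(counts, code = genetic_code()) {
  stopifnot(sum(counts) > 0)
  fams <- codon_families(code)
  out <- stats::setNames(rep(NA_real_, length(synonymous_codons(code))),
                         synonymous_codons(code))
  for (fam in fams) {
    n_aa <- sum(counts[fam])
    if (n_aa > 0) out[fam] <- counts[fam] * length(fam) / n_aa
  }
  out
}

# Wright's degeneracy classes for the standard/bacterial code: 2-, 3-, 4-
# and 6-fold families (Ile is the only 3-fold; Leu/Ser/Arg are 6-fold and
# kept whole, not split 2+4).
enc_family_classes <- function(code = genetic_code()) {
  fams <- codon_families(code)
  split(fams, vapply(fams, length, 1L))
}

#' Effective number of codons (Wright's Nc)
#'
#' Summarises how far a gene departs from uniform synonymous codon usage:
#' 20 when exactly one codon is used per amino acid, 61 when all synonyms
#' are used equally. Per family the codon homozygosity is estimated as
#' \deqn{\hat F = (n \sum p_i^2 - 1) / (n - 1)}
#' with n the family total and p the within-family codon fractions; families
#' with n < 2 are skipped. Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 with the
#' per-class mean homozygosities. When no 3-fold family is observed (or its
#' estimate is non-positive) F3 is interpolated as (F2 + F4)/2. The result
#' is clamped to [20, 61]; if any other degeneracy class is entirely
#' missing the statistic is undefined and \code{NA} is returned.
#'
#' @inheritParams rscu
#' @return Nc in [20, 61], or \code{NA} when undefined.
#' @export
enc <- function(counts, code = genetic_code()) {
  stopifnot(sum(counts) > 0)
  classes <- enc_family_classes(code)
  fbar <- numeric(0)
  for (k in names(classes)) {
    fs <- vapply(classes[[k]], function(fam) {
      n <- sum(counts[fam])
      if (n < 2) return(NA_real_)
      p <- counts[fam] / n
      (n * sum(p^2) - 1) / (n - 1)
    }, 1)
    fs <- fs[!is.na(fs) & fs > 0]
    fbar[k] <- if (length(fs)) mean(fs) else NA_real_
  }
  if (is.na(fbar["3"]) && !is.na(fbar["2"]) && !is.na(fbar["4"]))
    fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  n_fam <- vapply(classes, length, 1L)  # 9, 1, 5, 3 for the standard code
  if (anyNA(fbar[c("2", "4", "6")])) return(NA_real_)
  nc <- 2 + sum(n_fam[c("2", "3", "4", "6")] / fbar[c("2", "3", "4", "6")])
  min(max(nc, 20), 61)
}

#' Expected Nc under pure compositional bias
#'
#' Wright's expected effective number of codons for a gene whose codon
#' choice is driven only by the G+C content s at synonymous third positions:
#' \deqn{Nc(s) = 2 + s + 29 / (s^2 + (1-s)^2)}
#' Genes falling on this curve in an Nc-vs-GC3s plot are consistent with
#' mutational bias alone; genes below it show additional (e.g.
#' translational) selection.
#'
#' @param s GC3s value(s) in [0, 1]; vectorised.
#' @return expected Nc.
#' @export
enc_expected <- function(s) {
  stopifnot(all(s >= 0 & s <= 1))
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Base composition at synonymous third positions
#'
#' Fractions of A, T, G, C at the third position of synonymously variable
#' codons only — Met, Trp and stop codons are excluded — plus their G+C sum
#' (GC3s). All values are \code{NA} when the gene has no synonymous codons.
#'
#' @inheritParams rscu
#' @return named numeric vector \code{c(GC3s, A3s, T3s, G3s, C3s)}.
#' @export
third_position_composition <- function(counts, code = genetic_code()) {
  syn <- synonymous_codons(code)
  n <- sum(counts[syn])
  if (n == 0)
    return(c(GC3s = NA_real_, A3s = NA_real_, T3s = NA_real_,
             G3s = NA_real_, C3s = NA_real_))
  third <- substr(syn, 3L, 3L)
  by_base <- vapply(c("A", "T", "G", "C"),
                    function(b) sum(counts[syn[third == b]]) / n, 1)
  c(GC3s = unname(by_base["G"] + by_base["C"]),
    A3s = unname(by_base["A"]), T3s = unname(by_base["T"]),
    G3s = unname(by_base["G"]), C3s = unname(by_base["C"]))
}

#' Build CAI reference weights from a highly expressed gene set
#'
#' Relative adaptiveness weights from the pooled codon usage of a reference
#' set of putatively highly expressed genes (classically the ribosomal
#' proteins): within each synonymous family, \code{w(c) = count(c) /
#' max(count)}. Codons unobserved in the pool get a pseudo-count of 0.5
#' before weighting so that no weight is zero. Met, Trp and stops carry no
#' weight; per family the most used codon has weight exactly 1.
#'
#' @param ribosomal_tables list of codon count vectors of the reference
#'   genes (or a single pooled vector).
#' @param code a \code{\link{genetic_code}}.
#' @return object of class \code{"cai_reference"}: list with \code{weights}
#'   (named over the 59 synonymous codons) and \code{pooled} counts.
#' @export
build_cai_reference <- function(ribosomal_tables, code = genetic_code()) {
  if (is.numeric(ribosomal_tables)) ribosomal_tables <- list(ribosomal_tables)
  if (length(ribosomal_tables) == 0L)
    stop("empty CAI reference set: at least one reference gene is required")
  pool <- pool_counts(ribosomal_tables)
  fams <- codon_families(code)
  w <- stats::setNames(rep(NA_real_, length(synonymous_codons(code))),
                       synonymous_codons(code))
  for (fam in fams) {
    x <- as.numeric(pool[fam])
    if (sum(x) == 0)
      stop("CAI reference pool has zero counts for an entire family (",
           paste(fam, collapse = ","), ")")
    x[x == 0] <- 0.5
    w[fam] <- x / max(x)
  }
  structure(list(weights = w, pooled = pool, table_id = code$table_id),
            class = "cai_reference")
}

#' Codon adaptation index
#'
#' Geometric mean of the reference relative-adaptiveness weights over the
#' gene's codon occurrences, excluding Met, Trp and stop codons. 1 means
#' the gene uses only the reference set's preferred codons; low values mark
#' genes whose usage departs from the highly expressed profile.
#'
#' @inheritParams rscu
#' @param ref a \code{\link{build_cai_reference}} object.
#' @return CAI in (0, 1].
#' @export
cai <- function(counts, ref) {
  stopifnot(inherits(ref, "cai_reference"))
  w <- ref$weights
  n <- counts[names(w)]
  total <- sum(n)
  stopifnot(total > 0)
  exp(sum(n * log(w)) / total)
}

#' Frequency of optimal codons
#'
#' Fraction of codon occurrences that are translationally optimal, counted
#' over the codons belonging to families that contain at least one optimal
#' codon (so amino acids without an optimal codon do not dilute the index).
#'
#' @inheritParams rscu
#' @param optimal character vector of optimal codons (DNA spelling).
#' @return Fop in [0, 1]; \code{NA} when the optimal set is empty or the
#'   eligible denominator is zero.
#' @export
fop <- function(counts, optimal, code = genetic_code()) {
  optimal <- rna_to_dna(optimal)
  if (length(optimal) == 0L) return(NA_real_)
  fams <- codon_families(code)
  eligible <- unlist(fams[vapply(fams, function(f) any(f %in% optimal), TRUE)],
                     use.names = FALSE)
  denom <- sum(counts[eligible])
  if (denom == 0) return(NA_real_)
  sum(counts[intersect(optimal, eligible)]) / denom
}

# Kyte-Doolittle hydropathy values
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' GRAVY hydrophobicity index
#'
#' Grand average of hydropathy: the mean Kyte-Doolittle value over the
#' residues of a protein. Positive values mark hydrophobic proteins.
#'
#' @param protein one-letter amino-acid string.
#' @return mean hydropathy.
#' @export
gravy <- function(protein) {
  stopifnot(nchar(protein) >= 1L)
  aa <- strsplit(toupper(protein), "")[[1L]]
  h <- KYTE_DOOLITTLE[aa]
  if (anyNA(h))
    stop("unknown residue symbol: ", paste(unique(aa[is.na(h)]), collapse = ","))
  mean(h)
}

#' Per-gene usage profiles
#'
#' Computes every per-gene index in one pass: length, Nc, third-position
#' composition, CAI (against a reference built from the flagged ribosomal
#' genes unless one is supplied), Fop (against an optimal codon set, when
#' given) and GRAVY.
#'
#' @param genes list of filtered \code{\link{gene_record}}s.
#' @param code a \code{\link{genetic_code}}.
#' @param cai_ref optional \code{\link{build_cai_reference}} object; by
#'   default one is built from the genes flagged \code{is_ribosomal}.
#' @param optimal optional optimal codon set for Fop (default none: Fop NA).
#' @return data.frame, one row per gene: gene_id, length_codons, ENC, GC3s,
#'   A3s, T3s, G3s, C3s, CAI, Fop, GRAVY, is_ribosomal.
#' @export
usage_profiles <- function(genes, code = genetic_code(), cai_ref = NULL,
                           optimal = character(0)) {
  stopifnot(length(genes) >= 1L)
  tabs <- lapply(genes, count_codons, code = code)
  if (is.null(cai_ref)) {
    ribo <- vapply(genes, `[[`, TRUE, "is_ribosomal")
    if (!any(ribo))
      stop("no ribosomal-protein genes to build the CAI reference from; ",
           "pass cai_ref explicitly")
    cai_ref <- build_cai_reference(tabs[ribo], code)
  }
  rows <- lapply(seq_along(genes), function(i) {
    comp <- third_position_composition(tabs[[i]], code)
    data.frame(
      gene_id = genes[[i]]$gene_id,
      length_codons = length(genes[[i]]$codons),
      ENC = enc(tabs[[i]], code),
      GC3s = comp[["GC3s"]], A3s = comp[["A3s"]], T3s = comp[["T3s"]],
      G3s = comp[["G3s"]], C3s = comp[["C3s"]],
      CAI = cai(tabs[[i]], cai_ref),
      Fop = if (length(optimal)) fop(tabs[[i]], optimal, code) else NA_real_,
      GRAVY = gravy(translate_gene(genes[[i]], code)),
      is_ribosomal = genes[[i]]$is_ribosomal,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write per-gene usage profiles as TSV
#'
#' Full-precision values; column order is fixed as documented in
#' \code{\link{usage_profiles}}.
#'
#' @param profiles data.frame from \code{\link{usage_profiles}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_usage_tsv <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
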