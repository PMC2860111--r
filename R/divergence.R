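#' Import a 12-column tabular hit file
#'
#' Reads BLAST-style tabular output (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Malformed lines are logged and skipped; E-values are consumed from the
#' file, never computed.
#'
#' @param path tab-separated hit file.
#' @return data.frame with the 12 standard columns.
#' @export
import_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  num <- cols[-(1:2)]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 12L) return(NULL)
    v <- suppressWarnings(as.numeric(f[3:12]))
    if (anyNA(v)) return(NULL)
    df <- data.frame(qseqid = f[1L], sseqid = f[2L], stringsAsFactors = FALSE)
    df[num] <- as.list(v)
    df
  })
  bad <- vapply(rows, is.null, TRUE)
  if (any(bad))
    warning(sum(bad), " malformed hit line(s) skipped", call. = FALSE)
  rows <- rows[!bad]
  if (length(rows) == 0L) stop("no parseable hit lines in ", path)
  do.call(rbind, rows)
}

#' Write hit records as a 12-column tabular file
#'
#' @param hits data.frame as returned by \code{\link{import_hits}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# best hit per query: highest bitscore, ties by lower evalue then
# lexicographic subject id
best_hit_per_query <- function(hits) {
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$qseqid), c("qseqid", "sseqid"), drop = FALSE]
}

#' Reciprocal-best-hit ortholog pairing
#'
#' Filters both hit sets on percent identity, E-value, coverage of the
#' longer protein and minimum protein length, then keeps pairs (a, b) where
#' b is a's best surviving hit and a is b's. Coverage is the reported
#' alignment length divided by the length of the longer of the two proteins.
#'
#' @param hits_ab,hits_ba hit tables (\code{\link{import_hits}} format) of
#'   genome A vs B and B vs A.
#' @param len_a,len_b named integer vectors of protein lengths (aa) for the
#'   two genomes.
#' @param min_identity minimum percent identity (default 60).
#' @param max_evalue maximum E-value (default 1e-5); set \code{Inf} when
#'   E-values are not evaluated (internal alignment mode).
#' @param min_coverage minimum coverage of the longer protein (default 0.6).
#' @param min_length minimum protein length in aa for both partners
#'   (default 100).
#' @return data.frame with columns id_a, id_b (sorted by id_a).
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, len_a, len_b,
                                 min_identity = 60, max_evalue = 1e-5,
                                 min_coverage = 0.6, min_length = 100L) {
  pass <- function(hits, qlen, slen) {
    ql <- qlen[hits$qseqid]
    sl <- slen[hits$sseqid]
    ok <- !is.na(ql) & !is.na(sl) &
      hits$pident >= min_identity &
      hits$evalue <= max_evalue &
      hits$length / pmax(ql, sl) >= min_coverage &
      ql >= min_length & sl >= min_length
    hits[ok, , drop = FALSE]
  }
  ab <- best_hit_per_query(pass(hits_ab, len_a, len_b))
  ba <- best_hit_per_query(pass(hits_ba, len_b, len_a))
  ba_best <- stats::setNames(ba$sseqid, ba$qseqid)
  keep <- !is.na(ba_best[ab$sseqid]) & ba_best[ab$sseqid] == ab$qseqid
  out <- data.frame(id_a = ab$qseqid[keep], id_b = ab$sseqid[keep],
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gap penalties
#' (open 11, extend 1), the pairwise stand-in for a general multiple
#' aligner when exactly two sequences are aligned. Identity is computed over
#' aligned columns (gap columns included in the denominator, the hit-table
#' convention) and coverage as both-aligned columns over the longer
#' sequence.
#'
#' @param seq_a,seq_b amino-acid strings (no gaps).
#' @return list with \code{a}, \code{b} (aligned strings with \code{"-"}
#'   gaps), \code{score}, \code{identity} (percent), \code{coverage}.
#' @export
align_proteins <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) >= 1L, nchar(seq_b) >= 1L)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = e$BLOSUM62,
    gapOpening = 11, gapExtension = 1)
  a <- as.character(Biostrings::alignedPattern(al))
  b <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  ncol_both <- sum(ca != "-" & cb != "-")
  list(a = a, b = b, score = Biostrings::score(al),
       identity = 100 * sum(ca == cb & ca != "-") / length(ca),
       coverage = ncol_both / max(nchar(seq_a), nchar(seq_b)))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces every residue by its source codon and every gap by \code{"---"}.
#' The ungapped protein sequences must translate exactly from the supplied
#' codons (terminal stop codons are dropped automatically); any mismatch is
#' a validation error naming the offending position.
#'
#' @param aln protein alignment from \code{\link{align_proteins}} (or any
#'   list with gapped strings \code{a} and \code{b}).
#' @param codons_a,codons_b codon vectors of the two genes (coding strand;
#'   terminal stop allowed).
#' @param code a \code{\link{genetic_code}}.
#' @return list with codon vectors \code{a} and \code{b}, one entry per
#'   alignment column (\code{"---"} at gaps).
#' @export
backtranslate_alignment <- function(aln, codons_a, codons_b,
                                    code = genetic_code()) {
  place <- function(gapped, codons, which) {
    if (codons[length(codons)] %in% code$stops)
      codons <- codons[-length(codons)]
    ch <- strsplit(gapped, "")[[1L]]
    res <- sum(ch != "-")
    if (res != length(codons))
      stop("sequence ", which, ": alignment has ", res,
           " residues but ", length(codons), " codons supplied")
    aa <- unname(code$map[codons])
    aa_aln <- ch[ch != "-"]
    bad <- which(aa != aa_aln)
    if (length(bad))
      stop("sequence ", which, ": residue ", bad[1L], " is ",
           aa_aln[bad[1L]], " but codon ", codons[bad[1L]],
           " translates to ", aa[bad[1L]])
    out <- rep("---", length(ch))
    out[ch != "-"] <- codons
    out
  }
  list(a = place(aln$a, codons_a, "a"), b = place(aln$b, codons_b, "b"))
}

# --- Nei-Gojobori (1986) counting ---------------------------------------

BASES <- c("A", "C", "G", "T")

# per-codon synonymous site count: at each position, the fraction of the 3
# single-nucleotide changes that are synonymous (changes to stops count as
# nonsynonymous), summed over positions. s + n = 3 for every sense codon.
ng86_syn_sites <- function(code = genetic_code()) {
  sense <- names(code$map)[code$map != "*"]
  vapply(stats::setNames(sense, sense), function(cd) {
    ch <- strsplit(cd, "")[[1L]]
    s <- 0
    for (pos in 1:3) for (b in setdiff(BASES, ch[pos])) {
      alt <- ch; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (code$map[[alt]] == code$map[[cd]]) s <- s + 1 / 3
    }
    s
  }, 1)
}

.ng86_cache <- new.env(parent = emptyenv())

ng86_syn_sites_cached <- function(code) {
  key <- paste0("sites_", code$table_id)
  if (is.null(.ng86_cache[[key]]))
    .ng86_cache[[key]] <- ng86_syn_sites(code)
  .ng86_cache[[key]]
}

# average synonymous/nonsynonymous differences between two sense codons by
# enumerating all orderings of the differing positions; paths passing
# through a stop codon are excluded (all-blocked pairs fall back to every
# path). Returns c(sd, nd).
ng86_pair_diffs <- function(ca, cb, code = genetic_code()) {
  if (ca == cb) return(c(sd = 0, nd = 0))
  pos <- which(strsplit(ca, "")[[1L]] != strsplit(cb, "")[[1L]])
  perms <- permutations_of(pos)
  count_path <- function(ord) {
    cur <- strsplit(ca, "")[[1L]]
    tgt <- strsplit(cb, "")[[1L]]
    sd <- nd <- 0
    blocked <- FALSE
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      nxt <- paste(cur, collapse = "")
      if (code$map[[nxt]] == "*") blocked <- TRUE
      if (code$map[[prev]] == code$map[[nxt]]) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd, blocked = as.numeric(blocked))
  }
  paths <- vapply(perms, count_path, c(sd = 0, nd = 0, blocked = 0))
  ok <- paths["blocked", ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(paths))
  c(sd = mean(paths["sd", ok]), nd = mean(paths["nd", ok]))
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

#' Ka/Ks by the Nei-Gojobori counting method
#'
#' Counts synonymous and nonsynonymous sites (equal mutation weights;
#' changes creating a stop count as nonsynonymous so sites sum to 3 per
#' codon) and differences (all mutational pathways between differing codons
#' averaged, pathways through stop codons excluded) over the comparable
#' columns of a codon alignment, then applies the Jukes-Cantor correction
#' \eqn{d = -3/4 \log(1 - 4p/3)}. Columns with a gap, an ambiguous base or
#' a stop codon are excluded. Proportions at or beyond the JC saturation
#' point (p >= 3/4) give \code{NA} (saturation marker).
#'
#' Sites are averaged between the two sequences, the standard symmetric
#' treatment, so the estimate is invariant to sequence order.
#'
#' @param aln codon alignment from \code{\link{backtranslate_alignment}}
#'   (list of codon vectors \code{a}, \code{b}).
#' @param code a \code{\link{genetic_code}}.
#' @return list with Ka, Ks, and the underlying counts: S, N (sites), Sd,
#'   Nd (differences), pS, pN, n_codons (comparable columns).
#' @export
kaks_ng86 <- function(aln, code = genetic_code()) {
  stopifnot(length(aln$a) == length(aln$b))
  ok <- grepl("^[ACGT]{3}$", aln$a) & grepl("^[ACGT]{3}$", aln$b) &
    code$map[aln$a] != "*" & code$map[aln$b] != "*"
  ok[is.na(ok)] <- FALSE
  a <- aln$a[ok]; b <- aln$b[ok]
  if (length(a) == 0L)
    return(list(Ka = NA_real_, Ks = NA_real_, S = 0, N = 0, Sd = 0, Nd = 0,
                pS = NA_real_, pN = NA_real_, n_codons = 0L))
  ssites <- ng86_syn_sites_cached(code)
  S <- (sum(ssites[a]) + sum(ssites[b])) / 2
  N <- 3 * length(a) - S
  # aggregate differing columns by unique codon pair before path enumeration
  idx <- which(a != b)
  Sd <- Nd <- 0
  if (length(idx)) {
    key <- paste(a[idx], b[idx])
    mult <- table(key)
    ucodons <- strsplit(names(mult), " ", fixed = TRUE)
    diffs <- vapply(ucodons, function(cp) ng86_pair_diffs(cp[1L], cp[2L], code),
                    c(sd = 0, nd = 0))
    Sd <- sum(diffs["sd", ] * as.numeric(mult))
    Nd <- sum(diffs["nd", ] * as.numeric(mult))
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)  # saturated
    -3 / 4 * log(1 - 4 * p / 3)
  }
  list(Ka = jc(pN), Ks = jc(pS), S = S, N = N, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN, n_codons = length(a))
}

#' Align an ortholog pair and estimate its divergence
#'
#' Convenience wrapper: translate both genes, align the proteins, back-
#' translate to codons and estimate Ka/Ks.
#'
#' @param gene_a,gene_b \code{\link{gene_record}}s.
#' @param code a \code{\link{genetic_code}}.
#' @param ks_max saturation filter threshold (default 1.0).
#' @return one-row data.frame: gene_id_a, gene_id_b, identity, coverage,
#'   Ka, Ks, pass_ks_filter.
#' @export
ortholog_pair <- function(gene_a, gene_b, code = genetic_code(),
                          ks_max = 1.0) {
  aln <- align_proteins(translate_gene(gene_a, code),
                        translate_gene(gene_b, code))
  caln <- backtranslate_alignment(aln, gene_a$codons, gene_b$codons, code)
  kk <- kaks_ng86(caln, code)
  data.frame(gene_id_a = gene_a$gene_id, gene_id_b = gene_b$gene_id,
             identity = aln$identity, coverage = aln$coverage,
             Ka = kk$Ka, Ks = kk$Ks,
             pass_ks_filter = is.finite(kk$Ks) && kk$Ks < ks_max,
             stringsAsFactors = FALSE)
}

#' Filter ortholog pairs on Ks and correlate divergence with expression
#'
#' Retains pairs with finite Ks below \code{ks_max} (dropping saturated
#' pairs) and reports Pearson correlations of Ka and Ks against the
#' genome-A expression proxies: (Ka, CAI), (Ks, CAI), (Ka, Ks), (Ks, Fop).
#' Fewer than 3 surviving pairs leave the correlations undefined.
#'
#' @param pairs data.frame with gene_id_a, Ka, Ks (e.g. rbind of
#'   \code{\link{ortholog_pair}} rows).
#' @param profiles \code{\link{usage_profiles}} of genome A.
#' @param ks_max Ks saturation threshold (default 1.0).
#' @return list with \code{pairs} (the retained rows, CAI/Fop joined) and
#'   \code{correlations} (data.frame x, y, r, p, n).
#' @export
filter_and_correlate <- function(pairs, profiles, ks_max = 1.0) {
  keep <- is.finite(pairs$Ks) & is.finite(pairs$Ka) & pairs$Ks < ks_max
  kept <- pairs[keep, , drop = FALSE]
  m <- match(kept$gene_id_a, profiles$gene_id)
  kept$CAI <- profiles$CAI[m]
  kept$Fop <- profiles$Fop[m]
  combos <- list(c("Ka", "CAI"), c("Ks", "CAI"), c("Ka", "Ks"), c("Ks", "Fop"))
  corr <- do.call(rbind, lapply(combos, function(xy) {
    x <- kept[[xy[1L]]]; y <- kept[[xy[2L]]]
    ok <- is.finite(x) & is.finite(y)
    r <- p <- NA_real_
    if (sum(ok) >= 3L && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    data.frame(x = xy[1L], y = xy[2L], r = r, p = p, n = sum(ok),
               stringsAsFactors = FALSE)
  }))
  list(pairs = kept, correlations = corr)
}
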