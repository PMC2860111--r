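#' Construct a gene record
#'
#' One coding sequence, held as codons on the coding strand together with its
#' genomic placement and annotation. All coordinates are 1-based inclusive
#' (GenBank convention).
#'
#' @param gene_id identifier (locus tag or FASTA id).
#' @param codons character vector of 3-mers over \{A,C,G,T\}, coding strand,
#'   terminal stop included.
#' @param strand \code{"+"} or \code{"-"}.
#' @param start,end 1-based inclusive genomic coordinates, \code{start <= end}.
#' @param product free-text product annotation (may be \code{""}).
#' @param expression optional expression proxy (used by the simulator;
#'   \code{NA} for real data until a CAI is computed).
#' @return object of class \code{"gene_record"}.
#' @export
gene_record <- function(gene_id, codons, strand = "+", start = 1L,
                        end = start + 3L * length(codons) - 1L,
                        product = "", expression = NA_real_) {
  codons <- toupper(codons)
  stopifnot(length(codons) >= 1L, all(nchar(codons) == 3L),
            strand %in% c("+", "-"), start <= end)
  structure(list(gene_id = as.character(gene_id), codons = codons,
                 strand = strand, start = as.integer(start),
                 end = as.integer(end), product = as.character(product),
                 is_ribosomal = is_ribosomal_product(product),
                 expression = expression),
            class = "gene_record")
}

# The paper-style reference class is picked out by annotation text.
is_ribosomal_product <- function(product) {
  grepl("ribosomal protein", product, ignore.case = TRUE)
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record %s: %d codons, %s strand, %d..%d%s>\n",
              x$gene_id, length(x$codons), x$strand, x$start, x$end,
              if (x$is_ribosomal) ", ribosomal" else ""))
  invisible(x)
}

#' Read coding sequences from FASTA or GenBank
#'
#' Reads a CDS set into a list of \code{\link{gene_record}}s. FASTA input is
#' one CDS per record; since FASTA carries no coordinates, records are given
#' strand \code{"+"} and synthetic coordinates from a cumulative end-to-end
#' layout, and the description after the first whitespace is kept as the
#' product text. GenBank input is a flat file whose CDS features (including
#' \code{complement()} and \code{join()} locations) are extracted against the
#' ORIGIN sequence; codons are always reported on the coding strand.
#'
#' Records whose length is not a multiple of 3 are excluded with a warning,
#' never an error.
#'
#' @param path input file.
#' @param format \code{"fasta"} or \code{"genbank"}.
#' @return list of \code{gene_record}.
#' @export
read_cds <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  genes <- switch(format,
                  fasta = read_cds_fasta(path),
                  genbank = read_cds_genbank(path))
  if (length(genes) == 0L)
    stop("no usable CDS records parsed from ", path)
  genes
}

read_cds_fasta <- function(path) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("cannot parse FASTA file ", path,
                                            ": ", conditionMessage(e)))
  offset <- 0L
  genes <- vector("list", length(seqs))
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    nm <- names(seqs)[i]
    id <- sub("\\s.*$", "", nm)
    product <- if (grepl("\\s", nm)) sub("^\\S+\\s+", "", nm) else ""
    s <- as.character(seqs[[i]])
    if (nchar(s) %% 3L != 0L) {
      warning("record ", id, " length ", nchar(s),
              " not divisible by 3; excluded", call. = FALSE)
      next
    }
    genes[[i]] <- gene_record(id, codon_split(s), strand = "+",
                              start = offset + 1L, end = offset + nchar(s),
                              product = product)
    offset <- offset + nchar(s)
    keep[i] <- TRUE
  }
  genes[keep]
}

# split a nucleotide string into consecutive codons
codon_split <- function(s) {
  s <- toupper(s)
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Apply the gene inclusion filters
#'
#' Retains genes that (i) have at least \code{min_codons} codons, counting
#' the terminal stop, (ii) start with an accepted initiation codon,
#' (iii) end with a termination codon, and (iv) contain no internal stop and
#' no ambiguous base. Filtering never raises on content; it only drops.
#'
#' @param genes list of \code{\link{gene_record}}.
#' @param code a \code{\link{genetic_code}}.
#' @param min_codons minimum gene length in codons, stop included
#'   (default 100).
#' @return the retained sublist, in input order.
#' @export
filter_genes <- function(genes, code = genetic_code(), min_codons = 100L) {
  keep <- vapply(genes, function(g) {
    cd <- g$codons
    n <- length(cd)
    if (n < min_codons) return(FALSE)
    if (!all(grepl("^[ACGT]{3}$", cd))) return(FALSE)
    if (!(cd[1L] %in% code$starts)) return(FALSE)
    if (!(cd[n] %in% code$stops)) return(FALSE)
    !any(cd[-n] %in% code$stops)
  }, logical(1L))
  genes[keep]
}

#' Translate a gene record
#'
#' Translates the codons on the coding strand, dropping the terminal stop.
#' An internal stop codon is a validation error naming the gene: genes are
#' expected to have passed \code{\link{filter_genes}}.
#'
#' @inheritParams filter_genes
#' @param gene a \code{\link{gene_record}}.
#' @return one-letter amino-acid string of length \code{length(codons) - 1}
#'   when the gene ends in a stop, else \code{length(codons)}.
#' @export
translate_gene <- function(gene, code = genetic_code()) {
  cd <- gene$codons
  if (cd[length(cd)] %in% code$stops) cd <- cd[-length(cd)]
  aa <- unname(code$map[cd])
  if (anyNA(aa))
    stop("gene ", gene$gene_id, ": unknown codon ",
         cd[which(is.na(aa))[1L]])
  if (any(aa == "*"))
    stop("gene ", gene$gene_id, ": internal stop codon at codon position ",
         which(aa == "*")[1L])
  paste(aa, collapse = "")
}

#' Write the gene table as TSV
#'
#' @param genes list of \code{\link{gene_record}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  df <- gene_table(genes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene records as a data frame
#'
#' @param genes list of \code{\link{gene_record}}.
#' @return data.frame with columns gene_id, length_codons, strand, start,
#'   end, is_ribosomal.
#' @export
gene_table <- function(genes) {
  data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    length_codons = vapply(genes, function(g) length(g$codons), 1L),
    strand = vapply(genes, `[[`, "", "strand"),
    start = vapply(genes, `[[`, 1L, "start"),
    end = vapply(genes, `[[`, 1L, "end"),
    is_ribosomal = vapply(genes, `[[`, TRUE, "is_ribosomal"),
    stringsAsFactors = FALSE)
}

#' Write gene records as a CDS multi-FASTA
#'
#' @param genes list of \code{\link{gene_record}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cds_fasta <- function(genes, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(genes, function(g) paste(g$codons, collapse = ""), ""))
  names(seqs) <- vapply(genes, function(g)
    if (nzchar(g$product)) paste(g$gene_id, g$product) else g$gene_id, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
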