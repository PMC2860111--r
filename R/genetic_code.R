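#' Genetic code definition
#'
#' Wraps an NCBI translation table as a small list used throughout the
#' package: the codon-to-amino-acid map, the accepted initiation codons and
#' the termination codons. The default is the bacterial/archaeal table 11
#' with the alternative initiation codons ATG, GTG and TTG, which covers the
#' start-codon repertoire of GC-rich actinobacteria such as
#' \emph{Corynebacterium glutamicum}.
#'
#' @param table_id NCBI genetic code table number (default 11).
#' @param start_codons character vector of accepted initiation codons
#'   (DNA alphabet). Defaults to \code{c("ATG", "GTG", "TTG")} for table 11,
#'   otherwise to the table's annotated alternative initiation codons.
#' @return An object of class \code{"genetic_code"}: a list with elements
#'   \code{table_id}, \code{map} (named character vector of length 64,
#'   codon -> one-letter amino acid, stops mapped to \code{"*"}),
#'   \code{starts} and \code{stops}.
#' @examples
#' code <- genetic_code()
#' code$map[["ATG"]]   # "M"
#' code$stops          # "TAA" "TAG" "TGA"
#' @export
genetic_code <- function(table_id = 11L, start_codons = NULL) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- map[CODONS]  # fixed codon order
  if (is.null(start_codons)) {
    start_codons <- if (table_id == 11L) c("ATG", "GTG", "TTG") else
      unique(c("ATG", attr(Biostrings::getGeneticCode(as.character(table_id)),
                           "alt_init_codons")))
  }
  stops <- names(map)[map == "*"]
  stopifnot(length(map) == 64L, length(stops) >= 1L, length(start_codons) >= 1L)
  structure(list(table_id = as.integer(table_id), map = map,
                 starts = toupper(start_codons), stops = stops),
            class = "genetic_code")
}

# All 64 codons in the package's fixed column order (T, C, A, G by position,
# the classical codon-table order). Every count vector and usage matrix in
# the package follows this order.
CODONS <- {
  b <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("Genetic code table %d: %d sense codons, stops %s, starts %s\n",
              x$table_id, sum(x$map != "*"), paste(x$stops, collapse = ","),
              paste(x$starts, collapse = ",")))
  invisible(x)
}

#' Synonymous codon families
#'
#' Splits the sense codons into synonymous families, optionally dropping the
#' non-degenerate amino acids (Met, Trp) and the stop codons — the 59-codon
#' universe over which RSCU, GC3s, CAI and the ordination are defined.
#'
#' @param code a \code{\link{genetic_code}}.
#' @param drop_nondegenerate drop families of size 1 (Met, Trp) and stops.
#' @return named list of character vectors, one per amino acid, each the
#'   codons encoding it (in \code{CODONS} order).
#' @export
codon_families <- function(code = genetic_code(), drop_nondegenerate = TRUE) {
  fam <- split(names(code$map), code$map)
  fam <- fam[names(fam) != "*"]
  if (drop_nondegenerate) fam <- fam[vapply(fam, length, 1L) > 1L]
  fam
}

#' The 59 synonymously variable codons
#'
#' Codons belonging to degenerate families: all sense codons excluding Met,
#' Trp and the termination codons. This is the column set of the usage
#' matrix and the domain of RSCU, GC3s, CAI and Fop.
#'
#' @inheritParams codon_families
#' @return character vector of codons in \code{CODONS} order.
#' @export
synonymous_codons <- function(code = genetic_code()) {
  fam <- codon_families(code, drop_nondegenerate = TRUE)
  CODONS[CODONS %in% unlist(fam, use.names = FALSE)]
}

# RNA (U) <-> DNA (T) codon spelling, used when reading published tables.
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))
dna_to_rna <- function(x) chartr("T", "U", toupper(x))
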