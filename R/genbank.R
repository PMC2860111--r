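# Minimal GenBank flat-file reader: ORIGIN sequence plus CDS features with
# complement()/join() locations and /locus_tag, /gene, /product qualifiers.
# Only what a bacterial CDS extraction needs; not a general feature parser.

read_cds_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L)
    stop("cannot parse GenBank file ", path, ": no ORIGIN section")
  feat_at <- grep("^FEATURES", lines)
  if (length(feat_at) == 0L)
    stop("cannot parse GenBank file ", path, ": no FEATURES section")

  seq_lines <- lines[(origin_at[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(genome) == 0L)
    stop("cannot parse GenBank file ", path, ": empty ORIGIN sequence")

  feats <- parse_genbank_cds(lines[(feat_at[1L] + 1L):(origin_at[1L] - 1L)])
  if (length(feats) == 0L)
    stop("GenBank file ", path, " contains no CDS features")

  genes <- vector("list", length(feats))
  keep <- logical(length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    loc <- parse_genbank_location(f$location)
    if (is.null(loc)) {
      warning("CDS ", i, ": unsupported location '", f$location,
              "'; skipped", call. = FALSE)
      next
    }
    parts <- vapply(seq_len(nrow(loc$spans)), function(k)
      substr(genome, loc$spans[k, 1L], loc$spans[k, 2L]), "")
    s <- paste(parts, collapse = "")
    if (loc$strand == "-") s <- revcomp(s)
    id <- f$locus_tag %||% f$gene %||% paste0("CDS_", i)
    if (nchar(s) %% 3L != 0L) {
      warning("CDS ", id, " length ", nchar(s),
              " not divisible by 3; excluded", call. = FALSE)
      next
    }
    genes[[i]] <- gene_record(id, codon_split(s), strand = loc$strand,
                              start = min(loc$spans), end = max(loc$spans),
                              product = f$product %||% "")
    keep[i] <- TRUE
  }
  genes[keep]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Collect CDS feature blocks: a feature key line has indent 5, qualifier and
# continuation lines have indent 21.
parse_genbank_cds <- function(lines) {
  key_at <- grep("^ {5}\\S", lines)
  if (length(key_at) == 0L) return(list())
  block_end <- c(key_at[-1L] - 1L, length(lines))
  out <- list()
  for (j in seq_along(key_at)) {
    hdr <- lines[key_at[j]]
    key <- sub("^ {5}(\\S+).*$", "\\1", hdr)
    if (key != "CDS") next
    block <- c(sub("^ {5}\\S+\\s*", "", hdr),
               trimws(lines[seq(key_at[j] + 1L, block_end[j])
                            [key_at[j] < block_end[j]]]))
    block <- block[nzchar(block)]
    # location = leading lines up to the first qualifier
    qual_at <- grep("^/", block)
    loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(block)
    location <- paste(block[seq_len(loc_end)], collapse = "")
    quals <- parse_genbank_qualifiers(block[seq_along(block) > loc_end])
    out[[length(out) + 1L]] <- c(list(location = location), quals)
  }
  out
}

parse_genbank_qualifiers <- function(lines) {
  quals <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^/", ln)) {
      m <- regmatches(ln, regexec("^/([A-Za-z_]+)=?(.*)$", ln))[[1L]]
      current <- m[2L]
      quals[[current]] <- m[3L]
    } else if (!is.null(current)) {
      quals[[current]] <- paste(quals[[current]], ln)
    }
  }
  lapply(quals, function(v) gsub('^"|"$', "", v))
}

# Supports n..m, complement(...), join(a..b,c..d) and their composition;
# partial-end markers < and > are stripped. Returns NULL when unsupported.
parse_genbank_location <- function(loc) {
  loc <- gsub("[<>\\s]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  if (grepl("[a-z]", loc)) return(NULL)  # nested/remote locations unsupported
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  spans <- t(vapply(parts, function(p) {
    xs <- as.integer(strsplit(p, "..", fixed = TRUE)[[1L]])
    if (length(xs) == 1L) xs <- c(xs, xs)
    xs
  }, integer(2L)))
  if (anyNA(spans) || any(spans[, 1L] > spans[, 2L])) return(NULL)
  # complement(join(...)) lists segments in genomic order; extraction
  # concatenates them and reverse-complements the whole, which yields the
  # coding sequence directly
  list(strand = strand, spans = spans)
}
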