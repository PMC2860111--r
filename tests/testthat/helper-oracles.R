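# Independent oracles and tiny generators shared across the test files.
# Each oracle is a deliberately plain, separate transcription of the
# defining formulas, kept independent of the package implementation paths.

CODON_SET <- codonbias:::CODONS
TEST_CODE <- genetic_code()

# random sense-codon gene: ATG ... TAA, no internal stop
random_gene <- function(n_codons, id = "g1", seed = NULL, strand = "+",
                        start = 1L, product = "") {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(TEST_CODE$map)[TEST_CODE$map != "*" ]
  inner <- sample(sense, n_codons - 2L, replace = TRUE)
  gene_record(id, c("ATG", inner, "TAA"), strand = strand, start = start,
              end = start + 3L * n_codons - 1L, product = product)
}

# literal transcription of Wright's Nc formulas, written as nested loops
# over explicitly listed families (independent of enc()'s vectorised path)
wright_enc_oracle <- function(counts) {
  fam_by_aa <- split(names(TEST_CODE$map), TEST_CODE$map)
  fam_by_aa <- fam_by_aa[!names(fam_by_aa) %in% c("*", "M", "W")]
  deg <- sapply(fam_by_aa, length)
  fbar <- c()
  for (k in c(2, 3, 4, 6)) {
    fs <- c()
    for (aa in names(fam_by_aa)[deg == k]) {
      fam <- fam_by_aa[[aa]]
      n <- sum(counts[fam])
      if (n < 2) next
      p <- counts[fam] / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (f > 0) fs <- c(fs, f)
    }
    fbar[as.character(k)] <- if (length(fs)) mean(fs) else NA
  }
  if (is.na(fbar["3"])) fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  if (any(is.na(fbar[c("2", "4", "6")]))) return(NA_real_)
  nc <- 2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"]
  unname(min(max(nc, 20), 61))
}

# closed-form Pearson chi-square for a 2x2 table
chi2_2x2_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# chi-square distances between the row profiles of a contingency-like matrix
chisq_row_distances <- function(m) {
  P <- m / sum(m)
  prof <- P / rowSums(P)
  cmass <- colSums(P)
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((prof[i, ] - prof[j, ])^2 / cmass))
  d
}

# --- NG86 enumeration oracle ---------------------------------------------
# Sites: per codon, per position, count synonymous single-base changes
# (changes to stops are nonsynonymous). Differences: recursive depth-first
# enumeration of substitution orders, averaging over stop-free paths.

ng86_sites_oracle <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  aa <- TEST_CODE$map[[codon]]
  s <- 0
  for (pos in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
    alt <- ch
    alt[pos] <- b
    if (TEST_CODE$map[[paste(alt, collapse = "")]] == aa) s <- s + 1 / 3
  }
  s
}

ng86_paths_oracle <- function(ca, cb) {
  if (TEST_CODE$map[[ca]] == "*" || TEST_CODE$map[[cb]] == "*")
    return(NULL)
  if (ca == cb) return(c(sd = 0, nd = 0))
  walk <- function(cur, remaining) {
    # returns list of c(sd, nd, blocked) over all substitution orders
    if (length(remaining) == 0) return(list(c(0, 0, 0)))
    out <- list()
    for (p in remaining) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[p] <- strsplit(cb, "")[[1]][p]
      nxt <- paste(nxt, collapse = "")
      syn <- TEST_CODE$map[[cur]] == TEST_CODE$map[[nxt]]
      blocked <- TEST_CODE$map[[nxt]] == "*"
      step <- c(as.numeric(syn), as.numeric(!syn), as.numeric(blocked))
      for (tail in walk(nxt, setdiff(remaining, p)))
        out[[length(out) + 1]] <- step + tail
    }
    out
  }
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  paths <- walk(ca, pos)
  m <- do.call(rbind, paths)
  ok <- m[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, 1]), nd = mean(m[ok, 2]))
}

# direct per-window tally of GC skew, string-based
gc_skew_window_oracle <- function(genome, pos, window) {
  n <- nchar(genome)
  idx <- ((pos - 1):(pos + window - 2)) %% n + 1
  b <- strsplit(genome, "")[[1]][idx]
  g <- sum(b == "G")
  c_ <- sum(b == "C")
  if (g + c_ == 0) 0 else (g - c_) / (g + c_)
}

# global protein alignment score by plain affine-gap dynamic programming
# (Gotoh), BLOSUM62, for tiny sequences. A gap of length L costs
# gap_open + L * gap_ext (the BLAST-style convention).
dp_align_score_oracle <- function(a, b, gap_open = 11, gap_ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -gap_open - i * gap_ext
  for (j in seq_len(m)) Iy[1, j + 1] <- -gap_open - j * gap_ext
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- B[x[i], y[j]]
    M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                            Ix[i, j + 1] - gap_ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                            Iy[i + 1, j] - gap_ext)
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# score an already-aligned pair of gapped strings under the same scheme
score_alignment_oracle <- function(a, b, gap_open = 11, gap_ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  score <- 0
  in_gap_x <- in_gap_y <- FALSE
  for (k in seq_along(x)) {
    if (x[k] == "-" ) {
      score <- score - gap_ext - if (in_gap_x) 0 else gap_open
      in_gap_x <- TRUE; in_gap_y <- FALSE
    } else if (y[k] == "-") {
      score <- score - gap_ext - if (in_gap_y) 0 else gap_open
      in_gap_y <- TRUE; in_gap_x <- FALSE
    } else {
      score <- score + B[x[k], y[k]]
      in_gap_x <- in_gap_y <- FALSE
    }
  }
  score
}
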