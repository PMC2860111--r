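#' Windowed GC skew along a genome
#'
#' GC skew, (G - C)/(G + C), computed in sliding windows on the given strand
#' of a circular genome (windows wrap past the end). A window without G or C
#' gets skew 0 by convention. The sign of the cumulative skew flips at the
#' replication origin and terminus in most bacteria, because the leading
#' strand is G-rich.
#'
#' @param genome nucleotide string (A/C/G/T; case-insensitive).
#' @param window window size in bp (default 24000).
#' @param step step size in bp (default 3000).
#' @return data.frame with columns \code{position} (1-based window start)
#'   and \code{skew}.
#' @export
gc_skew_track <- function(genome, window = 24000L, step = 3000L) {
  genome <- toupper(genome)
  n <- nchar(genome)
  stopifnot(n >= window, step >= 1L)
  b <- strsplit(genome, "", fixed = TRUE)[[1L]]
  g <- as.integer(b == "G")
  cc <- as.integer(b == "C")
  # extend circularly by one window so every window is a contiguous slice
  gext <- cumsum(c(0L, g, g[seq_len(min(window, n))]))
  cext <- cumsum(c(0L, cc, cc[seq_len(min(window, n))]))
  pos <- seq.int(1L, n, by = step)
  gw <- gext[pos + window] - gext[pos]
  cw <- cext[pos + window] - cext[pos]
  skew <- ifelse(gw + cw == 0, 0, (gw - cw) / (gw + cw))
  data.frame(position = pos, skew = skew)
}

#' Locate replication origin and terminus by cumulative GC skew
#'
#' Walks the genome base by base, adding +1 for G and -1 for C, and takes
#' the global minimum of the cumulative walk as the origin and the global
#' maximum as the terminus (ties resolved to the smallest coordinate): on
#' the plus strand the walk rises across the replichore where that strand
#' is leading (G-rich) and falls across the other, so its extrema bracket
#' the two replichores.
#'
#' A genome with a flat walk (no G/C asymmetry) is degenerate: the positions
#' default to 1 and half the genome length, with a warning.
#'
#' @param genome nucleotide string; intended for genomes of at least ~10 kb.
#' @return list with \code{ori}, \code{ter} (1-based positions) and
#'   \code{degenerate} flag.
#' @export
locate_ori_ter <- function(genome) {
  genome <- toupper(genome)
  n <- nchar(genome)
  stopifnot(n >= 2L)
  b <- strsplit(genome, "", fixed = TRUE)[[1L]]
  walk <- cumsum((b == "G") - (b == "C"))
  if (max(walk) == min(walk)) {
    warning("flat GC-skew walk: origin/terminus are undefined; ",
            "defaulting to 1 and length/2", call. = FALSE)
    return(list(ori = 1L, ter = as.integer(n %/% 2L), degenerate = TRUE))
  }
  list(ori = which.min(walk), ter = which.max(walk), degenerate = FALSE)
}

#' Classify a gene as leading- or lagging-strand
#'
#' Replication proceeds bidirectionally from the origin towards the
#' terminus. On the replichore covered by the fork moving in the direction
#' of increasing coordinates (the arc from ori to ter, wrapping), a gene is
#' leading iff it lies on the \code{"+"} strand; on the other replichore
#' iff it lies on the \code{"-"} strand. Membership is decided by the gene
#' midpoint, which keeps genes spanning ori or ter stable.
#'
#' @param gene a \code{\link{gene_record}} (or any list with strand, start,
#'   end).
#' @param ori,ter origin and terminus positions (1-based).
#' @param genome_length genome length in bp.
#' @return \code{"leading"} or \code{"lagging"}.
#' @export
classify_strand <- function(gene, ori, ter, genome_length) {
  stopifnot(ori != ter, gene$end <= genome_length | gene$start <= genome_length)
  mid <- ((gene$start + gene$end) %/% 2L - 1L) %% genome_length + 1L
  on_right_fork <- if (ori < ter) mid >= ori && mid < ter
                   else mid >= ori || mid < ter
  plus <- gene$strand == "+"
  if (on_right_fork == plus) "leading" else "lagging"
}

#' Build a replication map for a genome and its genes
#'
#' Computes the windowed skew track, locates ori/ter by cumulative skew
#' (unless both are supplied, e.g. simulator ground truth), and classifies
#' every gene as leading or lagging.
#'
#' @param genome nucleotide string.
#' @param genes list of \code{\link{gene_record}}.
#' @param window,step skew window and step in bp.
#' @param ori,ter optional known origin/terminus positions; when \code{NULL}
#'   they are located from the cumulative skew.
#' @return object of class \code{"replication_map"}: list with
#'   genome_length, window, step, skew_track, ori, ter, degenerate, and
#'   \code{classes} (named character vector gene_id -> leading/lagging).
#' @export
replication_map <- function(genome, genes, window = 24000L, step = 3000L,
                            ori = NULL, ter = NULL) {
  n <- nchar(genome)
  track <- if (n >= window) gc_skew_track(genome, window, step) else
    data.frame(position = integer(0), skew = numeric(0))
  degenerate <- FALSE
  if (is.null(ori) || is.null(ter)) {
    loc <- locate_ori_ter(genome)
    ori <- loc$ori; ter <- loc$ter; degenerate <- loc$degenerate
  }
  classes <- vapply(genes, classify_strand, "", ori = ori, ter = ter,
                    genome_length = n)
  names(classes) <- vapply(genes, `[[`, "", "gene_id")
  structure(list(genome_length = n, window = window, step = step,
                 skew_track = track, ori = as.integer(ori),
                 ter = as.integer(ter), degenerate = degenerate,
                 classes = classes),
            class = "replication_map")
}

#' @export
print.replication_map <- function(x, ...) {
  cat(sprintf("<replication_map: %d bp, ori %d, ter %d, %d genes (%d leading)>\n",
              x$genome_length, x$ori, x$ter, length(x$classes),
              sum(x$classes == "leading")))
  invisible(x)
}

#' Leading-strand gene fractions by CAI bin
#'
#' Bins genes by CAI and tabulates how many fall on the leading versus
#' lagging strand per bin, with percentages (2 d.p. columns alongside full
#' precision). Boundary CAI values go to the lower bin. Named special sets
#' (e.g. the ribosomal proteins) are appended as extra rows; genes with
#' \code{NA} CAI are skipped in the bins but still counted in special rows.
#'
#' @param cai numeric CAI per gene.
#' @param leading logical per gene: TRUE = leading strand.
#' @param special named list of logical vectors selecting extra row sets.
#' @param bins interior CAI bin edges (default \code{c(0.35, 0.65)}).
#' @return data.frame: range, total, leading, lagging, leading_pct,
#'   lagging_pct (2 d.p.; \code{NA} for empty bins), leading_pct_full.
#' @export
leading_fraction_by_cai <- function(cai, leading, special = list(),
                                    bins = c(0.35, 0.65)) {
  stopifnot(length(cai) == length(leading), is.logical(leading))
  edges <- c(-Inf, sort(bins), Inf)
  labels <- c(paste0("CAI <= ", bins[1L]),
              if (length(bins) > 1L)
                paste0(utils::head(sort(bins), -1L), " < CAI <= ",
                       sort(bins)[-1L]),
              paste0("CAI > ", max(bins)))
  grp <- cut(cai, breaks = edges, labels = labels, right = TRUE)
  rows <- lapply(labels, function(lb) {
    sel <- !is.na(grp) & grp == lb
    bin_row(lb, leading[sel])
  })
  for (nm in names(special)) {
    sel <- special[[nm]]
    stopifnot(length(sel) == length(leading))
    rows[[length(rows) + 1L]] <- bin_row(nm, leading[sel])
  }
  do.call(rbind, rows)
}

bin_row <- function(label, leading) {
  n <- length(leading)
  nl <- sum(leading)
  pct <- if (n > 0) 100 * nl / n else NA_real_
  data.frame(range = label, total = n, leading = nl, lagging = n - nl,
             leading_pct = round(pct, 2), lagging_pct = round(100 - pct, 2),
             leading_pct_full = pct, stringsAsFactors = FALSE)
}

#' Percentages for an already-binned strand count table
#'
#' Adds 2-d.p. leading/lagging percentages to a table of per-bin totals,
#' e.g. the published \code{\link{cglutamicum_strand_counts}}.
#'
#' @param df data.frame with columns total, leading, lagging.
#' @return the data.frame with leading_pct and lagging_pct columns added.
#' @export
strand_percentages <- function(df) {
  stopifnot(all(c("total", "leading", "lagging") %in% names(df)),
            all(df$leading + df$lagging == df$total))
  df$leading_pct <- ifelse(df$total > 0, round(100 * df$leading / df$total, 2),
                           NA_real_)
  df$lagging_pct <- ifelse(df$total > 0, round(100 * df$lagging / df$total, 2),
                           NA_real_)
  df
}
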