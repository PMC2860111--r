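#' Build the gene-by-codon usage matrix
#'
#' Rows are genes, columns the 59 synonymously variable codons (Met, Trp and
#' stops excluded) in fixed \code{CODONS} order. \code{kind = "rscu"} fills
#' per-gene RSCU values, with families absent from a gene set to 0 so the
#' matrix stays complete and non-negative; \code{kind = "counts"} uses raw
#' codon counts. Genes whose row would be all zero are excluded with a
#' warning.
#'
#' @param tables named list of 64-entry codon count vectors (names become
#'   row names; unnamed lists get \code{gene_1 ...}).
#' @param code a \code{\link{genetic_code}}.
#' @param kind \code{"rscu"} (default) or \code{"counts"}.
#' @return numeric matrix, genes x 59.
#' @export
build_usage_matrix <- function(tables, code = genetic_code(),
                               kind = c("rscu", "counts")) {
  kind <- match.arg(kind)
  stopifnot(length(tables) >= 3L)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- paste0("gene_", seq_along(tables))
  syn <- synonymous_codons(code)
  rows <- lapply(tables, function(tab) {
    stopifnot(sum(tab) > 0)
    if (kind == "rscu") {
      r <- rscu(tab, code)
      r[is.na(r)] <- 0
      r
    } else {
      as.numeric(tab[syn])
    }
  })
  m <- do.call(rbind, rows)
  colnames(m) <- syn
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with all-zero usage rows excluded: ",
            paste(utils::head(names(tables)[zero], 5L), collapse = ","),
            call. = FALSE)
    m <- m[!zero, , drop = FALSE]
  }
  m
}

#' Correspondence analysis of a codon usage matrix
#'
#' Standard (chi-square metric) correspondence analysis: with
#' \eqn{P = X / N} (N the grand total), row masses r and column masses c,
#' the standardized residuals \eqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}}
#' are decomposed by SVD; row (gene) principal coordinates are
#' \eqn{D_r^{-1/2} U \Sigma}, column (codon) principal coordinates
#' \eqn{D_c^{-1/2} V \Sigma}, and each axis carries an inertia fraction
#' \eqn{\sigma_k^2 / \sum \sigma^2}. Axis signs are arbitrary; see
#' \code{\link{orient_axis}}.
#'
#' All-zero columns are dropped (and recorded); a matrix whose rows are all
#' proportional (total inertia 0) yields all-zero coordinates rather than an
#' error.
#'
#' @param m non-negative gene x codon matrix from
#'   \code{\link{build_usage_matrix}}.
#' @param n_axes number of axes to retain (default 4, capped at the rank).
#' @return object of class \code{"coa_result"}: list with
#'   \code{gene_coords}, \code{codon_coords}, \code{inertia_fraction}
#'   (percent per axis), \code{total_inertia}, \code{singular_values},
#'   \code{dropped_codons}.
#' @export
correspondence_analysis <- function(m, n_axes = 4L) {
  stopifnot(is.matrix(m), all(m >= 0), nrow(m) >= 3L)
  if (any(rowSums(m) == 0)) stop("all-zero rows must be removed before CA")
  dropped <- colnames(m)[colSums(m) == 0]
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (is.null(rownames(m))) rownames(m) <- paste0("gene_", seq_len(nrow(m)))

  P <- m / sum(m)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  tol <- max(dim(m)) * max(sv$d, 0) * .Machine$double.eps * 100
  total_inertia <- sum(sv$d^2)

  if (total_inertia <= tol^2 || max(sv$d) <= tol) {
    k <- min(n_axes, nrow(m) - 1L, ncol(m) - 1L)
    zg <- matrix(0, nrow(m), k, dimnames = list(rownames(m),
                                                paste0("Axis", seq_len(k))))
    zc <- matrix(0, ncol(m), k, dimnames = list(colnames(m),
                                                paste0("Axis", seq_len(k))))
    return(structure(list(gene_coords = zg, codon_coords = zc,
                          inertia_fraction = rep(0, k),
                          total_inertia = 0,
                          singular_values = rep(0, k),
                          dropped_codons = dropped),
                     class = "coa_result"))
  }
  rank <- sum(sv$d > tol)
  if (rank < 2L) stop("usage matrix has rank < 2: too few distinct genes")
  k <- min(n_axes, rank)
  d <- sv$d[seq_len(k)]
  gene_coords <- sweep(sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k), 1,
                       sqrt(r), "/")
  codon_coords <- sweep(sv$v[, seq_len(k), drop = FALSE] %*% diag(d, k), 1,
                        sqrt(cc), "/")
  dimnames(gene_coords) <- list(rownames(m), paste0("Axis", seq_len(k)))
  dimnames(codon_coords) <- list(colnames(m), paste0("Axis", seq_len(k)))
  structure(list(gene_coords = gene_coords, codon_coords = codon_coords,
                 inertia_fraction = 100 * d^2 / total_inertia,
                 total_inertia = total_inertia,
                 singular_values = d,
                 dropped_codons = dropped),
            class = "coa_result")
}

#' @export
print.coa_result <- function(x, ...) {
  cat(sprintf("Correspondence analysis: %d genes, %d codons, %d axes\n",
              nrow(x$gene_coords), nrow(x$codon_coords),
              ncol(x$gene_coords)))
  cat("Inertia (%):", paste(sprintf("%.2f", x$inertia_fraction),
                            collapse = " "), "\n")
  invisible(x)
}

#' Orient an ordination axis by a reference gene set
#'
#' CA axis signs are arbitrary. This flips the chosen axis (gene and codon
#' coordinates together) so that the mean coordinate of a reference set —
#' typically the ribosomal-protein genes, i.e. the putatively highly
#' expressed class — is positive, putting highly expressed genes at the
#' positive end of axis 1.
#'
#' @param coa a \code{\link{correspondence_analysis}} result.
#' @param reference logical vector over genes (TRUE = reference gene) or a
#'   character vector of gene ids.
#' @param axis axis number to orient (default 1).
#' @return the reoriented \code{coa_result}.
#' @export
orient_axis <- function(coa, reference, axis = 1L) {
  ids <- rownames(coa$gene_coords)
  sel <- if (is.character(reference)) ids %in% reference else reference
  stopifnot(length(sel) == length(ids))
  if (any(sel) && mean(coa$gene_coords[sel, axis]) < 0) {
    coa$gene_coords[, axis] <- -coa$gene_coords[, axis]
    coa$codon_coords[, axis] <- -coa$codon_coords[, axis]
  }
  coa
}

#' Extreme gene groups along an ordination axis
#'
#' The top and bottom \code{ceiling(fraction * n)} genes by the chosen axis
#' coordinate, ties broken by gene id. With axis 1 oriented by
#' \code{\link{orient_axis}}, the \code{high} group is the putatively highly
#' expressed end.
#'
#' @param coa a \code{\link{correspondence_analysis}} result.
#' @param axis axis number (default 1).
#' @param fraction fraction of genes per extreme, in (0, 0.5] (default 0.05).
#' @return list with character vectors \code{high} and \code{low}.
#' @export
axis_extremes <- function(coa, axis = 1L, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 0.5)
  x <- coa$gene_coords[, axis]
  ids <- rownames(coa$gene_coords)
  k <- ceiling(fraction * length(x))
  ord_low <- order(x, ids)
  ord_high <- order(-x, ids)
  list(high = ids[ord_high[seq_len(k)]], low = ids[ord_low[seq_len(k)]])
}

#' Correlate ordination axes with codon-usage indices
#'
#' Pearson correlation (and two-sided p) of each retained axis against each
#' index column of the per-gene profile table; the classical readout is a
#' strong positive r between axis 1 and CAI/Fop/C3s when translational
#' selection drives the major trend.
#'
#' @param coa a \code{\link{correspondence_analysis}} result.
#' @param profiles data.frame from \code{\link{usage_profiles}} whose rows
#'   align 1:1 with the CA genes (matched by gene_id).
#' @param indices profile columns to test.
#' @return data.frame with columns axis, index, r, p (r and p \code{NA} for
#'   zero-variance indices).
#' @export
correlate_axes <- function(coa, profiles,
                           indices = c("CAI", "GC3s", "G3s", "C3s",
                                       "A3s", "T3s", "Fop")) {
  ids <- rownames(coa$gene_coords)
  stopifnot(all(ids %in% profiles$gene_id))
  prof <- profiles[match(ids, profiles$gene_id), , drop = FALSE]
  indices <- intersect(indices, names(prof))
  out <- list()
  for (ax in seq_len(ncol(coa$gene_coords))) {
    for (idx in indices) {
      y <- prof[[idx]]
      ok <- is.finite(y)
      r <- p <- NA_real_
      if (sum(ok) >= 3L && stats::sd(y[ok]) > 0 &&
          stats::sd(coa$gene_coords[ok, ax]) > 0) {
        ct <- stats::cor.test(coa$gene_coords[ok, ax], y[ok],
                              method = "pearson")
        r <- unname(ct$estimate)
        p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(axis = ax, index = idx,
                                            r = r, p = p,
                                            stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write CA results as TSV files
#'
#' Writes the gene coordinates, codon coordinates and the per-axis inertia
#' table (axis, inertia percent) to three TSV files.
#'
#' @param coa a \code{\link{correspondence_analysis}} result.
#' @param prefix output path prefix; files are
#'   \code{<prefix>_gene_coords.tsv}, \code{<prefix>_codon_coords.tsv},
#'   \code{<prefix>_inertia.tsv}.
#' @return character vector of the three paths, invisibly.
#' @export
write_coa_tsv <- function(coa, prefix) {
  paths <- paste0(prefix, c("_gene_coords.tsv", "_codon_coords.tsv",
                            "_inertia.tsv"))
  gdf <- data.frame(gene_id = rownames(coa$gene_coords), coa$gene_coords,
                    stringsAsFactors = FALSE)
  utils::write.table(gdf, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cdf <- data.frame(codon = rownames(coa$codon_coords), coa$codon_coords,
                    stringsAsFactors = FALSE)
  utils::write.table(cdf, paths[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  idf <- data.frame(axis = seq_along(coa$inertia_fraction),
                    inertia_percent = round(coa$inertia_fraction, 2),
                    inertia_percent_full = coa$inertia_fraction)
  utils::write.table(idf, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
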