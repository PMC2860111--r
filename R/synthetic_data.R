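#' Default translationally optimal codon set
#'
#' The 22 codons reported as significantly more used in highly expressed
#' \emph{C. glutamicum} genes (14 C-ending, 3 G-ending), used as the default
#' planted optimal set of the simulator so synthetic fixtures echo the
#' biology of a GC-rich actinobacterium.
#'
#' @return character vector of 22 codons (DNA spelling).
#' @export
default_optimal_codons <- function() {
  tab <- cglutamicum_extreme_counts()$table
  rna_to_dna(tab$codon[tab$starred == 1L])
}

#' Specification of a synthetic bacterial genome
#'
#' Parameters of the generative model behind \code{\link{simulate_genome}}:
#' a circular chromosome of protein-coding genes whose synonymous codon
#' choice is driven by a target GC3 (mutational bias) plus an
#' expression-dependent preference for a designated optimal-codon set
#' (translational selection), and whose high-expression genes are placed on
#' the leading strand with elevated probability (replicational selection).
#'
#' @param n_genes number of genes (>= 10).
#' @param min_codons,max_codons gene length range in codons (stop included).
#' @param gc3 target G+C fraction at synonymous third positions under
#'   neutrality (default 0.57, a GC-rich actinobacterial value).
#' @param optimal_codons the planted optimal set (default
#'   \code{\link{default_optimal_codons}}).
#' @param s_expr selection strength: log-scale boost of optimal codons for
#'   the most highly expressed gene (0 = neutral).
#' @param leading_bias probability that a top-quartile-expression gene is
#'   placed on the leading strand (others 0.5).
#' @param frac_ribosomal fraction of genes annotated as ribosomal proteins,
#'   taken from the top of the expression distribution.
#' @param spacer_bp A/T spacer length between consecutive genes.
#' @param meanlog,sdlog log-normal expression parameters.
#' @param seed RNG seed; the same spec is byte-reproducible.
#' @return list of class \code{"synthetic_genome_spec"}.
#' @export
synthetic_genome_spec <- function(n_genes = 500L, min_codons = 200L,
                                  max_codons = 500L, gc3 = 0.57,
                                  optimal_codons = default_optimal_codons(),
                                  s_expr = 1.5, leading_bias = 0.85,
                                  frac_ribosomal = 0.04, spacer_bp = 150L,
                                  meanlog = 0, sdlog = 1, seed = 1L) {
  stopifnot(n_genes >= 10L, min_codons >= 3L, max_codons >= min_codons,
            gc3 >= 0, gc3 <= 1, s_expr >= 0,
            leading_bias >= 0, leading_bias <= 1,
            frac_ribosomal >= 0, frac_ribosomal <= 1, spacer_bp >= 0L)
  optimal_codons <- rna_to_dna(optimal_codons)
  structure(as.list(environment()), class = "synthetic_genome_spec")
}

# per-family baseline codon probabilities hitting the target GC3: within a
# family, GC-ending codons share probability gc3, AT-ending share 1 - gc3
baseline_family_probs <- function(fam, gc3) {
  third <- substr(fam, 3L, 3L)
  is_gc <- third %in% c("G", "C")
  p <- numeric(length(fam))
  if (all(is_gc) || all(!is_gc)) {
    p[] <- 1 / length(fam)
  } else {
    p[is_gc] <- gc3 / sum(is_gc)
    p[!is_gc] <- (1 - gc3) / sum(!is_gc)
  }
  stats::setNames(p, fam)
}

#' Simulate a bacterial genome with planted codon-usage structure
#'
#' Draws gene expression levels from a log-normal, then builds each gene
#' codon by codon: amino acids uniform over the 20, synonymous codons from
#' the family's baseline GC3-driven probabilities multiplied by
#' \code{exp(s_expr * e)} for optimal codons (e the gene's expression rank
#' in [0, 1]) and renormalised. Genes start with ATG, end with TAA, contain
#' no internal stop, and all pass \code{\link{filter_genes}}. Genes are laid
#' end to end with A/T spacers on a circular chromosome with the origin at
#' position 1 and the terminus at half the genome; top-quartile-expression
#' genes go to the leading strand with probability \code{leading_bias},
#' others with probability 0.5.
#'
#' @param spec a \code{\link{synthetic_genome_spec}}.
#' @return list with \code{genome} (string), \code{genes} (list of
#'   \code{\link{gene_record}}), \code{truth} (per-gene data.frame:
#'   gene_id, expression, expr_rank, top_quartile, strand, class,
#'   is_ribosomal), \code{ori}, \code{ter}, \code{spec}.
#' @export
simulate_genome <- function(spec = synthetic_genome_spec()) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  n <- spec$n_genes
  code <- genetic_code()
  fams <- codon_families(code, drop_nondegenerate = FALSE)
  base_p <- lapply(fams, baseline_family_probs, gc3 = spec$gc3)
  aas <- names(fams)

  expression <- stats::rlnorm(n, spec$meanlog, spec$sdlog)
  e <- (rank(expression, ties.method = "first") - 1) / (n - 1)
  top_q <- e >= stats::quantile(e, 0.75)
  n_ribo <- max(1L, round(spec$frac_ribosomal * n))
  ribo <- rank(-expression, ties.method = "first") <= n_ribo

  lens <- sample(spec$min_codons:spec$max_codons, n, replace = TRUE)
  genes_codons <- vector("list", n)
  for (i in seq_len(n)) {
    n_inner <- lens[i] - 2L
    aa_seq <- sample(aas, n_inner, replace = TRUE)
    cods <- character(n_inner)
    for (aa in unique(aa_seq)) {
      fam <- fams[[aa]]
      p <- base_p[[aa]]
      boost <- ifelse(fam %in% spec$optimal_codons,
                      exp(spec$s_expr * e[i]), 1)
      p <- p * boost / sum(p * boost)
      sel <- aa_seq == aa
      cods[sel] <- sample(fam, sum(sel), replace = TRUE, prob = p)
    }
    genes_codons[[i]] <- c("ATG", cods, "TAA")
  }

  # layout: spacer, gene, spacer, gene, ... on a circle; ori = 1,
  # ter = genome midpoint
  gene_bp <- 3L * lens
  genome_length <- sum(gene_bp) + (n + 1L) * spec$spacer_bp
  ter <- genome_length %/% 2L
  ori <- 1L

  genes <- vector("list", n)
  strand <- character(n)
  class <- character(n)
  offset <- spec$spacer_bp
  spacers <- list(random_at(spec$spacer_bp))
  for (i in seq_len(n)) {
    start <- offset + 1L
    end <- offset + gene_bp[i]
    mid <- (start + end) %/% 2L
    on_right <- mid >= ori && mid < ter
    want_leading <- stats::runif(1) < if (top_q[i]) spec$leading_bias else 0.5
    strand[i] <- if (on_right == want_leading) "+" else "-"
    class[i] <- if (want_leading) "leading" else "lagging"
    product <- if (ribo[i]) sprintf("50S ribosomal protein L%d", i)
               else "hypothetical protein"
    genes[[i]] <- gene_record(sprintf("SYN_%04d", i), genes_codons[[i]],
                              strand = strand[i], start = start, end = end,
                              product = product, expression = expression[i])
    spacers[[i + 1L]] <- random_at(spec$spacer_bp)
    offset <- end + spec$spacer_bp
  }
  stopifnot(offset == genome_length)

  pieces <- character(2L * n + 1L)
  pieces[1L] <- spacers[[1L]]
  for (i in seq_len(n)) {
    cds <- paste(genes_codons[[i]], collapse = "")
    pieces[2L * i] <- if (strand[i] == "+") cds else revcomp(cds)
    pieces[2L * i + 1L] <- spacers[[i + 1L]]
  }
  genome <- paste(pieces, collapse = "")

  truth <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    expression = expression, expr_rank = e, top_quartile = top_q,
    strand = strand, class = class, is_ribosomal = ribo,
    stringsAsFactors = FALSE)
  list(genome = genome, genes = genes, truth = truth,
       ori = ori, ter = ter, spec = spec)
}

random_at <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "T"), n, replace = TRUE), collapse = "")
}

# single-nucleotide codon neighbours, split into synonymous and
# nonsynonymous (stop-producing changes excluded from both)
codon_neighbours <- function(code = genetic_code()) {
  key <- paste0("nbr_", code$table_id)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  sense <- names(code$map)[code$map != "*"]
  out <- lapply(stats::setNames(sense, sense), function(cd) {
    ch <- strsplit(cd, "")[[1L]]
    syn <- nonsyn <- character(0)
    for (pos in 1:3) for (b in setdiff(BASES, ch[pos])) {
      alt <- ch; alt[pos] <- b
      alt <- paste(alt, collapse = "")
      if (code$map[[alt]] == "*") next
      if (code$map[[alt]] == code$map[[cd]]) syn <- c(syn, alt)
      else nonsyn <- c(nonsyn, alt)
    }
    list(syn = syn, nonsyn = nonsyn)
  })
  .ng86_cache[[key]] <- out
  out
}

#' Simulate a diverged ortholog of a gene
#'
#' Applies random single-nucleotide codon substitutions to a copy of the
#' gene: the number of synonymous events is Poisson with mean
#' \code{target_ks} times the gene's synonymous site count, the number of
#' nonsynonymous events Poisson with mean \code{omega * target_ks} times the
#' nonsynonymous site count (so omega is the planted Ka/Ks). Events pick a
#' codon in proportion to its currently available changes of that type and
#' never create an internal stop. Multiple hits at one site can occur, which
#' is exactly what the Jukes-Cantor correction of the estimator accounts
#' for. The realised event counts are returned as ground truth.
#'
#' @param gene a \code{\link{gene_record}}.
#' @param target_ks expected synonymous substitutions per synonymous site.
#' @param omega planted Ka/Ks ratio.
#' @param code a \code{\link{genetic_code}}.
#' @param seed RNG seed.
#' @return list with \code{gene} (the diverged \code{gene_record}) and
#'   \code{truth} (list: n_syn_events, n_nonsyn_events, syn_sites,
#'   nonsyn_sites).
#' @export
simulate_ortholog_pair <- function(gene, target_ks, omega = 0.2,
                                   code = genetic_code(), seed = 1L) {
  stopifnot(target_ks >= 0, omega >= 0)
  set.seed(seed)
  cods <- gene$codons
  stop_tail <- character(0)
  if (cods[length(cods)] %in% code$stops) {
    stop_tail <- cods[length(cods)]
    cods <- cods[-length(cods)]
  }
  ssites <- ng86_syn_sites_cached(code)
  S <- sum(ssites[cods])
  N <- 3 * length(cods) - S
  n_syn <- stats::rpois(1L, target_ks * S)
  n_nonsyn <- stats::rpois(1L, omega * target_ks * N)
  nbr <- codon_neighbours(code)
  n_opt <- vapply(nbr, function(x) c(length(x$syn), length(x$nonsyn)),
                  integer(2L))
  events <- sample(c(rep("syn", n_syn), rep("nonsyn", n_nonsyn)))
  for (ev in events) {
    row <- if (ev == "syn") 1L else 2L
    w <- n_opt[row, cods]
    if (all(w == 0)) next  # no available change of this type anywhere
    i <- sample.int(length(cods), 1L, prob = w)
    opts <- nbr[[cods[i]]][[if (ev == "syn") "syn" else "nonsyn"]]
    cods[i] <- opts[sample.int(length(opts), 1L)]
  }
  diverged <- gene_record(paste0(gene$gene_id, "_ortholog"),
                          c(cods, stop_tail), strand = gene$strand,
                          start = gene$start, end = gene$end,
                          product = gene$product, expression = gene$expression)
  list(gene = diverged,
       truth = list(n_syn_events = n_syn, n_nonsyn_events = n_nonsyn,
                    syn_sites = S, nonsyn_sites = N))
}

#' Write a synthetic genome fixture to disk
#'
#' Writes the genome FASTA, the CDS multi-FASTA, the gene table TSV, the
#' ground-truth TSV and a key=value config file recording the spec
#' (including the seed) into one directory.
#'
#' @param sim result of \code{\link{simulate_genome}}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_synthetic_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(sim$genome)
  names(g) <- "synthetic_chromosome"
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fasta"))
  write_cds_fasta(sim$genes, file.path(dir, "cds.fasta"))
  write_gene_table(sim$genes, file.path(dir, "gene_table.tsv"))
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- sim$spec
  cfg <- vapply(names(sp), function(k)
    paste0(k, "=", paste(sp[[k]], collapse = ",")), "")
  writeLines(c(cfg, paste0("ori=", sim$ori), paste0("ter=", sim$ter)),
             file.path(dir, "config.txt"))
  invisible(dir)
}
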