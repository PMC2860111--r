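# Stage orchestration: each run_* function performs one pipeline stage on a
# state list, writes its TSV outputs into outdir, and returns the augmented
# state so stages compose:
#   state <- run_indices("cds.fasta", out)
#   state <- run_coa(state, out)
#   state <- run_optimal(state, out)
#   state <- run_strand(state, genome, out)

#' Stage 1: read, filter and index a CDS set
#'
#' Reads the CDS file, applies the inclusion filters (length, start/stop,
#' no internal stop), computes per-gene usage profiles (CAI referenced on
#' the ribosomal-protein genes) and writes \code{indices.tsv} and
#' \code{gene_table.tsv}.
#'
#' @param cds_path CDS multi-FASTA or GenBank file.
#' @param outdir output directory (created if needed); \code{NULL} skips
#'   writing.
#' @param format \code{"fasta"} or \code{"genbank"}.
#' @param code a \code{\link{genetic_code}}.
#' @param min_codons inclusion threshold (default 100).
#' @return pipeline state: list with genes, tables (codon counts),
#'   profiles, cai_ref, code.
#' @export
run_indices <- function(cds_path, outdir = NULL, format = "fasta",
                        code = genetic_code(), min_codons = 100L) {
  genes <- read_cds(cds_path, format)
  n_read <- length(genes)
  genes <- filter_genes(genes, code, min_codons)
  if (length(genes) == 0L)
    stop("no genes pass the inclusion filters (", n_read, " read)")
  message(sprintf("indices: %d of %d genes pass filters", length(genes),
                  n_read))
  tables <- lapply(genes, count_codons, code = code)
  names(tables) <- vapply(genes, `[[`, "", "gene_id")
  profiles <- usage_profiles(genes, code)
  state <- list(genes = genes, tables = tables, profiles = profiles,
                code = code)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_usage_tsv(profiles, file.path(outdir, "indices.tsv"))
    write_gene_table(genes, file.path(outdir, "gene_table.tsv"))
  }
  state
}

#' Stage 2: correspondence analysis of codon usage
#'
#' Builds the gene x 59-codon matrix, runs CA, orients axis 1 so the
#' ribosomal-protein genes sit at the positive end, correlates the axes with
#' the usage indices, and writes the coordinate/inertia/correlation TSVs.
#'
#' @param state pipeline state from \code{\link{run_indices}}.
#' @param outdir output directory; \code{NULL} skips writing.
#' @param kind CA input: per-gene \code{"rscu"} (default) or raw
#'   \code{"counts"}.
#' @param n_axes axes to retain (default 4).
#' @return state augmented with \code{coa} and \code{axis_correlations}.
#' @export
run_coa <- function(state, outdir = NULL, kind = "rscu", n_axes = 4L) {
  m <- build_usage_matrix(state$tables, state$code, kind)
  coa <- correspondence_analysis(m, n_axes)
  ribo <- state$profiles$is_ribosomal[match(rownames(coa$gene_coords),
                                            state$profiles$gene_id)]
  coa <- orient_axis(coa, ribo, 1L)
  state$coa <- coa
  state$axis_correlations <- correlate_axes(coa, state$profiles)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_coa_tsv(coa, file.path(outdir, "coa"))
    utils::write.table(state$axis_correlations,
                       file.path(outdir, "axis_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  state
}

#' Stage 3: optimal codons from the axis-1 extreme groups
#'
#' Pools the codon counts of the genes at the two extremes of axis 1, calls
#' translationally optimal codons by per-codon chi-square, recomputes Fop
#' against the called set, and writes \code{optimal_codons.tsv} (and updates
#' \code{indices.tsv}).
#'
#' @param state pipeline state from \code{\link{run_coa}}.
#' @param outdir output directory; \code{NULL} skips writing.
#' @param fraction extreme-group fraction per end (default 0.05).
#' @param alpha significance level (default 0.01).
#' @return state augmented with \code{extremes}, \code{optimal} and
#'   Fop-filled \code{profiles}.
#' @export
run_optimal <- function(state, outdir = NULL, fraction = 0.05, alpha = 0.01) {
  if (is.null(state$coa)) stop("run_coa must precede run_optimal")
  ext <- axis_extremes(state$coa, 1L, fraction)
  high <- pool_counts(state$tables[ext$high])
  low <- pool_counts(state$tables[ext$low])
  opt <- call_optimal_codons(high, low, state$code, alpha)
  state$extremes <- ext
  state$optimal <- opt
  state$profiles$Fop <- vapply(state$tables[state$profiles$gene_id],
                               fop, 1, optimal = opt$optimal,
                               code = state$code)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_optimal_tsv(opt, file.path(outdir, "optimal_codons.tsv"))
    write_usage_tsv(state$profiles, file.path(outdir, "indices.tsv"))
  }
  state
}

#' Stage 4: replication strand analysis
#'
#' Builds the replication map (windowed GC skew; ori/ter from cumulative
#' skew unless supplied), classifies every gene as leading/lagging, and
#' tabulates leading-strand fractions by CAI bin with the ribosomal genes
#' as an extra row. Writes \code{skew_track.tsv} and
#' \code{strand_by_cai.tsv}.
#'
#' @param state pipeline state with profiles (Fop/CAI filled).
#' @param genome genome nucleotide string the genes' coordinates refer to.
#' @param outdir output directory; \code{NULL} skips writing.
#' @param window,step GC-skew window and step (bp).
#' @param ori,ter optional known origin/terminus.
#' @param bins interior CAI bin edges (default \code{c(0.35, 0.65)}).
#' @return state augmented with \code{replication} and \code{strand_table}.
#' @export
run_strand <- function(state, genome, outdir = NULL, window = 24000L,
                       step = 3000L, ori = NULL, ter = NULL,
                       bins = c(0.35, 0.65)) {
  rmap <- replication_map(genome, state$genes, window, step, ori, ter)
  leading <- rmap$classes[state$profiles$gene_id] == "leading"
  tab <- leading_fraction_by_cai(
    state$profiles$CAI, leading,
    special = list(Ribosomal = state$profiles$is_ribosomal), bins = bins)
  state$replication <- rmap
  state$strand_table <- tab
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rmap$skew_track, file.path(outdir, "skew_track.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tab, file.path(outdir, "strand_by_cai.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  state
}

#' Stage 5: ortholog divergence
#'
#' Aligns each ortholog pair (global protein alignment, back-translated to
#' codons), estimates Ka/Ks by Nei-Gojobori counting, filters on Ks and
#' correlates divergence with the genome-A expression proxies. Writes
#' \code{orthologs.tsv} and \code{divergence_correlations.tsv}.
#'
#' @param state pipeline state of genome A (profiles carry CAI/Fop).
#' @param genes_b list of \code{\link{gene_record}} of genome B.
#' @param pairs data.frame with columns id_a, id_b (e.g. from
#'   \code{\link{reciprocal_best_hits}}).
#' @param outdir output directory; \code{NULL} skips writing.
#' @param ks_max Ks saturation threshold (default 1.0).
#' @return state augmented with \code{orthologs} and
#'   \code{divergence_correlations}.
#' @export
run_kaks <- function(state, genes_b, pairs, outdir = NULL, ks_max = 1.0) {
  ids_a <- vapply(state$genes, `[[`, "", "gene_id")
  ids_b <- vapply(genes_b, `[[`, "", "gene_id")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- state$genes[[match(pairs$id_a[i], ids_a)]]
    gb <- genes_b[[match(pairs$id_b[i], ids_b)]]
    ortholog_pair(ga, gb, state$code, ks_max)
  })
  res <- do.call(rbind, rows)
  fc <- filter_and_correlate(res, state$profiles, ks_max)
  state$orthologs <- res
  state$divergence_correlations <- fc$correlations
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res, file.path(outdir, "orthologs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fc$correlations,
                       file.path(outdir, "divergence_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  state
}

#' Run the full analysis on a synthetic genome
#'
#' Simulates a genome from a spec, writes the fixture, then runs indices,
#' CA, optimal-codon calling and the strand analysis against the simulator's
#' ground-truth origin/terminus, writing every stage TSV into
#' \code{outdir}. A one-stop smoke entry point and the \code{simulate} +
#' \code{report} subcommands of the CLI script.
#'
#' @param spec a \code{\link{synthetic_genome_spec}}.
#' @param outdir output directory.
#' @param fraction,alpha extreme-group fraction and significance level.
#' @return the final pipeline state (invisibly), including the \code{sim}.
#' @export
run_simulated_pipeline <- function(spec = synthetic_genome_spec(),
                                   outdir = tempfile("codonbias_"),
                                   fraction = 0.05, alpha = 0.01) {
  sim <- simulate_genome(spec)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_synthetic_fixture(sim, file.path(outdir, "fixture"))
  state <- run_indices(file.path(outdir, "fixture", "cds.fasta"), outdir,
                       min_codons = min(100L, spec$min_codons))
  state <- run_coa(state, outdir)
  state <- run_optimal(state, outdir, fraction, alpha)
  # FASTA ingestion assigns synthetic layout coordinates; restore the
  # simulator's true genomic placement before the strand stage
  sim_ids <- vapply(sim$genes, `[[`, "", "gene_id")
  state$genes <- sim$genes[match(names(state$tables), sim_ids)]
  state <- run_strand(state, sim$genome, outdir, ori = sim$ori,
                      ter = sim$ter)
  state$sim <- sim
  invisible(state)
}
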