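# Pipeline orchestration: detect -> support -> filter -> predict ->
# relative coverage. Inputs may be file paths (PSL, SAM/BAM, genePredExt,
# BED, FASTA) or the corresponding in-memory objects; identical inputs and
# configuration give identical outputs.

as_contig_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  setNames(as.character(x), names(x))
}

#' Run the full chimera-detection pipeline
#'
#' @param contigs contig sequences: named character vector, `DNAStringSet`
#'   or FASTA path. Optional (NULL) — gap realignment, the poly(A) filter
#'   and the wild-type post-filter then degrade gracefully.
#' @param contig_alignments list of `ContigAlignment` or PSL path.
#' @param read_to_contig read-to-contig alignments: data.frame from
#'   [read_read_alignments()] or SAM/BAM path.
#' @param gene_models list of `GeneModel` or genePredExt path.
#' @param regions annotation regions data.frame (from
#'   `read_annotations(kind = "bed")`) or NULL.
#' @param wildtype_transcripts wild-type transcript sequences (named
#'   vector, `DNAStringSet` or FASTA path) for the collinear post-filter;
#'   NULL skips it.
#' @param read_to_genome read-to-genome alignments (data.frame or SAM/BAM
#'   path); required when `relcov = TRUE`.
#' @param genome_seqs genome sequences (named vector / `DNAStringSet` /
#'   FASTA) used for inversion gap realignment; optional.
#' @param params an [align_params()].
#' @param config a [filter_config()].
#' @param grouping_tolerance_nt candidate grouping tolerance (default 10).
#' @param boundary_tolerance exon-boundary match tolerance (default 0).
#' @param min_flank read-support flank (default 5).
#' @param read_length read length for relative-coverage regions (default
#'   75).
#' @param relcov compute relative coverage (default: TRUE iff
#'   `read_to_genome` given).
#' @param out_dir optional output directory for `predictions.tsv` and
#'   per-stage intermediates.
#' @return list with `predictions` (list of `EventPrediction`), `table`
#'   (report data.frame), `candidates`, `groups`, `n_contigs`,
#'   `dropped` (per-candidate filter failures).
#' @export
run_pipeline <- function(contigs = NULL, contig_alignments, read_to_contig,
                         gene_models, regions = NULL,
                         wildtype_transcripts = NULL, read_to_genome = NULL,
                         genome_seqs = NULL,
                         params = align_params(), config = filter_config(),
                         grouping_tolerance_nt = 10, boundary_tolerance = 0,
                         min_flank = 5, read_length = 75,
                         relcov = !is.null(read_to_genome),
                         out_dir = NULL) {
  if (relcov && is.null(read_to_genome))
    stop("relative coverage requested but no read-to-genome alignments given")
  if (is.character(contig_alignments))
    contig_alignments <- read_psl(contig_alignments)
  if (is.character(read_to_contig))
    read_to_contig <- read_read_alignments(read_to_contig, "read_to_contig")
  if (!is.null(read_to_genome) && is.character(read_to_genome))
    read_to_genome <- read_read_alignments(read_to_genome, "read_to_genome")
  if (is.character(gene_models) && length(gene_models) == 1L &&
      file.exists(gene_models))
    gene_models <- read_annotations(gene_models, "genepredext")
  if (!is.null(contigs)) contigs <- as_contig_seqs(contigs)
  if (!is.null(wildtype_transcripts))
    wildtype_transcripts <- as_contig_seqs(wildtype_transcripts)
  fetcher <- if (!is.null(genome_seqs))
    make_genome_fetcher(genome_seqs) else NULL

  # --- stage 1.1: per-contig alignment selection and candidate creation
  by_contig <- split(contig_alignments,
                     vapply(contig_alignments, `[[`, "", "contig_id"))
  candidates <- list()
  for (cid in sort(names(by_contig))) {
    alns <- by_contig[[cid]]
    clen <- alns[[1]]$contig_length
    cseq <- if (!is.null(contigs) && cid %in% names(contigs))
      contigs[[cid]] else NULL
    sel <- select_alignment_sets(alns, clen, params)
    realigns <- list()
    if (sel$case == "II" && !is.null(cseq)) {
      gaps <- lapply(sel$gaps, function(g) {
        g$gap_sequence <- substr(cseq, g$start + 1, g$end + 1)
        g
      })
      sel$gaps <- gaps
      realigns <- lapply(gaps, function(g)
        realign_gap(cseq, g, sel$sets[[1]][[1]], fetcher, params))
    }
    candidates <- c(candidates, make_candidates(
      list(id = cid, length = clen, seq = cseq), sel, realigns, params))
  }

  # --- stage 1.2/1.3: grouping and annotation
  groups <- group_candidates(candidates, grouping_tolerance_nt)
  group_counts <- attr(groups, "contig_group_counts")
  annotations <- lapply(candidates, annotate_candidate, gene_models = gene_models,
                        regions = regions,
                        boundary_tolerance = boundary_tolerance)
  names(annotations) <- vapply(candidates, `[[`, "", "id")

  # --- stage 2: read support (event contig set = the candidate's group)
  group_of <- function(cand) {
    for (g in groups) if (cand$id %in%
                          vapply(g$members, `[[`, "", "id")) return(g)
    NULL
  }
  supports <- lapply(candidates, function(cand) {
    g <- group_of(cand)
    read_support(cand, read_to_contig,
                 event_contigs = g$contigs %||% cand$contig_id,
                 min_flank = min_flank)
  })
  names(supports) <- names(annotations)

  # --- stage 3: filtering
  filter_results <- lapply(seq_along(candidates), function(k) {
    cand <- candidates[[k]]
    gc <- if (cand$contig_id %in% names(group_counts))
      as.integer(group_counts[[cand$contig_id]]) else 1L
    apply_filters(cand, annotations[[k]], supports[[k]], config,
                  group_count = gc)
  })
  names(filter_results) <- names(annotations)

  # --- stage 4: one prediction per group (best-supported passing member)
  predictions <- list()
  for (g in groups) {
    ids <- vapply(g$members, `[[`, "", "id")
    passing <- ids[vapply(ids, function(i) filter_results[[i]]$passed,
                          logical(1))]
    if (length(passing) == 0L) next
    best <- passing[which.max(vapply(passing, function(i)
      supports[[i]]$strong_support, integer(1)))]
    cand <- g$members[[match(best, ids)]]
    p <- classify_event(cand, annotations[[best]])
    if (is.null(p)) next
    p$group_id <- g$group_id
    p$support <- supports[[best]]
    p$filter_result <- filter_results[[best]]
    predictions[[length(predictions) + 1L]] <- p
  }
  if (!is.null(wildtype_transcripts) && !is.null(contigs))
    predictions <- wildtype_collinear_filter(predictions,
                                             wildtype_transcripts, contigs)

  # --- stage 5: relative coverage
  if (relcov) {
    predictions <- lapply(predictions, function(p) {
      fl <- flanking_regions(p$candidate, read_length, gene_models)
      pa <- depth_partition(fl$A, p, read_to_genome, q = min_flank)
      pb <- depth_partition(fl$B, p, read_to_genome, q = min_flank)
      p$flanks <- fl
      p$relcov <- relative_coverage(p$support$total_support, pa, pb)
      p
    })
  }

  tab <- predictions_table(predictions)
  dropped <- do.call(rbind, lapply(names(filter_results), function(i) {
    fr <- filter_results[[i]]
    if (fr$passed) return(NULL)
    data.frame(candidate = i,
               failures = paste(fr$failures$id, collapse = ","))
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_predictions(tab, file.path(out_dir, "predictions.tsv"))
    if (!is.null(dropped))
      utils::write.table(dropped, file.path(out_dir, "filtered_out.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(predictions = predictions, table = tab, candidates = candidates,
       groups = groups, annotations = annotations, supports = supports,
       filter_results = filter_results, n_contigs = length(by_contig),
       dropped = dropped)
}
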