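# Stage 4: typing surviving candidates as fusion / PTD / ITD, and the
# wild-type collinear-alignment post-filter.

#' Type a candidate as a fusion, PTD or ITD
#'
#' Fusions come from split-candidates whose alignments overlap only
#' distinct genes and do not overlap each other in the genome; no
#' exon-boundary requirement applies, and whether the transcription
#' direction of the two genes is maintained is reported. PTDs come from
#' split-candidates with duplication or eversion topology whose alignments
#' overlap one gene and whose both breakpoints match annotated exon
#' boundaries (junction contigs over the non-canonical exon junction), and
#' from gap-duplication candidates meeting the same boundary condition
#' (circular isoforms are indistinguishable in poly(A)-selected data and
#' are labeled PTD). ITDs are the same topologies with at least one
#' breakpoint off every annotated exon boundary; for gap candidates the
#' number of inserted bases between the copies is reported.
#'
#' @param candidate a `Candidate` that passed filtering.
#' @param annotation its `CandidateAnnotation`.
#' @return an `EventPrediction` (list with `event_type`, `genes`,
#'   `breakpoints`, `dup_segment`, `inserted_bases`,
#'   `direction_maintained`, `candidate`, `annotation`) or NULL when no
#'   event type applies.
#' @export
classify_event <- function(candidate, annotation) {
  shared <- intersect(annotation$genes_a, annotation$genes_b)
  mk <- function(type, genes, inserted = NA_integer_, dir = NA) {
    structure(list(event_type = type, genes = genes,
                   breakpoints = candidate$breakpoints,
                   dup_segment = candidate$dup_segment,
                   inserted_bases = inserted,
                   direction_maintained = dir,
                   exon_boundary_match = annotation$exon_boundary_match,
                   contig_id = candidate$contig_id,
                   candidate = candidate, annotation = annotation),
              class = "EventPrediction")
  }
  dup_like <- candidate$topology %in% c("duplication", "eversion")
  if (dup_like && length(shared) > 0) {
    if (candidate$kind == "split") {
      return(if (annotation$exon_boundary_match == "both")
        mk("PTD", shared) else mk("ITD", shared))
    }
    if (candidate$topology == "duplication") {
      inserted <- max(0L, as.integer(
        (candidate$gap$end - candidate$gap$start + 1) -
          candidate$aln_b$aligned_length))
      return(if (annotation$exon_boundary_match == "both")
        mk("PTD", shared) else mk("ITD", shared, inserted = inserted))
    }
    return(NULL)
  }
  if (candidate$kind == "split" &&
      length(annotation$genes_a) > 0 && length(annotation$genes_b) > 0 &&
      length(shared) == 0) {
    disjoint <- candidate$chrom_a != candidate$chrom_b || {
      ga <- aln_genome_span(candidate$aln_a)
      gb <- aln_genome_span(candidate$aln_b)
      min(ga[2], gb[2]) <= max(ga[1], gb[1])
    }
    if (disjoint)
      return(mk("fusion", list(a = annotation$genes_a, b = annotation$genes_b),
                dir = annotation$transcription_direction_maintained))
  }
  NULL
}

# does the contig align full-length and collinearly to the transcript?
# a large indel (e.g. a duplicated segment absent from the wild type)
# breaks collinearity even when the flanking match is near-complete
collinear_match <- function(contig_seq, transcript_seq, min_coverage,
                            min_identity, max_indel = 5) {
  # exact containment is the common (and fast) case for clean assemblies
  if (grepl(contig_seq, transcript_seq, fixed = TRUE)) return(TRUE)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(contig_seq),
    subject = Biostrings::DNAString(transcript_seq),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 2)
  nm <- Biostrings::nmatch(pa)
  ident <- 100 * nm / (nm + Biostrings::nmismatch(pa))
  gap_runs <- function(s) {
    r <- rle(strsplit(s, "")[[1]] == "-")
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }
  biggest_indel <- max(gap_runs(as.character(Biostrings::pattern(pa))),
                       gap_runs(as.character(Biostrings::subject(pa))))
  nm / nchar(contig_seq) >= min_coverage && ident >= min_identity &&
    biggest_indel <= max_indel
}

#' Remove predictions explained by a wild-type transcript
#'
#' A prediction is removed iff its contig (or reverse complement) exhibits
#' a full-length collinear alignment to any single wild-type transcript:
#' coverage of at least `min_coverage` of the contig at `min_identity`
#' percent identity in one monotone alignment. With no transcripts the
#' filter is vacuous.
#'
#' @param predictions list of `EventPrediction`.
#' @param transcript_sequences named character vector or `DNAStringSet` of
#'   wild-type transcript sequences (may be empty).
#' @param contig_sequences named character vector or `DNAStringSet` of
#'   contig sequences.
#' @param min_coverage minimum aligned-match fraction of the contig
#'   (default 0.95).
#' @param min_identity minimum percent identity (default 98).
#' @return surviving predictions.
#' @export
wildtype_collinear_filter <- function(predictions, transcript_sequences,
                                      contig_sequences,
                                      min_coverage = 0.95,
                                      min_identity = 98) {
  txs <- setNames(as.character(transcript_sequences),
                  names(transcript_sequences))
  ctgs <- setNames(as.character(contig_sequences), names(contig_sequences))
  if (length(txs) == 0L) return(predictions)
  Filter(function(p) {
    if (!p$contig_id %in% names(ctgs)) return(TRUE)
    cs <- ctgs[[p$contig_id]]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cs)))
    for (t in txs) {
      if (collinear_match(cs, t, min_coverage, min_identity) ||
          collinear_match(rc, t, min_coverage, min_identity)) return(FALSE)
    }
    TRUE
  }, predictions)
}
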