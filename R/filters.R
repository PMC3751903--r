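# Stage 3: the ten-candidate filter screen. All filters are evaluated (no
# short-circuit) so review output lists every violation.

#' Filter configuration with the screen's default thresholds
#'
#' @param max_groups_per_contig fail contigs involved in more than this
#'   many candidate groups (default 3).
#' @param reject_multimapping fail multi-mapping candidates (default TRUE).
#' @param reject_homopolymer fail homopolymer gap events (default TRUE).
#' @param reject_repeat_breakpoints fail breakpoints in annotated repeats
#'   (default FALSE: breakpoints in repeats are allowed).
#' @param reject_struct_rna fail breakpoints in small structural RNA
#'   regions (default TRUE).
#' @param min_percent_identity minimum percent identity of either
#'   alignment (default 99.0).
#' @param min_inclusion minimum fraction of contig positions aligned by
#'   the pair, counting union coverage (default 0.9).
#' @param min_strong_reads minimum strongly supporting reads (default 5).
#' @param max_contig_overlap_nt maximum contig-coordinate overlap of the
#'   alignment pair (default 75 nt, a typical read length).
#' @param reject_polya fail poly(A)-tail misalignment artifacts
#'   (default TRUE).
#' @return list of class `FilterConfig`.
#' @export
filter_config <- function(max_groups_per_contig = 3L,
                          reject_multimapping = TRUE,
                          reject_homopolymer = TRUE,
                          reject_repeat_breakpoints = FALSE,
                          reject_struct_rna = TRUE,
                          min_percent_identity = 99.0,
                          min_inclusion = 0.9,
                          min_strong_reads = 5L,
                          max_contig_overlap_nt = 75L,
                          reject_polya = TRUE) {
  structure(as.list(environment()), class = "FilterConfig")
}

#' Is a candidate a homopolymer gap event?
#'
#' True iff the candidate is a gap-candidate and every base of the
#' realigned portion of its query gap is the same.
#'
#' @param candidate a `Candidate`.
#' @return logical.
#' @export
is_homopolymer_gap <- function(candidate) {
  if (candidate$kind != "gap" || is.null(candidate$gap$aligned_seq))
    return(FALSE)
  s <- toupper(candidate$gap$aligned_seq)
  nchar(s) > 0 && length(unique(strsplit(s, "")[[1]])) == 1L
}

#' Is a candidate a poly(A)-tail misalignment artifact?
#'
#' True iff one alignment of the pair covers only a terminal run: a run of
#' T's at the very beginning of the contig, or a run of A's at the very
#' end. A run qualifies when it is at least `min_run` nt long and at least
#' 90 percent a single base.
#'
#' @param candidate a `Candidate`.
#' @param contig_sequence contig sequence; defaults to the sequence stored
#'   on the candidate.
#' @param min_run minimum run length (default 8).
#' @return logical.
#' @export
is_polya_artifact <- function(candidate, contig_sequence = candidate$contig_seq,
                              min_run = 8L) {
  if (is.null(contig_sequence) || is.na(contig_sequence)) return(FALSE)
  L <- nchar(contig_sequence)
  run_like <- function(span, base) {
    len <- span[2] - span[1]
    if (len < min_run) return(FALSE)
    s <- toupper(substr(contig_sequence, span[1] + 1, span[2]))
    frac <- sum(strsplit(s, "")[[1]] == base) / len
    frac >= 0.9
  }
  for (span in list(candidate$contig_span_a, candidate$contig_span_b)) {
    if (span[1] == 0 && run_like(span, "T")) return(TRUE)
    if (span[2] == L && run_like(span, "A")) return(TRUE)
  }
  FALSE
}

#' Apply the ten candidate filters
#'
#' Evaluates all ten filters and reports every violation: (1) candidate
#' group count of the contig, (2) contig multi-mapping, (3) homopolymer
#' gap, (4) breakpoints in repeats, (5) breakpoints in structural RNAs,
#' (6) alignment percent identity, (7) contig inclusion, (8) strong read
#' support, (9) contig-coordinate alignment overlap, (10) poly(A)
#' artifact.
#'
#' @param candidate a `Candidate`.
#' @param annotation its `CandidateAnnotation` (or NULL: annotation-driven
#'   filters 4 and 5 then pass).
#' @param support its `ReadSupport` (required).
#' @param config a [filter_config()].
#' @param group_count number of candidate groups involving the candidate's
#'   contig (default 1).
#' @return list of class `FilterResult` with `passed` and `failures`
#'   (data.frame of `id`, `reason`).
#' @export
apply_filters <- function(candidate, annotation, support,
                          config = filter_config(), group_count = 1L) {
  if (is.null(support)) stop("read support missing for candidate")
  fails <- list()
  fail <- function(id, reason) fails[[length(fails) + 1L]] <<-
    data.frame(id = id, reason = reason)
  if (group_count > config$max_groups_per_contig)
    fail(1L, sprintf("contig in %d groups (max %d)", group_count,
                     config$max_groups_per_contig))
  if (config$reject_multimapping && isTRUE(candidate$multimapping))
    fail(2L, "multi-mapping candidate")
  if (config$reject_homopolymer && is_homopolymer_gap(candidate))
    fail(3L, "homopolymer gap event")
  if (config$reject_repeat_breakpoints && !is.null(annotation) &&
      isTRUE(annotation$repeat_overlap))
    fail(4L, "breakpoint in repeat region")
  if (config$reject_struct_rna && !is.null(annotation) &&
      isTRUE(annotation$struct_rna_overlap))
    fail(5L, "breakpoint in structural RNA region")
  min_ident <- min(candidate$identity_a, candidate$identity_b)
  if (min_ident < config$min_percent_identity)
    fail(6L, sprintf("alignment identity %.1f%% < %.1f%%", min_ident,
                     config$min_percent_identity))
  if (candidate$inclusion < config$min_inclusion)
    fail(7L, sprintf("inclusion %.3f < %.2f", candidate$inclusion,
                     config$min_inclusion))
  if (support$strong_support < config$min_strong_reads)
    fail(8L, sprintf("%d strong reads < %d", support$strong_support,
                     config$min_strong_reads))
  if (candidate$contig_overlap_nt > config$max_contig_overlap_nt)
    fail(9L, sprintf("%d nt alignment overlap > %d nt",
                     candidate$contig_overlap_nt,
                     config$max_contig_overlap_nt))
  if (config$reject_polya && is_polya_artifact(candidate))
    fail(10L, "poly(A) tail misalignment artifact")
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(id = integer(0), reason = character(0))
  structure(list(passed = nrow(failures) == 0L, failures = failures),
            class = "FilterResult")
}
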