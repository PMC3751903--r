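# Stage 2: breakpoint search regions on the contig and read-to-contig
# support, with strong/weak scoring of reads that map to several contigs.

#' Breakpoint search region of a candidate
#'
#' For split candidates the region spans the contig-coordinate overlap of
#' the two alignments, extended by 1 nt on each side (for abutting
#' alignments this leaves the two junction-flanking bases). For
#' gap-duplication candidates it is the region between the two copies of
#' the duplicated sequence; for gap-inversion candidates, the gap extended
#' by 1 nt.
#'
#' @param candidate a `Candidate`.
#' @return numeric `c(start, end)`, a 0-based half-open contig interval.
#' @export
breakpoint_region <- function(candidate) {
  L <- candidate$contig_length
  clamp <- function(p) c(max(0, p[1]), min(L, p[2]))
  if (candidate$kind == "split") {
    o1 <- max(candidate$contig_span_a[1], candidate$contig_span_b[1])
    o2 <- min(candidate$contig_span_a[2], candidate$contig_span_b[2])
    if (o2 >= o1) return(clamp(c(o1 - 1, o2 + 1)))
    return(clamp(c(o2 - 1, o1 + 1)))  # unaligned junction between the pieces
  }
  i <- candidate$gap$start; j <- candidate$gap$end
  if (candidate$topology == "duplication") {
    # existing copy vs the realigned portion of the gap (the second copy;
    # inserted bases between the copies are part of the region)
    ts <- candidate$contig_span_b[1]; te <- candidate$contig_span_b[2]
    off <- candidate$aln_b$gap_offset %||% 0
    cb1 <- i + off
    cb2 <- cb1 + (candidate$aln_b$aligned_length %||% (j - i + 1))
    p <- if (te <= cb1) c(te, cb1) else c(cb2, ts)
    if (p[2] <= p[1]) p <- c(p[1] - 1, p[1] + 1)  # adjacent copies
    return(clamp(p))
  }
  clamp(c(i - 1, j + 2))
}

#' Score a read against an event's contig set
#'
#' For a read mapping to contig set `C(r)` and an event represented by
#' contig set `E`, `score = |C(r) \intersect E| / |C(r)|`; the read
#' strongly supports the event iff score >= 0.5.
#'
#' @param read_contigs character vector: contigs the read maps to
#'   (non-empty).
#' @param event_contigs character vector: contigs grouped into the event.
#' @return list with `score` and `strong`.
#' @export
support_score <- function(read_contigs, event_contigs) {
  if (length(read_contigs) == 0L) stop("read maps to no contig")
  score <- length(intersect(read_contigs, event_contigs)) /
    length(unique(read_contigs))
  list(score = score, strong = score >= 0.5)
}

#' Read support of a candidate breakpoint
#'
#' At each position p of the breakpoint search region, `R(p)` counts
#' mismatch-free reads (NM = 0 and a single match-run CIGAR) overlapping p
#' by at least `min_flank` nt on each side. The reported total support is
#' `min_p R(p)`, which guarantees that wherever the true breakpoint lies in
#' the region, at least that many read alignments span it. Strong support
#' additionally requires each counted read to strongly support the event
#' under [support_score()].
#'
#' @param candidate a `Candidate`.
#' @param read_alignments data.frame from
#'   `read_read_alignments(mode = "read_to_contig")` covering all contigs
#'   (used both for support counting and for each read's mapped-contig set).
#' @param event_contigs contigs representing the same event (defaults to
#'   the candidate's contig).
#' @param min_flank minimum overlap on each side of a position (default 5).
#' @return list of class `ReadSupport` with `region_P`, `total_support`,
#'   `strong_support`, `min_flank`.
#' @export
read_support <- function(candidate, read_alignments,
                         event_contigs = candidate$contig_id,
                         min_flank = 5) {
  P <- breakpoint_region(candidate)
  if (P[2] <= P[1]) stop("empty breakpoint search region")
  reads <- read_alignments[read_alignments$target_id == candidate$contig_id &
                             !read_alignments$has_mismatch, , drop = FALSE]
  positions <- seq.int(P[1], P[2] - 1)
  depth <- vapply(positions, function(p) {
    sum(p - reads$target_start >= min_flank - 1 &
          reads$target_end - p >= min_flank)
  }, numeric(1))
  total <- if (length(depth)) min(depth) else 0
  p_star <- positions[which.min(depth)]
  at_min <- reads[p_star - reads$target_start >= min_flank - 1 &
                    reads$target_end - p_star >= min_flank, , drop = FALSE]
  strong <- 0L
  if (nrow(at_min) > 0) {
    contig_sets <- split(read_alignments$target_id, read_alignments$read_id)
    strong <- sum(vapply(at_min$read_id, function(r) {
      support_score(unique(contig_sets[[r]]), event_contigs)$strong
    }, logical(1)))
  }
  structure(list(region_P = P, total_support = as.integer(total),
                 strong_support = as.integer(strong),
                 min_flank = min_flank),
            class = "ReadSupport")
}
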