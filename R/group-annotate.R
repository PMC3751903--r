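# Candidate grouping (meta-assemblies give several contigs per event) and
# annotation against gene models and region tracks.

# canonical orientation signature: sides ordered by (chrom, pos); when the
# sort swaps the sides, both strands are complemented, so that a contig and
# its reverse complement produce identical signatures.
candidate_signature <- function(cand) {
  bp <- cand$breakpoints
  key <- order(bp$chrom, bp$pos)
  flip <- !identical(key, 1:2)
  strands <- bp$strand[key]
  if (flip) strands <- ifelse(strands == "+", "-", "+")
  list(chroms = bp$chrom[key], pos = bp$pos[key], strands = strands,
       sig = paste(bp$chrom[key][1], bp$chrom[key][2],
                   strands[1], strands[2], sep = "|"))
}

#' Group candidates representing one event
#'
#' Single-linkage clustering: two candidates join one group iff they share
#' the chromosome pair and orientation signature and both (canonically
#' ordered) breakpoints lie within `tolerance_nt` of each other.
#'
#' @param candidates list of `Candidate` objects.
#' @param tolerance_nt breakpoint distance tolerance (default 10).
#' @return list of groups; each group is a list with `group_id`, `members`
#'   (candidates), `contigs` (member contig ids), `breakpoints`
#'   (representative, from the first member) and `signature`. The result
#'   carries a `contig_group_counts` attribute: a named count of groups per
#'   contig (used by the group-count filter).
#' @export
group_candidates <- function(candidates, tolerance_nt = 10) {
  n <- length(candidates)
  if (n == 0L) {
    out <- list()
    attr(out, "contig_group_counts") <- integer(0)
    return(out)
  }
  sigs <- lapply(candidates, candidate_signature)
  joined <- function(i, j) {
    a <- sigs[[i]]; b <- sigs[[j]]
    a$sig == b$sig &&
      all(abs(a$pos - b$pos) <= tolerance_nt)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (joined(i, j)) parent[find(j)] <- find(i)
  roots <- vapply(seq_len(n), find, integer(1))
  idx <- split(seq_len(n), match(roots, unique(roots)))
  out <- lapply(seq_along(idx), function(k) {
    members <- candidates[idx[[k]]]
    list(group_id = sprintf("group%04d", k),
         members = members,
         contigs = unique(vapply(members, `[[`, "", "contig_id")),
         breakpoints = members[[1]]$breakpoints,
         signature = sigs[[idx[[k]][1]]]$sig)
  })
  contigs <- unlist(lapply(out, `[[`, "contigs"))
  attr(out, "contig_group_counts") <- table(contigs)
  out
}

# gene ids whose exons intersect any of the given genome blocks
genes_overlapping_blocks <- function(gene_models, chrom, blocks) {
  hits <- vapply(gene_models, function(g) {
    if (g$chrom != chrom) return(FALSE)
    for (k in seq_len(nrow(blocks))) {
      if (any(pmin(g$exons[, "end"], blocks[k, 2]) >
              pmax(g$exons[, "start"], blocks[k, 1]))) return(TRUE)
    }
    FALSE
  }, logical(1))
  unique(vapply(gene_models[hits], `[[`, "", "gene_id"))
}

#' Annotate a candidate against gene models and region tracks
#'
#' Assigns genes overlapping each breakpoint side (a gene overlaps a side
#' if any exon of any of its transcripts intersects any alignment block of
#' that side), determines whether each genomic breakpoint matches an
#' annotated exon boundary (first or last base of any exon, within
#' `boundary_tolerance`), and flags overlap of the breakpoints with repeat,
#' segmental-duplication and structural-RNA regions.
#'
#' @param candidate a `Candidate`.
#' @param gene_models list of `GeneModel` records.
#' @param regions optional data.frame from
#'   `read_annotations(kind = "bed")` (columns `chrom`, `start`, `end`,
#'   `class`), or NULL.
#' @param boundary_tolerance exon-boundary match tolerance in nt
#'   (default 0 = exact).
#' @return list of class `CandidateAnnotation` with fields `genes_a`,
#'   `genes_b`, `boundary_match_a`, `boundary_match_b`,
#'   `exon_boundary_match` (`"both"`, `"one"`, `"neither"`),
#'   `repeat_overlap`, `segdup_overlap`, `struct_rna_overlap`,
#'   `transcription_direction_maintained`.
#' @export
annotate_candidate <- function(candidate, gene_models, regions = NULL,
                               boundary_tolerance = 0) {
  genes_a <- genes_overlapping_blocks(gene_models, candidate$chrom_a,
                                      candidate$genome_blocks_a)
  genes_b <- genes_overlapping_blocks(gene_models, candidate$chrom_b,
                                      candidate$genome_blocks_b)
  bp_matches <- vapply(1:2, function(k) {
    chrom <- candidate$breakpoints$chrom[k]
    pos <- candidate$breakpoints$pos[k]
    for (g in gene_models) {
      if (g$chrom != chrom) next
      if (any(abs(gene_exon_boundaries(g) - pos) <= boundary_tolerance))
        return(TRUE)
    }
    FALSE
  }, logical(1))
  ebm <- c("neither", "one", "both")[sum(bp_matches) + 1L]
  region_hit <- function(cls) {
    if (is.null(regions) || nrow(regions) == 0L) return(FALSE)
    r <- regions[regions$class == cls, , drop = FALSE]
    if (nrow(r) == 0L) return(FALSE)
    any(vapply(1:2, function(k) {
      any(r$chrom == candidate$breakpoints$chrom[k] &
            r$start <= candidate$breakpoints$pos[k] &
            r$end > candidate$breakpoints$pos[k])
    }, logical(1)))
  }
  dir_maintained <- NA
  if (length(genes_a) > 0 && length(genes_b) > 0) {
    gm_by_id <- function(id) Filter(function(g) g$gene_id == id, gene_models)[[1]]
    ga <- gm_by_id(genes_a[1]); gb <- gm_by_id(genes_b[1])
    dir_maintained <- (candidate$strand_a == ga$strand) ==
      (candidate$strand_b == gb$strand)
  }
  structure(list(
    genes_a = genes_a, genes_b = genes_b,
    boundary_match_a = bp_matches[1], boundary_match_b = bp_matches[2],
    exon_boundary_match = ebm,
    repeat_overlap = region_hit("repeat"),
    segdup_overlap = region_hit("segmental_duplication"),
    struct_rna_overlap = region_hit("struct_rna"),
    transcription_direction_maintained = dir_maintained),
    class = "CandidateAnnotation")
}
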