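# Stage 1: alignment-set selection over contig-to-genome alignments,
# query-gap discovery and realignment, topology labeling, and creation of
# gap-/split-candidates.
#
# A contig's alignments are grouped transitively by pairwise contig-coordinate
# overlap; one representative (at most) is taken per group so that the chosen
# subset maximizes score = quality + inclusion - overlap - size. Four cases
# follow from the chosen subset: a clean single alignment (non-chimeric), a
# single gapped alignment (gap-candidate), a pair (split-candidate), or 3+
# alignments (left uncharacterized).

#' Parameters for alignment selection and candidate creation
#'
#' @param case1_inclusion_min single-alignment inclusion above which a
#'   gap-free contig is called non-chimeric and skipped (default 0.95).
#' @param overlap_group_min pairwise contig-overlap fraction above which two
#'   alignments fall in one group (default 0.10).
#' @param multimap_quality_window alignments within this quality of their
#'   group's best are kept and flagged multi-mapping (default 0.05).
#' @param min_gap_length minimum query-gap length (nt) considered (default
#'   4, the smallest duplication unit worth realigning).
#' @param gap_quality_min,gap_inclusion_min thresholds a single gapped
#'   alignment must meet before its gaps are realigned (default 0.9 each).
#' @param split_inclusion_min minimum joint inclusion of a pair of
#'   alignments for a split-candidate (default 0.9).
#' @param realign_min_fraction,realign_min_identity success criteria for a
#'   gap realignment: aligned fraction of the gap (default 0.9) and percent
#'   identity (default 95).
#' @param polya_min_run minimum terminal A/T run length for the poly(A)
#'   artifact check (default 8 nt at >= 90 percent A or T).
#' @param mito_names chromosome names treated as mitochondrial.
#' @param drop_mito drop candidates touching mitochondrial sequence
#'   (default TRUE).
#' @return list of parameters, class `align_params`.
#' @export
align_params <- function(case1_inclusion_min = 0.95,
                         overlap_group_min = 0.10,
                         multimap_quality_window = 0.05,
                         min_gap_length = 4L,
                         gap_quality_min = 0.9,
                         gap_inclusion_min = 0.9,
                         split_inclusion_min = 0.9,
                         realign_min_fraction = 0.9,
                         realign_min_identity = 95,
                         polya_min_run = 8L,
                         mito_names = c("chrM", "chrMT", "MT", "M"),
                         drop_mito = TRUE) {
  structure(as.list(environment()), class = "align_params")
}

#' Metrics of a set of alignments of one contig
#'
#' `inclusion` is the fraction of contig positions covered by at least one
#' alignment block, `overlap` the fraction covered by more than one,
#' `quality` the sum of member qualities, `size` the member count, and
#' `score = quality + inclusion - overlap - size`.
#'
#' @param alignments non-empty list of `ContigAlignment` records of one
#'   contig.
#' @param contig_length contig length in nt.
#' @return list with `quality`, `inclusion`, `overlap`, `size`, `score`.
#' @export
alignment_set_metrics <- function(alignments, contig_length) {
  if (length(alignments) == 0L)
    stop("alignment set metrics are undefined for an empty set")
  cov <- integer(contig_length)
  for (a in alignments) {
    p <- aln_contig_positions(a) + 1L
    cov[p] <- cov[p] + 1L
  }
  quality <- sum(vapply(alignments, `[[`, numeric(1), "quality"))
  inclusion <- sum(cov >= 1L) / contig_length
  overlap <- sum(cov >= 2L) / contig_length
  size <- length(alignments)
  list(quality = quality, inclusion = inclusion, overlap = overlap,
       size = size, score = quality + inclusion - overlap - size)
}

#' Find query gaps of one alignment
#'
#' A query gap is a maximal run of contig positions not aligned by any
#' block, including runs at either contig edge.
#'
#' @param alignment a `ContigAlignment`.
#' @param contig_length contig length.
#' @param contig_seq optional contig sequence (character); when given, each
#'   gap carries its sequence.
#' @return list of gaps, each a list with `contig_id`, `start`, `end`
#'   (0-based, inclusive) and `gap_sequence` (or NA).
#' @export
find_query_gaps <- function(alignment, contig_length, contig_seq = NULL) {
  covered <- logical(contig_length)
  covered[aln_contig_positions(alignment) + 1L] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) {
      i <- starts[k] - 1L; j <- ends[k] - 1L
      out[[length(out) + 1L]] <- list(
        contig_id = alignment$contig_id, start = i, end = j,
        gap_sequence = if (!is.null(contig_seq))
          substr(contig_seq, i + 1L, j + 1L) else NA_character_)
    }
  }
  out
}

# transitive grouping of alignments by pairwise contig-overlap fraction
overlap_groups <- function(alignments, contig_length, threshold) {
  n <- length(alignments)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pos <- lapply(alignments, aln_contig_positions)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ov <- length(intersect(pos[[i]], pos[[j]])) / contig_length
      if (ov > threshold) parent[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), match(roots, unique(roots)))
}

#' Select the alignment subset(s) best explaining a contig
#'
#' If a single gap-free alignment already covers more than
#' `case1_inclusion_min` of the contig, the contig is non-chimeric (Case I).
#' Otherwise alignments are grouped transitively by pairwise overlap, and a
#' subset taking at most one member per group is chosen to maximize
#' `score = quality + inclusion - overlap - size`. Within a group, members
#' whose quality is within `multimap_quality_window` of the group's best are
#' flagged multi-mapping, and substituting them yields alternate sets.
#'
#' @param alignments non-empty list of `ContigAlignment` records of one
#'   contig.
#' @param contig_length contig length.
#' @param params an [align_params()] object.
#' @return list with `case` (`"I"`, `"II"`, `"III"`, `"IV"`), `sets` (list
#'   of alignment subsets, primary first; empty for Case I), `multimapping`
#'   (logical per set), `groups` (member indices per overlap group), and
#'   `gaps` (query gaps of the single Case II alignment).
#' @export
select_alignment_sets <- function(alignments, contig_length,
                                  params = align_params()) {
  stopifnot(length(alignments) >= 1)
  gap_len <- function(a) {
    g <- find_query_gaps(a, contig_length)
    if (length(g) == 0L) 0L else max(vapply(g, function(x) x$end - x$start + 1L,
                                            integer(1)))
  }
  # Case I shortcut: a gap-free high-inclusion single alignment
  for (a in alignments) {
    inc <- alignment_set_metrics(list(a), contig_length)$inclusion
    if (inc > params$case1_inclusion_min && gap_len(a) < params$min_gap_length)
      return(list(case = "I", sets = list(), multimapping = logical(0),
                  groups = NULL, gaps = list()))
  }
  groups <- overlap_groups(alignments, contig_length, params$overlap_group_min)
  # exact score maximization over at-most-one-member-per-group subsets
  choices <- lapply(groups, function(idx) c(NA_integer_, idx))
  n_combo <- prod(lengths(choices))
  pick_best <- function() {
    if (n_combo <= 4096) {
      grid <- do.call(expand.grid, c(choices, KEEP.OUT.ATTRS = FALSE))
      best <- NULL; best_score <- -Inf; best_quality <- -Inf
      for (r in seq_len(nrow(grid))) {
        idx <- stats::na.omit(as.integer(grid[r, ]))
        if (length(idx) == 0L) next
        m <- alignment_set_metrics(alignments[idx], contig_length)
        if (m$score > best_score + 1e-12 ||
            (abs(m$score - best_score) <= 1e-12 && m$quality > best_quality)) {
          best <- idx; best_score <- m$score; best_quality <- m$quality
        }
      }
      best
    } else {
      vapply(groups, function(idx) {
        idx[which.max(vapply(alignments[idx], `[[`, numeric(1), "quality"))]
      }, integer(1))
    }
  }
  primary <- sort(pick_best())
  # multi-mapping: other same-group members within the quality window
  alts <- lapply(primary, function(i) {
    grp <- groups[[which(vapply(groups, function(g) i %in% g, logical(1)))]]
    q <- vapply(alignments[grp], `[[`, numeric(1), "quality")
    setdiff(grp[q >= max(q) - params$multimap_quality_window], i)
  })
  multimapped <- any(lengths(alts) > 0L)
  sets <- list(alignments[primary])
  for (slot in seq_along(primary)) {
    for (alt in alts[[slot]]) {
      v <- primary; v[slot] <- alt
      sets[[length(sets) + 1L]] <- alignments[sort(v)]
    }
  }
  gaps <- list()
  case <- if (length(primary) == 1L) {
    g <- find_query_gaps(alignments[[primary]], contig_length)
    g <- Filter(function(x) x$end - x$start + 1L >= params$min_gap_length, g)
    if (length(g) > 0L) { gaps <- g; "II" } else "I"
  } else if (length(primary) == 2L) "III" else "IV"
  if (case == "I")
    return(list(case = "I", sets = list(), multimapping = logical(0),
                groups = groups, gaps = list()))
  list(case = case, sets = sets,
       multimapping = rep(multimapped, length(sets)),
       groups = groups, gaps = gaps)
}

#' Classify the topology of an ordered alignment pair
#'
#' The two alignments must belong to one contig and be ordered by contig
#' coordinate. Labels: `interchromosomal` (different chromosomes),
#' `inversion` (same chromosome, different strands), `duplication` (same
#' chromosome and strand, overlapping genomic intervals), `eversion` (same
#' chromosome and strand, genomic block order reversed relative to contig
#' order), and `read_through` (same chromosome and strand, collinear order,
#' disjoint intervals).
#'
#' @param aln_a,aln_b `ContigAlignment` records ordered by contig
#'   coordinate.
#' @return topology label (character).
#' @export
classify_topology <- function(aln_a, aln_b) {
  if (aln_a$chrom != aln_b$chrom) return("interchromosomal")
  if (aln_a$strand != aln_b$strand) return("inversion")
  ga <- aln_genome_span(aln_a); gb <- aln_genome_span(aln_b)
  if (min(ga[2], gb[2]) > max(ga[1], gb[1])) return("duplication")
  in_order <- if (aln_a$strand == "+") ga[2] <= gb[1] else gb[2] <= ga[1]
  if (in_order) "read_through" else "eversion"
}

#' Build a genome fetcher from sequences
#'
#' @param sequences named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @return `function(chrom, start, end)` returning the 0-based half-open
#'   subsequence as a character string.
#' @export
make_genome_fetcher <- function(sequences) {
  seqs <- setNames(as.character(sequences), names(sequences))
  function(chrom, start, end) {
    if (!chrom %in% names(seqs)) stop("unknown chromosome: ", chrom)
    substr(seqs[[chrom]], start + 1, end)
  }
}

# Core of a local alignment after edge trimming: any non-match column
# within `edge` columns of either end is trimmed through, so chance
# extension over a few inserted/mutated bases at the alignment boundary
# does not dilute identity (ITDs often carry short inserts between the
# copies).
sw_core <- function(pa, edge = 6L) {
  p <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  m <- p == s & p != "-" & s != "-"
  lo <- 1L; hi <- length(m)
  repeat {
    w <- lo:min(lo + edge - 1L, hi)
    bad <- w[!m[w]]
    if (length(bad) == 0L || max(bad) + 1L > hi) break
    lo <- max(bad) + 1L
  }
  repeat {
    w <- max(lo, hi - edge + 1L):hi
    bad <- w[!m[w]]
    if (length(bad) == 0L || min(bad) - 1L < lo) break
    hi <- min(bad) - 1L
  }
  if (hi < lo) return(NULL)
  core <- lo:hi
  aligned_pairs <- sum(p[core] != "-" & s[core] != "-")
  list(nmatch = sum(m[core]),
       aligned_pairs = aligned_pairs,
       pat_len = sum(p[core] != "-"),
       pat_core = paste(p[core][p[core] != "-"], collapse = ""),
       pat_off = sum(p[seq_len(lo - 1L)] != "-"),
       subj_off = sum(s[seq_len(lo - 1L)] != "-"),
       subj_len = sum(s[core] != "-"))
}

sw_align <- function(query, subject) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(subject),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 1)
}

#' Attempt to realign a query gap
#'
#' Two local (Smith-Waterman, match +1 / mismatch -1 / gap open -2 / gap
#' extend -1) realignments explain a query gap: (1) against the contig with
#' the gap masked out, detecting tandem duplications; (2) for internal gaps
#' only, against the genomic window between the gap-flanking bases' genomic
#' mates (both orientations), detecting inversions. A realignment succeeds
#' when it covers at least `realign_min_fraction` of the gap at
#' `realign_min_identity` percent identity. When both succeed the
#' duplication is kept (the shorter explanatory distance) and the conflict
#' recorded.
#'
#' @param contig_seq full contig sequence (character).
#' @param gap a gap from [find_query_gaps()].
#' @param host_alignment the gapped `ContigAlignment`.
#' @param genome_fetcher from [make_genome_fetcher()]; may be NULL to skip
#'   the inversion attempt.
#' @param params an [align_params()] object.
#' @return a `GapRealignment` (list with `kind`, `target_interval`,
#'   `target_chrom`, `identity`, `aligned_fraction`, `gap_aligned_seq`,
#'   `conflict`) or NULL if neither attempt succeeds.
#' @export
realign_gap <- function(contig_seq, gap, host_alignment, genome_fetcher = NULL,
                        params = align_params()) {
  L <- nchar(contig_seq)
  i <- gap$start; j <- gap$end
  if (i < 0 || j >= L || i > j) stop("gap coordinates outside contig")
  gap_seq <- substr(contig_seq, i + 1, j + 1)
  gap_len <- j - i + 1
  eval_aln <- function(aln) {
    if (is.na(Biostrings::score(aln)) || Biostrings::score(aln) <= 0)
      return(NULL)
    core <- sw_core(aln)
    if (is.null(core) || core$aligned_pairs == 0L) return(NULL)
    frac <- core$pat_len / gap_len
    ident <- 100 * core$nmatch / core$aligned_pairs
    if (frac >= params$realign_min_fraction - 1e-9 &&
        ident >= params$realign_min_identity)
      list(frac = frac, ident = ident, aln = aln, core = core) else NULL
  }
  # attempt 1: duplication, against the gap-masked contig
  masked <- paste0(substr(contig_seq, 1, i), substr(contig_seq, j + 2, L))
  dup <- NULL
  if (nchar(masked) > 0) {
    res <- eval_aln(sw_align(gap_seq, masked))
    if (!is.null(res)) {
      s <- IRanges::start(Biostrings::subject(res$aln)) - 1 + res$core$subj_off
      e <- s + res$core$subj_len
      # map masked-contig coordinates back onto the original contig
      map_back <- function(x) if (x >= i) x + gap_len else x
      dup <- structure(list(
        kind = "duplication",
        target_chrom = NA_character_,
        target_interval = c(map_back(s), map_back(e - 1) + 1),
        identity = res$ident, aligned_fraction = res$frac,
        aligned_length = res$core$pat_len,
        gap_offset = res$core$pat_off,
        gap_aligned_seq = res$core$pat_core,
        conflict = FALSE), class = "GapRealignment")
    }
  }
  # attempt 2: inversion, against the flanked genomic window
  inv <- NULL
  if (!is.null(genome_fetcher) && i > 0 && j < L - 1) {
    gi <- aln_genome_mate(host_alignment, i - 1)
    gj <- aln_genome_mate(host_alignment, j + 1)
    if (!is.na(gi) && !is.na(gj)) {
      win <- genome_fetcher(host_alignment$chrom, min(gi, gj), max(gi, gj) + 1)
      win_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
      for (ori in c(win_rc, win)) {
        res <- eval_aln(sw_align(gap_seq, ori))
        if (!is.null(res)) {
          s0 <- IRanges::start(Biostrings::subject(res$aln)) - 1 +
            res$core$subj_off
          e0 <- s0 + res$core$subj_len
          base <- min(gi, gj)
          intv <- if (identical(ori, win_rc)) {
            wlen <- nchar(win)
            c(base + wlen - e0, base + wlen - s0)
          } else c(base + s0, base + e0)
          inv <- structure(list(
            kind = "inversion",
            target_chrom = host_alignment$chrom,
            target_interval = intv,
            identity = res$ident, aligned_fraction = res$frac,
            aligned_length = res$core$pat_len,
            gap_offset = res$core$pat_off,
            gap_aligned_seq = res$core$pat_core,
            conflict = FALSE), class = "GapRealignment")
          break
        }
      }
    }
  }
  if (!is.null(dup)) {
    dup$conflict <- !is.null(inv)
    dup
  } else inv
}
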