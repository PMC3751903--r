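# Stage 5: chimeric vs wild-type relative coverage from read-to-genome
# alignments. Two genomic flank regions (A and B) are built from the
# candidate's alignment blocks on each side of the breakpoint, each cut or
# extended to two read lengths of transcript; per-position depth in each
# region is partitioned into wild-type-only (DW), shared-single-copy (T1)
# and duplicated (T2) reads.

# keep `budget` nt of a junction-first block sequence; cut far ends,
# optionally extend along a gene model's transcript structure
build_flank <- function(label, chrom, blocks_jf, keep_high, budget,
                        gene_models) {
  kept <- NULL
  rem <- budget
  for (k in seq_len(nrow(blocks_jf))) {
    if (rem <= 0) break
    b <- blocks_jf[k, ]
    len <- b[2] - b[1]
    if (len <= rem) {
      kept <- rbind(kept, b)
      rem <- rem - len
    } else {
      kept <- rbind(kept, if (keep_high) c(b[2] - rem, b[2])
                    else c(b[1], b[1] + rem))
      rem <- 0
    }
  }
  # extend along annotated transcript structure, away from the junction
  if (rem > 0 && !is.null(gene_models) && !is.null(kept)) {
    far <- if (keep_high) kept[nrow(kept), 1] else kept[nrow(kept), 2] - 1
    gm <- NULL
    for (g in gene_models) {
      if (g$chrom == chrom &&
          any(g$exons[, "start"] <= far & g$exons[, "end"] > far)) {
        gm <- g; break
      }
    }
    if (!is.null(gm)) {
      ex <- gm$exons
      k <- which(ex[, "start"] <= far & ex[, "end"] > far)
      # room left inside the containing exon
      if (keep_high) {
        room <- far - ex[k, "start"]
        take <- min(room, rem)
        if (take > 0) { kept <- rbind(kept, c(far - take, far)); rem <- rem - take }
        ks <- rev(seq_len(k - 1))
      } else {
        room <- ex[k, "end"] - far - 1
        take <- min(room, rem)
        if (take > 0) { kept <- rbind(kept, c(far + 1, far + 1 + take)); rem <- rem - take }
        ks <- seq_len(nrow(ex))[-seq_len(k)]
      }
      for (kk in ks) {
        if (rem <= 0) break
        len <- ex[kk, "end"] - ex[kk, "start"]
        take <- min(len, rem)
        kept <- rbind(kept, if (keep_high) c(ex[kk, "end"] - take, ex[kk, "end"])
                      else c(ex[kk, "start"], ex[kk, "start"] + take))
        rem <- rem - take
      }
    }
  }
  kept <- matrix(kept, ncol = 2, dimnames = list(NULL, c("start", "end")))
  structure(list(label = label, chrom = chrom, blocks = kept,
                 total_length = sum(kept[, 2] - kept[, 1]),
                 truncated = rem > 0),
            class = "FlankRegion")
}

#' Breakpoint-flanking genomic regions of an event
#'
#' Builds regions A and B from the alignment blocks on each side of the
#' breakpoint, cut from the far end or extended along the annotated
#' transcript structure so that each region totals `2 * read_length` nt of
#' transcript adjacent to the breakpoint. A region that cannot reach the
#' target length (e.g. a terminal exon with no neighbor) is truncated and
#' flagged.
#'
#' @param candidate a `Candidate`.
#' @param read_length read length in nt.
#' @param gene_models optional gene models used for extension.
#' @return list with elements `A` and `B` of class `FlankRegion` (`label`,
#'   `chrom`, junction-first `blocks`, `total_length`, `truncated`).
#' @export
flanking_regions <- function(candidate, read_length, gene_models = NULL) {
  budget <- 2 * read_length
  if (candidate$kind == "split") {
    blocks_a <- candidate$genome_blocks_a
    blocks_b <- candidate$genome_blocks_b
    # junction-first ordering: side A's junction is at the contig-end of
    # its piece, side B's at the contig-start
    jf_a <- blocks_a[rev(seq_len(nrow(blocks_a))), , drop = FALSE]
    jf_b <- blocks_b
    keep_high_a <- candidate$strand_a == "+"
    keep_high_b <- candidate$strand_b == "-"
  } else {
    # gap duplication: A ends at the duplicated segment's end, B starts at
    # its start (the NCEJ joins segment end back to segment start)
    seg <- candidate$dup_segment
    host <- candidate$genome_blocks_a
    clip <- function(lo, hi) {
      b <- cbind(pmax(host[, 1], lo), pmin(host[, 2], hi))
      b[b[, 2] > b[, 1], , drop = FALSE]
    }
    jf_a <- clip(-Inf, seg$end)
    jf_a <- jf_a[rev(seq_len(nrow(jf_a))), , drop = FALSE]
    jf_b <- clip(seg$start, Inf)
    keep_high_a <- candidate$strand_a == "+"
    keep_high_b <- candidate$strand_a == "-"
  }
  list(A = build_flank("A", candidate$chrom_a, jf_a, keep_high_a, budget,
                       gene_models),
       B = build_flank("B", candidate$chrom_b, jf_b, keep_high_b, budget,
                       gene_models))
}

#' Partition read depth in a flank region
#'
#' At each region position s, reads overlapping s by at least `q` aligned
#' bases on each side are counted into exactly one of: `DW` (reads spanning
#' a wild-type junction or adjacency that the chimeric structure destroys —
#' for fusions, reads whose alignment continues across the breakpoint),
#' `T2` (positions inside the duplicated genomic segment of a PTD/ITD), or
#' `T1` (all other qualifying reads). Fusion events have no T2 positions;
#' duplication events have no identifiable DW reads (an intact genome
#' alignment is compatible with both structures there).
#'
#' @param region a `FlankRegion`.
#' @param event an `EventPrediction`.
#' @param read_to_genome data.frame from
#'   `read_read_alignments(mode = "read_to_genome")`.
#' @param q minimum overlap on each side of a position (default 5).
#' @return data.frame of class `DepthPartition` with columns `pos`, `DW`,
#'   `T1`, `T2`, `T` (`T = DW + T1 + T2`).
#' @export
depth_partition <- function(region, event, read_to_genome, q = 5) {
  pos <- unlist(lapply(seq_len(nrow(region$blocks)), function(k)
    seq.int(region$blocks[k, 1], region$blocks[k, 2] - 1)))
  pos <- sort(unique(pos))
  DW <- T1 <- T2 <- setNames(numeric(length(pos)), pos)
  is_dup <- event$event_type %in% c("PTD", "ITD")
  seg <- event$dup_segment
  in_seg <- if (is_dup && !is.null(seg) && seg$chrom == region$chrom)
    pos >= seg$start & pos < seg$end else rep(FALSE, length(pos))
  bp <- event$breakpoints$pos[match(region$label, c("A", "B"))]
  bp_chrom <- event$breakpoints$chrom[match(region$label, c("A", "B"))]
  lo <- min(pos); hi <- max(pos) + 1
  rows <- which(read_to_genome$target_id == region$chrom &
                  read_to_genome$target_end > lo &
                  read_to_genome$target_start < hi)
  for (r in rows) {
    bl <- read_to_genome$blocks[[r]]
    aligned <- unlist(lapply(seq_len(nrow(bl)), function(k)
      seq.int(bl[k, 1], bl[k, 2] - 1)))
    n <- length(aligned)
    if (n < 2 * q - 1) next
    qualifying <- aligned[q:(n - q + 1)]
    idx <- match(qualifying, pos)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    is_dw <- !is_dup && region$chrom == bp_chrom &&
      sum(aligned <= bp) >= q && sum(aligned > bp) >= q
    if (is_dw) {
      DW[idx] <- DW[idx] + 1
    } else {
      T2[idx[in_seg[idx]]] <- T2[idx[in_seg[idx]]] + 1
      T1[idx[!in_seg[idx]]] <- T1[idx[!in_seg[idx]]] + 1
    }
  }
  out <- data.frame(pos = pos, DW = unname(DW), T1 = unname(T1),
                    T2 = unname(T2), T = unname(DW + T1 + T2))
  class(out) <- c("DepthPartition", class(out))
  out
}

#' Relative coverage of a chimeric transcript
#'
#' Per position, the wild-type depth is estimated as
#' `W(r,s) = DW(r,s) + I1 * (T1(r,s) - C) + I2 * (T2(r,s) - 2C)` where `Ij`
#' indicates `Tj(r,s) > 0`, under the assumption that each duplication
#' involves a single extra copy. `W(r)` is the per-region maximum of
#' `W(r,s)`, `T(r)` the maximum total depth among positions attaining
#' `W(r)`; `W(*)` and `T(*)` average the two regions. Seven depth values
#' and the six ratios `C/W(r)`, `C/T(r)` for r in {A, B, *} are reported.
#' Negative intermediate `W(r,s)` values are clamped at 0 and flagged; a
#' non-positive `W(r)` yields an infinite ratio sentinel rather than an
#' error.
#'
#' @param C chimeric breakpoint depth: the event's read-to-contig support.
#' @param partition_a,partition_b `DepthPartition` for regions A and B.
#' @return list of class `RelativeCoverage` with `C`, `W_A`, `T_A`, `W_B`,
#'   `T_B`, `W_star`, `T_star`, `ratios` (named: `C_W_A`, `C_T_A`,
#'   `C_W_B`, `C_T_B`, `C_W_star`, `C_T_star`) and `clamped`.
#' @export
relative_coverage <- function(C, partition_a, partition_b) {
  clamped <- FALSE
  region_stats <- function(p) {
    W <- p$DW + (p$T1 > 0) * (p$T1 - C) + (p$T2 > 0) * (p$T2 - 2 * C)
    if (any(W < 0)) { clamped <<- TRUE; W <- pmax(W, 0) }
    Wr <- max(W)
    Tr <- max(p$T[W == Wr])
    c(W = Wr, T = Tr)
  }
  a <- region_stats(partition_a)
  b <- region_stats(partition_b)
  W_star <- (a["W"] + b["W"]) / 2
  T_star <- (a["T"] + b["T"]) / 2
  ratio <- function(den) { den <- unname(den); if (den > 0) C / den else Inf }
  structure(list(
    C = C,
    W_A = unname(a["W"]), T_A = unname(a["T"]),
    W_B = unname(b["W"]), T_B = unname(b["T"]),
    W_star = unname(W_star), T_star = unname(T_star),
    ratios = c(C_W_A = ratio(a["W"]), C_T_A = ratio(a["T"]),
               C_W_B = ratio(b["W"]), C_T_B = ratio(b["T"]),
               C_W_star = ratio(W_star), C_T_star = ratio(T_star)),
    clamped = clamped), class = "RelativeCoverage")
}
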