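# PSL (BLAT 21-column) reading/writing and the ContigAlignment container.
#
# PSL minus-strand records give query block starts in reverse-complement
# query coordinates; these are flipped to forward-contig coordinates at
# parse time so that all downstream logic sees one convention.

#' Construct a contig-to-genome alignment record
#'
#' @param contig_id contig name.
#' @param contig_length contig length in nt.
#' @param chrom target sequence name.
#' @param strand `"+"` or `"-"`: strand of the genome the (forward) contig
#'   aligns to.
#' @param blocks numeric matrix with columns `contig_start`, `genome_start`,
#'   `length` (0-based half-open). For minus-strand alignments the i-th
#'   contig base of a block pairs with the i-th genome base counted from the
#'   block's genomic end.
#' @param matches,mismatches aligned base counts; `matches` defaults to the
#'   total block length minus `mismatches`.
#' @return object of class `ContigAlignment`. `quality` is
#'   `(matches - mismatches) / (matches + mismatches)` clamped to \[0,1\] —
#'   a normalized per-alignment score, monotone in both the aligner score
#'   and percent identity and independent of how much of the contig the
#'   alignment covers (coverage is captured separately by set inclusion);
#'   `percent_identity` is `100 * matches / (matches + mismatches)`.
#' @export
contig_alignment <- function(contig_id, contig_length, chrom, strand, blocks,
                             matches = NULL, mismatches = 0L) {
  blocks <- matrix(as.numeric(blocks), ncol = 3,
                   dimnames = list(NULL, c("contig_start", "genome_start", "length")))
  blocks <- blocks[order(blocks[, "contig_start"]), , drop = FALSE]
  total <- sum(blocks[, "length"])
  if (is.null(matches)) matches <- total - mismatches
  stopifnot(strand %in% c("+", "-"),
            matches + mismatches == total,
            contig_length > 0)
  cs <- blocks[, "contig_start"]
  if (nrow(blocks) > 1 &&
      any(cs[-1] < (cs + blocks[, "length"])[-nrow(blocks)]))
    stop("block contig intervals overlap within one alignment")
  structure(list(
    contig_id = contig_id,
    contig_length = as.integer(contig_length),
    chrom = chrom,
    strand = strand,
    blocks = blocks,
    matches = as.integer(matches),
    mismatches = as.integer(mismatches),
    quality = if (total > 0) clamp01((matches - mismatches) / total) else 0,
    percent_identity = if (total > 0) 100 * matches / total else 0
  ), class = "ContigAlignment")
}

#' @export
print.ContigAlignment <- function(x, ...) {
  cat(sprintf("<ContigAlignment> %s (%d nt) -> %s:%s, %d block(s), q=%.3f, id=%.1f%%\n",
              x$contig_id, x$contig_length, x$chrom, x$strand,
              nrow(x$blocks), x$quality, x$percent_identity))
  invisible(x)
}

# 0-based contig positions covered by the alignment
aln_contig_positions <- function(aln) {
  runs_positions(aln$blocks[, "contig_start"], aln$blocks[, "length"])
}

# contig-coordinate span [start, end)
aln_contig_span <- function(aln) {
  n <- nrow(aln$blocks)
  c(aln$blocks[1, "contig_start"],
    aln$blocks[n, "contig_start"] + aln$blocks[n, "length"])
}

# genome-coordinate span [start, end)
aln_genome_span <- function(aln) {
  c(min(aln$blocks[, "genome_start"]),
    max(aln$blocks[, "genome_start"] + aln$blocks[, "length"]))
}

# genomic mate (0-based) of a covered contig position; NA if uncovered
aln_genome_mate <- function(aln, pos) {
  for (k in seq_len(nrow(aln$blocks))) {
    b <- aln$blocks[k, ]
    if (pos >= b["contig_start"] && pos < b["contig_start"] + b["length"]) {
      off <- pos - b["contig_start"]
      return(unname(if (aln$strand == "+") b["genome_start"] + off
                    else b["genome_start"] + b["length"] - 1 - off))
    }
  }
  NA_real_
}

# genomic coordinate paired with the junction-side contig edge.
# side = "left" means this alignment covers the 5' (contig-first) piece, so
# the junction edge is its highest contig position; "right" the lowest.
aln_junction_breakpoint <- function(aln, side = c("left", "right")) {
  side <- match.arg(side)
  span <- aln_contig_span(aln)
  pos <- if (side == "left") span[2] - 1 else span[1]
  aln_genome_mate(aln, pos)
}

#' Read contig-to-genome alignments from a PSL file
#'
#' Accepts both headered (`psLayout`) and headerless PSL; columns beyond the
#' 21 standard ones are ignored. Minus-strand query coordinates are
#' normalized to forward-contig coordinates.
#'
#' @param path PSL file path.
#' @return list of [contig_alignment()] records.
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # skip header block: any line whose first field is not an integer
  is_data <- vapply(lines, function(l) {
    grepl("^[0-9]+\t", l) || grepl("^[0-9]+ ", l)
  }, logical(1))
  out <- vector("list", sum(is_data))
  n <- 0L
  for (idx in which(is_data)) {
    f <- strsplit(lines[[idx]], "[\t ]+")[[1]]
    if (length(f) < 21)
      stop(sprintf("PSL parse error at line %d: %d columns (21 required)",
                   idx, length(f)))
    matches <- as.integer(f[1]); mism <- as.integer(f[2])
    rep_m <- as.integer(f[3]); n_count <- as.integer(f[4])
    strand <- substr(f[9], 1, 1)
    q_name <- f[10]; q_size <- as.integer(f[11])
    t_name <- f[14]
    n_blocks <- as.integer(f[18])
    sizes <- as.integer(strsplit(f[19], ",")[[1]])
    q_starts <- as.integer(strsplit(f[20], ",")[[1]])
    t_starts <- as.integer(strsplit(f[21], ",")[[1]])
    if (length(sizes) != n_blocks || length(q_starts) != n_blocks ||
        length(t_starts) != n_blocks)
      stop(sprintf("PSL parse error at line %d: blockCount %d disagrees with block lists",
                   idx, n_blocks))
    if (strand == "-") q_starts <- q_size - (q_starts + sizes)
    n <- n + 1L
    out[[n]] <- contig_alignment(
      contig_id = q_name, contig_length = q_size, chrom = t_name,
      strand = strand, blocks = cbind(q_starts, t_starts, sizes),
      matches = matches + rep_m, mismatches = mism + n_count)
  }
  out[seq_len(n)]
}

#' Write contig-to-genome alignments to a PSL file
#'
#' Inverse of [read_psl()] on its output: a written record re-reads to an
#' identical `ContigAlignment`.
#'
#' @param alignments list of `ContigAlignment` records.
#' @param path output path.
#' @param genome_sizes optional named vector of target sequence lengths
#'   (tSize column); defaults to each alignment's genomic end.
#' @export
write_psl <- function(alignments, path, genome_sizes = NULL) {
  rows <- vapply(alignments, function(a) {
    b <- a$blocks
    q_starts <- b[, "contig_start"]
    sizes <- b[, "length"]
    t_starts <- b[, "genome_start"]
    if (a$strand == "-") {
      # PSL stores minus-strand query blocks in reverse-complement query
      # coordinates, ordered by target position
      ord <- rev(seq_len(nrow(b)))
      q_starts <- (a$contig_length - (q_starts + sizes))[ord]
      sizes <- sizes[ord]
      t_starts <- t_starts[ord]
    }
    t_size <- if (!is.null(genome_sizes) && a$chrom %in% names(genome_sizes))
      genome_sizes[[a$chrom]] else max(t_starts + sizes)
    q_span <- aln_contig_span(a)
    paste(
      a$matches, a$mismatches, 0L, 0L, 0L, 0L, 0L, 0L, a$strand,
      a$contig_id, a$contig_length, q_span[1], q_span[2],
      a$chrom, t_size, min(t_starts), max(t_starts + sizes),
      length(sizes),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(q_starts, collapse = ","), ","),
      paste0(paste(t_starts, collapse = ","), ","),
      sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
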