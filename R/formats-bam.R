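# Read alignment (SAM/BAM) input and a minimal SAM writer for synthetic
# fixtures. SAM and BAM are accepted interchangeably; SAM keeps fixtures
# human-readable and is converted on the fly.

cigar_ref_width <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(gsub("[A-Z=]", "", toks))
  ops <- gsub("[0-9]+", "", toks)
  sum(lens[ops %in% c("M", "D", "N", "=", "X")])
}

# reference-coordinate aligned blocks (0-based half-open) of a CIGAR at pos
cigar_ref_blocks <- function(cigar, pos) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(gsub("[A-Z=]", "", toks))
  ops <- gsub("[0-9]+", "", toks)
  blocks <- NULL
  cur_start <- pos
  cur <- pos
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      cur <- cur + lens[k]
    } else if (op %in% c("D", "N")) {
      if (cur > cur_start) blocks <- rbind(blocks, c(cur_start, cur))
      cur <- cur + lens[k]
      cur_start <- cur
    }
    # I, S, H, P consume no reference
  }
  if (cur > cur_start) blocks <- rbind(blocks, c(cur_start, cur))
  if (is.null(blocks)) blocks <- matrix(numeric(0), ncol = 2)
  colnames(blocks) <- c("start", "end")
  blocks
}

#' Read read alignments from SAM or BAM
#'
#' @param path SAM or BAM file (extension decides; SAM is converted via
#'   [Rsamtools::asBam()]).
#' @param mode `"read_to_contig"` or `"read_to_genome"`; the mode is
#'   recorded on the result and `read_to_genome` keeps spliced block
#'   structure.
#' @param region optional `"chrom:start-end"` (1-based inclusive) region
#'   restriction; requires an indexed BAM.
#' @return data.frame with one row per mapped alignment record: `read_id`,
#'   `target_id`, `target_start`, `target_end` (0-based half-open, span on
#'   the target), `has_mismatch`, `perfect` (NM = 0 and a single match-run
#'   CIGAR), `mate` (1/2/NA) and a `blocks` list-column of
#'   reference-coordinate aligned blocks. Unmapped records are skipped.
#' @export
read_read_alignments <- function(path, mode = c("read_to_contig", "read_to_genome"),
                                 region = NULL) {
  mode <- match.arg(mode)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = TRUE)
  }
  what <- c("qname", "flag", "rname", "pos", "cigar")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, tag = "NM")
  } else {
    m <- regmatches(region, regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("region must be 'chrom:start-end'")
    if (!file.exists(paste0(path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", path)))
      stop("region queries require an indexed BAM")
    gr <- GenomicRanges::GRanges(m[2], IRanges::IRanges(as.integer(m[3]),
                                                        as.integer(m[4])))
    Rsamtools::ScanBamParam(what = what, tag = "NM", which = gr)
  }
  res <- Rsamtools::scanBam(path, param = param)
  recs <- do.call(rbind, lapply(res, function(x) {
    data.frame(read_id = x$qname, flag = x$flag,
               target_id = as.character(x$rname), pos = x$pos,
               cigar = x$cigar,
               nm = x$tag$NM %||% rep(NA_integer_, length(x$qname)))
  }))
  if (is.null(recs) || nrow(recs) == 0L) {
    out <- data.frame(read_id = character(), target_id = character(),
                      target_start = numeric(), target_end = numeric(),
                      has_mismatch = logical(), perfect = logical(),
                      mate = integer())
    out$blocks <- list()
    attr(out, "mode") <- mode
    return(out)
  }
  mapped <- !bitwAnd(recs$flag, 4L)
  recs <- recs[mapped & !is.na(recs$pos), , drop = FALSE]
  recs <- unique(recs)  # region queries can return duplicates at overlaps
  start0 <- recs$pos - 1
  widths <- vapply(recs$cigar, cigar_ref_width, numeric(1), USE.NAMES = FALSE)
  nm <- ifelse(is.na(recs$nm), 0L, recs$nm)
  single_run <- grepl("^[0-9]+M$", recs$cigar)
  out <- data.frame(
    read_id = recs$read_id,
    target_id = recs$target_id,
    target_start = start0,
    target_end = start0 + widths,
    has_mismatch = nm > 0L | grepl("[IDSHX]", recs$cigar),
    perfect = nm == 0L & single_run,
    mate = ifelse(bitwAnd(recs$flag, 64L) > 0L, 1L,
                  ifelse(bitwAnd(recs$flag, 128L) > 0L, 2L, NA_integer_)))
  out$blocks <- if (mode == "read_to_genome") {
    mapply(cigar_ref_blocks, recs$cigar, start0, SIMPLIFY = FALSE)
  } else {
    mapply(function(s, e) matrix(c(s, e), ncol = 2,
                                 dimnames = list(NULL, c("start", "end"))),
           start0, start0 + widths, SIMPLIFY = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Write alignment records as SAM
#'
#' Minimal SAM emitter used for synthetic fixtures.
#'
#' @param records data.frame with columns `read_id`, `target_id`, `pos`
#'   (0-based), `cigar`, `seq`, and optionally `flag`, `nm`, `mate`.
#' @param target_lengths named integer vector of reference lengths for the
#'   header.
#' @param path output `.sam` path.
#' @export
write_sam <- function(records, target_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(target_lengths),
                   as.integer(target_lengths)))
  if (nrow(records) > 0) {
    ord <- order(match(records$target_id, names(target_lengths)), records$pos)
    records <- records[ord, , drop = FALSE]
    flag <- records$flag %||% rep(0L, nrow(records))
    if (!is.null(records$mate))
      flag <- flag + ifelse(is.na(records$mate), 0L,
                            1L + 32L + ifelse(records$mate == 1L, 64L, 128L))
    nm <- records$nm %||% rep(0L, nrow(records))
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                    records$read_id, as.integer(flag), records$target_id,
                    as.integer(records$pos) + 1L, records$cigar,
                    records$seq, as.integer(nm))
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
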