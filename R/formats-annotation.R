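# Gene models (UCSC genePredExt) and annotation regions (BED4+).

#' Construct a gene model
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom,strand genomic location.
#' @param exons numeric matrix with columns `start`, `end`
#'   (0-based half-open), sorted and non-overlapping.
#' @return object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  stopifnot(nrow(exons) >= 1, all(exons[, "end"] > exons[, "start"]),
            strand %in% c("+", "-"))
  if (nrow(exons) > 1 && any(exons[-1, "start"] < exons[-nrow(exons), "end"]))
    stop("gene model exons overlap")
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("<GeneModel> %s/%s %s:%s, %d exon(s) [%d,%d)\n",
              x$gene_id, x$transcript_id, x$chrom, x$strand, nrow(x$exons),
              as.integer(x$exons[1, 1]),
              as.integer(x$exons[nrow(x$exons), 2])))
  invisible(x)
}

# spliced transcript length
gene_model_length <- function(gm) sum(gm$exons[, "end"] - gm$exons[, "start"])

# all exon boundary genomic positions (first and last base of each exon)
gene_exon_boundaries <- function(gm) {
  sort(unique(c(gm$exons[, "start"], gm$exons[, "end"] - 1)))
}

#' Read gene models or annotation regions
#'
#' @param path input file.
#' @param kind `"genepredext"` for UCSC genePredExt gene models (an optional
#'   leading bin column is tolerated), or `"bed"` for BED4+ regions.
#' @param class region class assigned to BED records: one of `"repeat"`,
#'   `"segmental_duplication"`, `"struct_rna"`.
#' @return for `"genepredext"`, a list of [gene_model()] records; for
#'   `"bed"`, a data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `class` (0-based half-open).
#' @export
read_annotations <- function(path, kind = c("genepredext", "bed"),
                             class = "repeat") {
  kind <- match.arg(kind)
  if (kind == "bed") {
    class <- match.arg(class, c("repeat", "segmental_duplication", "struct_rna"))
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
    if (length(lines) == 0L)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), name = character(),
                        class = character()))
    f <- strsplit(lines, "[\t ]+")
    data.frame(
      chrom = vapply(f, `[`, "", 1),
      start = as.numeric(vapply(f, `[`, "", 2)),
      end = as.numeric(vapply(f, `[`, "", 3)),
      name = vapply(f, function(x) if (length(x) >= 4) x[4] else ".", ""),
      class = class)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !grepl("^#", lines)]
    lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[[i]], "\t")[[1]]
      if (!f[3] %in% c("+", "-") && length(f) >= 4 && f[4] %in% c("+", "-"))
        f <- f[-1]  # leading bin column
      if (length(f) < 12)
        stop(sprintf("genePredExt parse error at line %d: %d columns", i,
                     length(f)))
      n_exons <- as.integer(f[8])
      starts <- as.numeric(strsplit(f[9], ",")[[1]])
      ends <- as.numeric(strsplit(f[10], ",")[[1]])
      if (length(starts) != n_exons || length(ends) != n_exons)
        stop(sprintf("genePredExt parse error at line %d: exonCount %d disagrees with exonStarts/exonEnds",
                     i, n_exons))
      gene_model(gene_id = f[12], transcript_id = f[1], chrom = f[2],
                 strand = f[3], exons = cbind(starts, ends))
    })
  }
}

#' Write gene models as genePredExt
#'
#' @param gene_models list of `GeneModel` records.
#' @param path output path.
#' @export
write_genepredext <- function(gene_models, path) {
  rows <- vapply(gene_models, function(g) {
    s <- g$exons[, "start"]; e <- g$exons[, "end"]
    paste(g$transcript_id, g$chrom, g$strand, min(s), max(e), min(s), max(e),
          nrow(g$exons),
          paste0(paste(s, collapse = ","), ","),
          paste0(paste(e, collapse = ","), ","),
          0, g$gene_id, "none", "none",
          paste0(paste(rep(-1, nrow(g$exons)), collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
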