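#' Read gene annotations from GFF3 or BED
#'
#' Gene intervals are returned as a [GenomicRanges::GRanges] (1-based
#' closed, the Bioconductor convention) with a `gene_id` metadata column.
#' GFF3 coordinates are 1-based closed on file, BED coordinates 0-based
#' half-open; both are converted at the file boundary. For GFF3, features
#' of type `gene` are kept when a `type` column is present, otherwise all
#' features are taken as genes.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return `GRanges` with unique `gene_id`s.
#' @seealso [writeGenes()] for the inverse; round-tripping restores the
#'   original file coordinates exactly.
#' @export
readGenes <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
    format <- switch(ext,
      gff = , gff3 = "gff3",
      bed = "bed",
      stop(sprintf("cannot infer coordinate dialect from extension '.%s'; pass format=", ext),
           call. = FALSE))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop(sprintf("malformed %s file %s: %s",
                                     format, path, conditionMessage(e)),
                             call. = FALSE))
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
  } else {
    ids <- S4Vectors::mcols(gr)$name
  }
  if (is.null(ids) || anyNA(ids)) ids <- paste0("gene", seq_along(gr))
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                               IRanges::ranges(gr),
                               strand = BiocGenerics::strand(gr))
  S4Vectors::mcols(gr)$gene_id <- as.character(ids)
  if (anyDuplicated(gr$gene_id))
    stop("gene ids are not unique within the annotation", call. = FALSE)
  gr
}

#' Write gene annotations to GFF3 or BED
#'
#' The exact inverse of [readGenes()]: GFF3 is written 1-based closed, BED
#' 0-based half-open, so read-then-write restores the original integers.
#'
#' @param genes `GRanges` with a `gene_id` metadata column.
#' @param path output file.
#' @param format `"gff3"` or `"bed"`.
#' @export
writeGenes <- function(genes, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  chrom <- as.character(GenomicRanges::seqnames(genes))
  strand <- as.character(BiocGenerics::strand(genes))
  strand[strand == "*"] <- "."
  ids <- genes$gene_id
  if (is.null(ids)) ids <- paste0("gene", seq_along(genes))
  if (format == "gff3") {
    lines <- c("##gff-version 3",
               sprintf("%s\tcontamScreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       chrom, IRanges::start(genes), IRanges::end(genes),
                       strand, ids))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     chrom, IRanges::start(genes) - 1L, IRanges::end(genes),
                     ids, strand)
  }
  writeLines(lines, path)
  invisible(path)
}
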