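#' Write an evaluation report as a TSV bundle
#'
#' Emits one TSV per report section with fixed column order:
#' `purity.tsv` (cluster, n_contigs, n_reads, dominant_species,
#' purity_contig, purity_read, tier), `concentration.tsv` (cluster,
#' ts_contigs, concentration_contig, ts_reads, concentration_read),
#' `dichotomy.tsv`, `coverage.tsv` (metric/value pairs), `data_loss.tsv`
#' and `ledger.tsv`. Percentage columns are written with one decimal.
#'
#' @param report an [EvaluationReport-class].
#' @param out_dir directory (created if absent).
#' @return invisibly, the paths written.
#' @seealso [readReportTables()]
#' @export
writeReportTables <- function(report, out_dir) {
  stopifnot(is(report, "EvaluationReport"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)

  fmt_pct <- function(df, cols) {
    for (cc in intersect(cols, names(df)))
      df[[cc]] <- ifelse(is.na(df[[cc]]), "NA", sprintf("%.1f", df[[cc]]))
    df
  }
  wr <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  pct_cols <- c("purity_contig", "purity_read", "concentration_contig",
                "concentration_read", "value", "marginal_total",
                "cumulative_total", "marginal_target", "cumulative_target")
  paths <- c(
    wr(fmt_pct(report@purity, pct_cols), "purity.tsv"),
    wr(fmt_pct(report@concentration, pct_cols), "concentration.tsv"),
    wr(fmt_pct(data.frame(metric = names(report@dichotomy),
                          value = unname(report@dichotomy)), pct_cols),
       "dichotomy.tsv"),
    wr(local({
      df <- data.frame(metric = names(report@coverage),
                       value = unname(report@coverage))
      pct <- grepl("_coverage$", df$metric)
      df$value <- ifelse(pct, sprintf("%.1f", df$value),
                         format(df$value, trim = TRUE))
      df
    }), "coverage.tsv"),
    wr(fmt_pct(report@dataLoss, pct_cols), "data_loss.tsv"),
    wr(report@ledger, "ledger.tsv"))
  invisible(paths)
}

#' Read back a report TSV bundle
#'
#' @param out_dir directory written by [writeReportTables()].
#' @return named list of data.frames (one per table found).
#' @export
readReportTables <- function(out_dir) {
  files <- c("purity", "concentration", "dichotomy", "coverage",
             "data_loss", "ledger")
  out <- list()
  for (f in files) {
    p <- file.path(out_dir, paste0(f, ".tsv"))
    if (file.exists(p))
      out[[f]] <- utils::read.delim(p, stringsAsFactors = FALSE)
  }
  out
}
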