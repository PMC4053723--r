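probe_table_cols <- c("probe_id", "gene", "chrom", "pos", "sample_id",
                      "sex", "sample_set", "informative", "intensity",
                      "frac_cdna", "frac_gdna", "channel")

#' Read a tab-separated probe table
#'
#' One row per probe measurement per sample: probe id, gene id (empty for
#' autosomal background probes), chromosome, 0-based position, sample id,
#' sex, sample-set label, informativity flag (heterozygous), total cDNA
#' intensity, allele-1 cDNA fraction, allele-1 genomic-DNA fraction, and a
#' channel tag (`"expression"` or `"chip:<mark>"`). Fractions must lie in
#' `[0, 1]`; violations are reported with their row numbers.
#'
#' @param path File path (TSV with header; `#`-prefixed comment lines are
#'   skipped).
#' @return Validated tibble.
#' @export
read_probe_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           probe_id = "c", gene = "c", chrom = "c",
                           pos = "i", sample_id = "c", sex = "c",
                           sample_set = "c", informative = "l",
                           intensity = "d", frac_cdna = "d",
                           frac_gdna = "d", channel = "c"))
  missing <- setdiff(probe_table_cols, names(tab))
  if (length(missing) > 0) {
    stop("probe table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_probe_table(tab, path)
  tab[, probe_table_cols]
}

validate_probe_table <- function(tab, label = "probe table") {
  for (col in c("frac_cdna", "frac_gdna")) {
    bad <- which(!is.na(tab[[col]]) & (tab[[col]] < 0 | tab[[col]] > 1))
    if (length(bad) > 0) {
      stop(label, ": ", col, " out of [0, 1] at row ", bad[1],
           " (value ", tab[[col]][bad[1]], ")", call. = FALSE)
    }
  }
  bad <- which(!is.na(tab$intensity) & tab$intensity < 0)
  if (length(bad) > 0) {
    stop(label, ": negative intensity at row ", bad[1], call. = FALSE)
  }
  dup <- duplicated(tab[, c("probe_id", "sample_id", "channel")])
  if (any(dup)) {
    stop(label, ": duplicate (probe, sample, channel) at row ",
         which(dup)[1], call. = FALSE)
  }
  invisible(tab)
}

#' Write a probe table
#'
#' @param tab Probe table tibble.
#' @param path Output path.
#' @param comment Optional character vector written as `#` header lines
#'   (e.g. config hash and seed).
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(tab, path, comment = NULL) {
  write_tsv_commented(tab[, probe_table_cols], path, comment)
}

write_tsv_commented <- function(tab, path, comment = NULL) {
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(tab, path)
  }
  invisible(path)
}

#' Read a BED6+1 gene annotation with PAR1 flags
#'
#' BED convention: 0-based half-open intervals, columns chrom, start, end,
#' name, score, strand, plus a seventh logical/0-1 column flagging PAR1
#' genes. The TSS is the start for `+`-strand genes and the end for
#' `-`-strand genes.
#'
#' @param path File path.
#' @return Tibble: `chrom`, `start`, `end`, `gene`, `score`, `strand`,
#'   `par1`, `tss`, `tes`.
#' @export
read_gene_annotation <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_names = c("chrom", "start", "end", "gene",
                                       "score", "strand", "par1"),
                         col_types = "ciicicl")
  if (any(tab$start >= tab$end)) {
    stop("annotation ", path, ": start >= end at row ",
         which(tab$start >= tab$end)[1], call. = FALSE)
  }
  if (anyDuplicated(tab$gene)) {
    stop("annotation ", path, ": duplicate gene id '",
         tab$gene[anyDuplicated(tab$gene)], "'", call. = FALSE)
  }
  tab$tss <- ifelse(tab$strand == "-", tab$end, tab$start)
  tab$tes <- ifelse(tab$strand == "-", tab$start, tab$end)
  tab
}

#' Write a BED6+1 gene annotation
#'
#' @param annotation Tibble with `chrom`, `start`, `end`, `gene`, `score`,
#'   `strand`, `par1`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  readr::write_tsv(annotation[, c("chrom", "start", "end", "gene",
                                  "score", "strand", "par1")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a training-set gene list (one id per line)
#'
#' @param path File path; blank lines and `#` comments are skipped.
#' @return Character vector of gene ids.
#' @export
read_training_genes <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
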