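# Plain-text interchange: TSV for marker, trial, BLUE and kinship tables,
# plus a minimal biallelic VCF for marker matrices.

#' Read and write marker matrices as TSV
#'
#' Lines x markers layout: header row of marker ids, first column
#' `line_id`, entries -1/0/1/NA.
#'
#' @param markers lines x markers matrix.
#' @param path file path.
#' @return `read_marker_tsv()` returns the matrix; writers return the
#'   path invisibly.
#' @export
write_marker_tsv <- function(markers, path) {
  df <- data.frame(line_id = rownames(markers), markers,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_tsv
#' @export
read_marker_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Read and write plot-level trial data as TSV
#'
#' Columns: `line_id`, `trial_id`, `year`, `stage`, `row`, `col`,
#' `is_check`, `yield`, `protein`.
#'
#' @param trials plot-level data.frame.
#' @param path file path.
#' @export
write_trial_tsv <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_tsv
#' @export
read_trial_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$is_check <- as.logical(df$is_check)
  df
}

#' Write a kinship matrix as a square TSV with line ids
#'
#' @param K a `gas_grm` or plain matrix.
#' @param path file path.
#' @export
write_kinship_tsv <- function(K, path) {
  write_marker_tsv(as_kinship(K), path)
}

#' Write a marker matrix as a minimal VCF
#'
#' Sites-only biallelic VCF with a GT field per line: -1 maps to `0/0`,
#' 0 to `0/1`, +1 to `1/1`, `NA` to `./.`. Markers are placed on a dummy
#' chromosome at consecutive positions — the file carries genotype codes,
#' not real coordinates.
#'
#' @param markers lines x markers matrix.
#' @param path output path (uncompressed `.vcf`).
#' @export
write_marker_vcf <- function(markers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr0>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(markers)),
                     collapse = "\t")), con)
  code <- c(`-1` = "0/0", `0` = "0/1", `1` = "1/1")
  for (k in seq_len(ncol(markers))) {
    gt <- code[as.character(markers[, k])]
    gt[is.na(gt)] <- "./."
    writeLines(paste(c("chr0", k, colnames(markers)[k], "A", "T", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a biallelic VCF into a marker matrix
#'
#' Maps GT `0/0` to -1, heterozygotes to 0, `1/1` to +1, and missing to
#' `NA`. Uses the VariantAnnotation package when installed; otherwise a
#' minimal internal parser handles plain uncompressed GT-first VCFs such
#' as those produced by [write_marker_vcf()].
#'
#' @param path VCF path.
#' @return lines x markers matrix.
#' @export
read_marker_vcf <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)$GT
    m <- matrix(NA_real_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
    m[t(gt) %in% c("0/0", "0|0")] <- -1
    m[t(gt) %in% c("0/1", "1/0", "0|1", "1|0")] <- 0
    m[t(gt) %in% c("1/1", "1|1")] <- 1
    return(m)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ids <- header[-(1:9)]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  m <- matrix(NA_real_, length(ids), length(body),
              dimnames = list(ids,
                              vapply(body, `[[`, "", 3L)))
  map <- c(`0/0` = -1, `0|0` = -1, `0/1` = 0, `1/0` = 0, `0|1` = 0,
           `1|0` = 0, `1/1` = 1, `1|1` = 1)
  for (k in seq_along(body)) {
    gt <- sub(":.*$", "", body[[k]][-(1:9)])
    m[, k] <- unname(map[gt])
  }
  m
}

#' Read and write structured key-value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment; numeric values
#' are converted, comma-separated values become vectors.
#'
#' @param config named list.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(config[[k]], collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    vals <- trimws(strsplit(kv[2L], ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) num else vals
  }
  out
}
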