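#' @name mycoroot-io
#' @title Tabular and sequence input/output
#' @description TSV is the canonical tabular dialect (UTF-8, tab separator,
#'   `.` decimal): matrices carry OTU ids in the header row and sample or
#'   species ids in the first column; writers use a deterministic column
#'   order and prepend a one-line provenance comment (`#!`). FASTA/FASTQ pass
#'   through Biostrings, tolerating wrapped lines and CRLF endings.
NULL

provenance_block <- function(seed = NULL, extra = list()) {
  c(list(package = "mycoroot",
         version = as.character(utils::packageVersion("mycoroot")),
         seed = if (is.null(seed)) NA else seed),
    extra)
}

provenance_line <- function(prov) {
  paste0("#! ", jsonlite::toJSON(prov, auto_unbox = TRUE, null = "null"))
}

#' Write a matrix as TSV with ids in the first column
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the first (id) column.
#' @param provenance Optional provenance list written as a `#!` comment line.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(m, path, id_col = "id", provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance_line(provenance), con)
  df <- data.frame(rownames(m), as.data.frame(unclass(m), check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_tsv_matrix()]
#'
#' @param path Input path.
#' @return Numeric matrix with ids as row names; provenance (if present) in
#'   attribute `provenance`.
#' @export
read_tsv_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  prov <- NULL
  if (length(lines) > 0 && startsWith(lines[1], "#!")) {
    prov <- jsonlite::fromJSON(sub("^#!\\s*", "", lines[1]))
    lines <- lines[-1]
  }
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate ids in first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  attr(m, "provenance") <- prov
  m
}

#' Write/read a data frame as TSV
#'
#' @param df Data frame.
#' @param path File path.
#' @param provenance Optional provenance list (write only).
#' @return The path (write) or the data frame (read).
#' @export
write_tsv_table <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance_line(provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  if (length(lines) > 0 && startsWith(lines[1], "#!")) lines <- lines[-1]
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read and write FASTA / FASTQ
#'
#' Thin wrappers over Biostrings readers/writers. `read_fastq()` returns a
#' data frame compatible with [trim_and_filter()]; CRLF line endings are
#' normalized before parsing.
#'
#' @param path File path.
#' @param seqs Named character vector of sequences (FASTA write).
#' @param reads Data frame with `read_id`, `sequence`, `quality` (FASTQ
#'   write); a `sample_id` column is preserved on read via the description.
#' @return `read_fasta`: named character vector. `read_fastq`: data frame
#'   with `read_id`, `sequence`, `quality`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(normalize_eol(path), format = "fasta")
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(normalize_eol(path), format = "fastq",
                                    with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(rbind(paste0("@", reads$read_id), reads$sequence,
                   "+", reads$quality), con)
  invisible(path)
}

# Biostrings FASTQ parsing expects Unix line endings; rewrite to a temp file
# only when CRLF is detected
normalize_eol <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (!any(raw == as.raw(13L))) return(path)
  tmp <- tempfile(fileext = paste0(".", tools::file_ext(path)))
  writeLines(sub("\r$", "", readLines(path)), tmp)
  tmp
}

#' Write or read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a restored [pipeline_config()];
#'   the round trip preserves all settings.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  # yaml serializes named atomic vectors as plain sequences; keep the names
  # by converting them to maps
  yamlify <- function(x) {
    if (is.list(x)) lapply(unclass(x), yamlify)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  yaml::write_yaml(yamlify(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
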