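#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; sequence names are
#' truncated at the first whitespace, matching common tool behaviour.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a polygon selection from JSON
#'
#' Expected shape: `{"vertices": [[x, y], ...]}` with at least three
#' vertices; the polygon is implicitly closed.
#'
#' @param path JSON file path.
#' @return A two-column matrix of vertices.
#' @export
read_polygon <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$vertices
  if (is.null(v)) stopf("polygon JSON must contain a 'vertices' field")
  v <- as.matrix(v)
  if (ncol(v) != 2 || nrow(v) < 3)
    stopf("polygon needs >= 3 (x, y) vertices")
  storage.mode(v) <- "double"
  v
}

#' Write a polygon selection to JSON
#'
#' @param vertices Two-column matrix or data.frame of (x, y) vertices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_polygon <- function(vertices, path) {
  v <- as.matrix(vertices)
  jsonlite::write_json(list(vertices = lapply(seq_len(nrow(v)), function(i)
    c(v[i, 1], v[i, 2]))), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a gene coverage table
#'
#' Expects columns `gene_id`, optionally `length`, then one numeric
#' column per sample.
#'
#' @param path TSV path.
#' @return data.frame as stored.
#' @export
read_coverage_table <- function(path) {
  df <- read_tsv(path)
  if (!"gene_id" %in% names(df)) stopf("coverage table needs a gene_id column")
  df
}

# Extract the numeric sample matrix from a coverage data.frame.
coverage_matrix <- function(cov) {
  meta <- intersect(c("gene_id", "length"), names(cov))
  m <- as.matrix(cov[, setdiff(names(cov), meta), drop = FALSE])
  rownames(m) <- cov$gene_id
  storage.mode(m) <- "double"
  m
}
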