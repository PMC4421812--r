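#' Read and write Newick trees
#'
#' Thin validated wrappers around [ape::read.tree()] / [ape::write.tree()].
#' `read_newick` accepts a file path or a literal Newick string; trees
#' round-trip losslessly (topology, labels, branch lengths to 10 significant
#' digits).
#'
#' @param x Newick text (containing `";"`) or a file path.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  txt <- if (grepl(";", x, fixed = TRUE)) x else {
    if (!file.exists(x)) stop("Newick file not found: ", x)
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  n_open <- stringr::str_count(txt, stringr::fixed("("))
  n_close <- stringr::str_count(txt, stringr::fixed(")"))
  if (n_open != n_close) {
    offset <- unbalanced_offset(txt)
    stop("unbalanced parentheses in Newick text at character ", offset)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("failed to parse Newick text")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  tree
}

unbalanced_offset <- function(txt) {
  depth <- cumsum(
    (strsplit(txt, "")[[1]] == "(") - (strsplit(txt, "")[[1]] == ")")
  )
  bad <- which(depth < 0)
  if (length(bad) > 0) bad[1] else nchar(txt)
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @param path Optional output path; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read and write FASTA files
#'
#' @param path File path.
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80L
  )
  invisible(path)
}

#' Read a gene annotation
#'
#' Accepts 4-column BED (`chrom`, `start`, `end`, `gene_id`; 0-based
#' half-open, the internal convention) or a 4-column TSV dialect with a header
#' naming those columns in any order. Returns a tibble with a scaffold-order
#' index per chromosome.
#'
#' @param path Path to the BED/TSV file.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `order` columns.
#' @export
read_gene_bed <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_id", first)
  if (has_header) {
    tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(tb)))
  } else {
    tb <- readr::read_tsv(
      path, col_names = c("chrom", "start", "end", "gene_id"),
      show_col_types = FALSE, progress = FALSE
    )
  }
  tb <- tb |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    select("gene_id", "chrom", "start", "end")
  if (any(tb$start >= tb$end)) stop("gene annotation with start >= end")
  if (anyDuplicated(tb$gene_id)) stop("duplicate gene_id in annotation")
  tb |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(order = dplyr::row_number()) |>
    ungroup()
}

#' Read and write family count/presence matrices
#'
#' TSV with a header row of taxon ids and a first column of family ids.
#' Counts are non-negative integers; presence is derived as `count > 0`.
#'
#' @param path File path.
#' @return `read_family_matrix`: an integer matrix, families x taxa.
#' @export
read_family_matrix <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(tb[[1]])
  if (any(m < 0, na.rm = TRUE)) stop("negative family counts")
  m
}

#' @rdname read_family_matrix
#' @param m Matrix with family rownames and taxon colnames.
#' @export
write_family_matrix <- function(m, path) {
  tb <- as_tibble(m, rownames = "family_id")
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Convert a count matrix to a presence matrix
#' @param m Non-negative integer matrix (families x taxa).
#' @return Logical matrix of the same shape.
#' @export
as_presence <- function(m) {
  if (is.logical(m)) return(m)
  m > 0
}
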