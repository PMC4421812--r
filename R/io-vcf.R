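#' Read a VCF file into a variant table
#'
#' Parses a (possibly gzip-compressed) VCF v4.x file and returns the biallelic
#' single-nucleotide variants as a tibble: one row per retained site with
#' `chrom`, `pos` (0-based; VCF positions are converted on the way in), `ref`,
#' `alt`, and one integer column per sample holding the genotype coded as
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing. Indels and multiallelic records are dropped and the counts
#' reported.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param samples Optional character vector of sample names to retain, in the
#'   requested order. Unknown names are an error listing the available ones.
#' @param quiet Suppress the dropped-record message.
#' @return A `variant_tbl` tibble (see Details).
#' @details The parser is GT-centric: only the genotype call of each sample is
#'   retained. Positions are strictly increasing within each chromosome after
#'   filtering; violations are an error because downstream window statistics
#'   assume sorted input.
#' @export
read_vcf <- function(path, samples = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  check_vcf_records(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    warning("no variant records in ", path)
    return(empty_variant_tbl(vcf_sample_names(vcf)))
  }
  gt <- vcf@gt
  available <- colnames(gt)[-1]
  if (!is.null(samples)) {
    missing <- setdiff(samples, available)
    if (length(missing) > 0) {
      stop(
        "sample(s) not in VCF: ", paste(missing, collapse = ", "),
        "; available: ", paste(available, collapse = ", ")
      )
    }
  } else {
    samples <- available
  }

  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  is_snv <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  is_multi <- grepl(",", alt, fixed = TRUE)
  n_multi <- sum(is_multi)
  n_indel <- sum(!is_snv & !is_multi)
  keep <- is_snv & !is_multi

  if (!quiet && (n_multi + n_indel) > 0) {
    message(
      "read_vcf: dropped ", n_indel, " indel/non-SNV and ",
      n_multi, " multiallelic record(s); retained ", sum(keep), " SNV(s)"
    )
  }
  if (sum(keep) == 0) {
    warning("no biallelic SNV records retained from ", path)
    return(empty_variant_tbl(samples))
  }

  gt_calls <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  geno <- apply(gt_calls[, samples, drop = FALSE], 2, decode_gt)
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = length(samples))
  colnames(geno) <- samples

  out <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]) - 1L,
    ref = ref[keep],
    alt = alt[keep]
  )
  out <- dplyr::bind_cols(out, as_tibble(geno))
  validate_variant_tbl(out)
  new_variant_tbl(out)
}

# Cheap structural pre-check so malformed records are reported with their
# line number rather than failing inside the parser.
check_vcf_records <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("not a VCF file (missing ##fileformat header): ", path)
  }
  body <- which(!startsWith(lines, "#"))
  if (length(body) == 0) return(invisible(TRUE))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield < 8]
  if (length(bad) > 0) {
    stop("malformed VCF record at line ", bad[1], " of ", path)
  }
  invisible(TRUE)
}

vcf_sample_names <- function(vcf) {
  gt <- vcf@gt
  if (is.null(gt)) character() else colnames(gt)[-1]
}

decode_gt <- function(x) {
  x <- sub(":.*$", "", x)
  x <- gsub("|", "/", x, fixed = TRUE)
  out <- rep(NA_integer_, length(x))
  out[x %in% c("0/0")] <- 0L
  out[x %in% c("0/1", "1/0")] <- 1L
  out[x %in% c("1/1")] <- 2L
  out
}

encode_gt <- function(x) {
  out <- rep("./.", length(x))
  out[!is.na(x) & x == 0L] <- "0/0"
  out[!is.na(x) & x == 1L] <- "0/1"
  out[!is.na(x) & x == 2L] <- "1/1"
  out
}

new_variant_tbl <- function(x) {
  class(x) <- unique(c("variant_tbl", class(as_tibble(x))))
  x
}

empty_variant_tbl <- function(samples) {
  out <- tibble(
    chrom = character(), pos = integer(),
    ref = character(), alt = character()
  )
  for (s in samples) out[[s]] <- integer()
  new_variant_tbl(out)
}

validate_variant_tbl <- function(x) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(x)))
  split_pos <- split(x$pos, x$chrom)
  ok <- vapply(split_pos, function(p) all(diff(p) > 0), logical(1))
  if (!all(ok)) {
    stop(
      "positions not strictly increasing on: ",
      paste(names(ok)[!ok], collapse = ", ")
    )
  }
  invisible(x)
}

#' Sample names of a variant table
#' @param x A `variant_tbl`.
#' @return Character vector of sample column names.
#' @export
variant_samples <- function(x) {
  setdiff(names(x), c("chrom", "pos", "ref", "alt"))
}

#' Write a variant table as a minimal VCF
#'
#' Emits a minimal, spec-conformant VCF v4.2 (GT-only FORMAT) such that
#' `read_vcf(write_vcf(x))` reproduces `x` exactly. Internal 0-based positions
#' are converted back to VCF's 1-based convention.
#'
#' @param x A `variant_tbl`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(x, path) {
  samples <- variant_samples(x)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kelpscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(
      c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", samples),
      collapse = "\t"
    )
  )
  if (nrow(x) > 0) {
    gt_cols <- vapply(samples, function(s) encode_gt(x[[s]]), character(nrow(x)))
    if (is.null(dim(gt_cols))) gt_cols <- matrix(gt_cols, nrow = nrow(x))
    body <- paste(
      x$chrom, x$pos + 1L, ".", x$ref, x$alt, ".", ".", ".", "GT",
      apply(gt_cols, 1, paste, collapse = "\t"),
      sep = "\t"
    )
  } else {
    body <- character()
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
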