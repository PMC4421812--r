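#' Expand diploid genotypes into a haplotype matrix
#'
#' Converts a single-chromosome slice of a variant table into a matrix of
#' allele copies: two rows per individual, one column per site, entries in
#' \{0, 1, NA\}. The expansion is deterministic — hom-ref becomes (0,0), het
#' (0,1), hom-alt (1,1), missing (NA,NA) — which is sufficient for all the
#' frequency-based window statistics (they do not depend on phase).
#'
#' @param x A `variant_tbl` restricted to one chromosome.
#' @param samples Optional sample subset.
#' @return Integer matrix `(2 x individuals) x sites` with attributes
#'   `positions` (0-based) and `chrom`; rownames are `<sample>.a/.b`.
#' @export
as_haplotype_matrix <- function(x, samples = NULL) {
  chroms <- unique(x$chrom)
  if (length(chroms) > 1) {
    stop("variant table spans multiple chromosomes; subset to one first")
  }
  samples <- samples %||% variant_samples(x)
  missing <- setdiff(samples, variant_samples(x))
  if (length(missing) > 0) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  }
  geno <- t(as.matrix(x[, samples, drop = FALSE]))  # samples x sites
  n_sites <- ncol(geno)
  hap <- matrix(
    NA_integer_, nrow = 2L * length(samples), ncol = n_sites,
    dimnames = list(
      paste(rep(samples, each = 2), c("a", "b"), sep = "."), NULL
    )
  )
  a <- geno
  a[geno == 2L] <- 1L
  a[geno == 1L] <- 0L
  b <- geno
  b[geno == 2L] <- 1L
  b[geno == 1L] <- 1L
  hap[seq(1, nrow(hap), by = 2), ] <- a
  hap[seq(2, nrow(hap), by = 2), ] <- b
  attr(hap, "positions") <- x$pos
  attr(hap, "chrom") <- if (length(chroms) == 1) chroms else NA_character_
  class(hap) <- c("haplotype_matrix", class(hap))
  hap
}

#' Collapse a haplotype matrix into a variant table
#'
#' Consecutive row pairs are treated as the two allele copies of one diploid
#' individual. Monomorphic columns are dropped (they carry no variant).
#'
#' @param hap 0/1/NA matrix with an even number of rows and attributes
#'   `positions` and `chrom` (as produced by the simulators).
#' @param sample_ids Individual names; defaults to `s1, s2, ...`.
#' @param ref,alt Reference/alternate alleles to assign (recycled).
#' @return A `variant_tbl`.
#' @export
haplotypes_to_variants <- function(hap, sample_ids = NULL, ref = "A", alt = "T") {
  stopifnot(nrow(hap) %% 2 == 0)
  n_ind <- nrow(hap) %/% 2
  sample_ids <- sample_ids %||% paste0("s", seq_len(n_ind))
  stopifnot(length(sample_ids) == n_ind)
  pos <- attr(hap, "positions")
  chrom <- attr(hap, "chrom") %||% "chr1"
  a <- hap[seq(1, nrow(hap), by = 2), , drop = FALSE]
  b <- hap[seq(2, nrow(hap), by = 2), , drop = FALSE]
  geno <- a + b
  # polymorphic among called alleles only
  keep <- apply(hap, 2, function(col) {
    col <- col[!is.na(col)]
    length(unique(col)) > 1
  })
  out <- tibble(
    chrom = chrom,
    pos = as.integer(pos[keep]),
    ref = rep_len(ref, sum(keep)),
    alt = rep_len(alt, sum(keep))
  )
  geno <- t(geno[, keep, drop = FALSE])
  colnames(geno) <- sample_ids
  out <- dplyr::bind_cols(out, as_tibble(geno))
  new_variant_tbl(out)
}
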