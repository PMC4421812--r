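#' Tajima's D variance constants
#'
#' The standard constants of Tajima's D as functions of the allele count n:
#' a1 = sum(1/i), a2 = sum(1/i^2) for i in 1..n-1, b1 = (n+1)/(3(n-1)),
#' b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2+a2).
#'
#' @param n_alleles Number of sequences (allele copies), >= 2.
#' @return One-row tibble with columns `n, a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n_alleles) {
  n <- as.numeric(n_alleles)
  if (is.na(n) || n < 2) stop("tajima_constants requires n_alleles >= 2")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  tibble(
    n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
    c1 = c1, c2 = c2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2)
  )
}

#' Nucleotide diversity (window total) from a haplotype slice
#'
#' Mean number of pairwise differences between haplotypes across the window,
#' computed in the unbiased frequency form: per segregating site with derived
#' count k among n_s called alleles, the contribution is
#' 2 k (n_s - k) / (n_s (n_s - 1)), summed over sites. This equals the
#' all-pairs mean difference count exactly when no data are missing.
#'
#' @param hap 0/1/NA haplotype matrix (alleles x sites).
#' @return Numeric window-total pi; `NaN` when no site has >= 2 called
#'   alleles and the window is non-empty.
#' @export
window_pi <- function(hap) {
  if (ncol(hap) == 0) return(0)
  called <- colSums(!is.na(hap))
  derived <- colSums(hap == 1L, na.rm = TRUE)
  usable <- called >= 2
  if (!any(usable)) return(NaN)
  k <- derived[usable]
  ns <- called[usable]
  sum(2 * k * (ns - k) / (ns * (ns - 1)))
}

#' Count segregating sites among called alleles
#' @param hap 0/1/NA haplotype matrix.
#' @return Integer count of columns with both alleles observed.
#' @export
count_segregating <- function(hap) {
  if (ncol(hap) == 0) return(0L)
  anc <- colSums(hap == 0L, na.rm = TRUE)
  der <- colSums(hap == 1L, na.rm = TRUE)
  sum(anc > 0 & der > 0)
}

#' Watterson's theta from segregating sites
#' @param S Number of segregating sites (>= 0).
#' @param n_alleles Number of allele copies (>= 2).
#' @return S / a1(n).
#' @export
window_theta_w <- function(S, n_alleles) {
  stopifnot(S >= 0)
  S / tajima_constants(n_alleles)$a1
}

#' Tajima's D
#'
#' D = (pi - theta_W) / sqrt(e1 S + e2 S (S - 1)), with pi and theta_W as
#' window totals. Undefined (NA) for S = 0 or n < 3 (the variance is
#' degenerate); undefined windows are excluded from empirical quantiles.
#'
#' @param pi Window-total nucleotide diversity.
#' @param S Segregating sites.
#' @param n_alleles Allele count used for the constants.
#' @return Numeric D, or `NA` where undefined.
#' @export
tajimas_d <- function(pi, S, n_alleles) {
  if (is.na(S) || S < 1 || n_alleles < 3) return(NA_real_)
  const <- tajima_constants(n_alleles)
  v <- const$e1 * S + const$e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi - S / const$a1) / sqrt(v)
}

#' Sliding-window diversity scan
#'
#' Tiles each chromosome with windows starting at 0 in increments of `step`
#' and computes per-window S, window-total pi, Watterson's theta and Tajima's
#' D for the chosen population sample. Trailing windows shorter than
#' `window_size` are kept and flagged (`partial`): S and pi are window
#' totals and the D constants depend on n, not on window length. The
#' per-window allele count n used for the constants is the number of allele
#' copies with <= 20% missing calls in the window; per-site called counts
#' are used inside pi.
#'
#' @param variants A `variant_tbl`.
#' @param window_size,step Window and step in bp; `window_size >= step >= 1`.
#' @param samples Optional character vector naming the population's samples.
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the last variant position + 1 per chromosome.
#' @param max_missing Per-allele missingness ceiling for inclusion in n.
#' @return A `tajima_scan` tibble: `chrom, start, end, partial, n_alleles,
#'   n_sites, S, pi, theta_w, D`.
#' @export
sliding_scan <- function(variants, window_size = 10000, step = 5000,
                         samples = NULL, chrom_lengths = NULL,
                         max_missing = 0.2) {
  stopifnot(window_size >= step, step >= 1)
  samples <- samples %||% variant_samples(variants)
  unknown <- setdiff(samples, variant_samples(variants))
  if (length(unknown) > 0) {
    stop("unknown sample(s) in population list: ", paste(unknown, collapse = ", "))
  }
  chroms <- unique(variants$chrom)
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    vt <- variants[variants$chrom == chrom, , drop = FALSE]
    hap <- as_haplotype_matrix(vt, samples)
    pos <- attr(hap, "positions")
    len <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      as.numeric(chrom_lengths[[chrom]])
    } else {
      max(pos, 0) + 1
    }
    starts <- seq(0, max(len - 1, 0), by = step)
    rows <- purrr::map(starts, function(s) {
      e <- min(s + window_size, len)
      in_win <- pos >= s & pos < e
      slice <- hap[, in_win, drop = FALSE]
      if (ncol(slice) > 0) {
        miss <- rowMeans(is.na(slice))
      } else {
        miss <- rep(0, nrow(hap))
      }
      n_used <- sum(miss <= max_missing)
      S <- count_segregating(slice)
      pi <- window_pi(slice)
      theta_w <- if (n_used >= 2) window_theta_w(S, n_used) else NA_real_
      D <- if (n_used >= 3) tajimas_d(pi, S, n_used) else NA_real_
      tibble(
        chrom = chrom, start = s, end = e,
        partial = (e - s) < window_size,
        n_alleles = n_used, n_sites = ncol(slice),
        S = S, pi = pi, theta_w = theta_w, D = D
      )
    })
    out[[ci]] <- list_rbind(rows)
  }
  res <- list_rbind(out)
  class(res) <- unique(c("tajima_scan", class(res)))
  res
}

#' Empirical tail thresholds of Tajima's D
#'
#' Lower and upper empirical quantiles (`tail_fraction`, `1 - tail_fraction`)
#' of the finite D values, by linear interpolation between order statistics.
#' Windows with undefined D are excluded.
#'
#' @param D Numeric vector of D values, or a `tajima_scan` tibble.
#' @param tail_fraction Tail mass in (0, 0.5); default 0.05 — windows beyond
#'   the 5% tails of the empirical distribution become sweep candidates.
#' @return Named numeric vector `c(low =, high =)`.
#' @export
empirical_thresholds <- function(D, tail_fraction = 0.05) {
  if (is.data.frame(D)) D <- D$D
  stopifnot(tail_fraction > 0, tail_fraction < 0.5)
  d <- D[is.finite(D)]
  if (length(d) == 0) stop("no finite Tajima's D values")
  if (length(d) < 20) {
    stop("need >= 20 finite D values for empirical tails, got ", length(d))
  }
  q <- quantile(d, c(tail_fraction, 1 - tail_fraction), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Call candidate sweep regions from a scan
#'
#' Windows with D below `low` are labelled `<prefix>N` (negative tail) and
#' above `high` labelled `<prefix>P`; consecutive or overlapping same-label
#' candidate windows are merged into regions. With the conventional prefixes
#' this yields the CN/CP (cultivated) and WN/WP (wild) region classes.
#'
#' @param scan A `tajima_scan` tibble (any tibble with `chrom, start, end, D`).
#' @param low,high Thresholds from [empirical_thresholds()]; `low < high`.
#' @param population_label One-letter population prefix, e.g. `"C"` or `"W"`.
#' @return A `sweep_regions` tibble: `chrom, start, end, label, n_windows,
#'   mean_D`.
#' @export
candidate_regions <- function(scan, low, high, population_label = "C") {
  if (low >= high) stop("low threshold must be below high threshold")
  cand <- scan |>
    filter(is.finite(.data$D), .data$D < low | .data$D > high) |>
    mutate(label = paste0(
      population_label, ifelse(.data$D < low, "N", "P")
    )) |>
    arrange(.data$chrom, .data$label, .data$start)
  if (nrow(cand) == 0) {
    return(new_sweep_regions(tibble(
      chrom = character(), start = integer(), end = integer(),
      label = character(), n_windows = integer(), mean_D = numeric()
    )))
  }
  merged <- cand |>
    group_by(.data$chrom, .data$label) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$start)
      grp <- cumsum(c(1, df$start[-1] > cummax(df$end)[-nrow(df)]))
      df |>
        mutate(.grp = grp) |>
        group_by(.data$.grp) |>
        summarise(
          start = min(.data$start), end = max(.data$end),
          n_windows = dplyr::n(), mean_D = mean(.data$D),
          .groups = "drop"
        ) |>
        select(-".grp")
    }) |>
    ungroup() |>
    select("chrom", "start", "end", "label", "n_windows", "mean_D") |>
    arrange(.data$chrom, .data$start, .data$label)
  new_sweep_regions(merged)
}

new_sweep_regions <- function(x) {
  class(x) <- unique(c("sweep_regions", class(as_tibble(x))))
  x
}

#' Genes overlapping sweep regions
#'
#' A gene is reported for a region if their half-open intervals overlap by at
#' least 1 bp (a gene exactly abutting a region boundary is not reported).
#' The unique gene total across all regions is attached as attribute
#' `n_genes` (a gene spanning two regions counts once).
#'
#' @param regions A `sweep_regions` tibble.
#' @param annotation Gene annotation tibble from [read_gene_bed()] (columns
#'   `gene_id, chrom, start, end`).
#' @return The regions tibble with list-column `gene_ids` and column
#'   `n_genes`; attribute `n_genes` holds the unique total.
#' @export
genes_in_regions <- function(regions, annotation) {
  missing_chrom <- setdiff(unique(regions$chrom), unique(annotation$chrom))
  if (length(missing_chrom) > 0) {
    warning(
      "region chromosome(s) absent from annotation: ",
      paste(missing_chrom, collapse = ", ")
    )
  }
  gene_ids <- purrr::pmap(
    list(regions$chrom, regions$start, regions$end),
    function(chrom, start, end) {
      hit <- annotation$chrom == chrom &
        annotation$start < end & annotation$end > start
      annotation$gene_id[hit]
    }
  )
  out <- regions |>
    mutate(
      gene_ids = gene_ids,
      n_genes = lengths(gene_ids)
    )
  attr(out, "n_genes") <- length(unique(unlist(gene_ids)))
  out
}
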