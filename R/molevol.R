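#' Proportion of pairwise differences (p-distance) between aligned sequences
#'
#' Columns containing a gap (`-`) or ambiguity code (anything outside
#' A/C/G/T) in either sequence are excluded from the comparison, matching the
#' convention that insertions and deletions do not contribute to substitution
#' counts.
#'
#' @param a,b Aligned sequences of equal length (character scalars).
#' @return Mismatches / compared columns; `NaN` when no column is comparable.
#' @export
p_distance <- function(a, b) {
  av <- toupper(strsplit(a, "")[[1]])
  bv <- toupper(strsplit(b, "")[[1]])
  if (length(av) != length(bv)) stop("aligned sequences differ in length")
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NaN)
  sum(av[ok] != bv[ok]) / sum(ok)
}

#' Jukes-Cantor corrected distance
#'
#' One-parameter correction d = -(3/4) ln(1 - (4/3) p) of an observed
#' difference proportion p; the inverse map is
#' p = (3/4)(1 - exp(-4d/3)) (see [jc_p_from_d()]).
#'
#' @param p Observed proportion of differing sites, 0 <= p < 0.75.
#' @return Corrected substitutions per site.
#' @export
jc_distance <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("p must be non-negative")
  if (any(p >= 0.75, na.rm = TRUE)) {
    stop("saturated distance: p >= 0.75 has no finite Jukes-Cantor correction")
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' @rdname jc_distance
#' @param d Substitutions per site, d >= 0.
#' @export
jc_p_from_d <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("d must be non-negative")
  0.75 * (1 - exp(-4 * d / 3))
}

#' Transposable-element age distribution
#'
#' Computes the Jukes-Cantor distance of each repeat copy to its family
#' consensus and bins copies by distance: counts per family per bin
#' `[k w, (k+1) w)`. Copies with saturated p (>= 0.75) go to an overflow bin
#' (`bin_low = Inf`); the non-overflow mass equals the number of
#' non-saturated copies. Distance correlates with insertion age, so the
#' histogram is the family's age distribution.
#'
#' @param alignments Tibble with columns `copy_id`, `family_id`, `copy`,
#'   `consensus` (aligned, equal length, gaps allowed).
#' @param bin_width Bin width in substitutions/site (default 0.01).
#' @return A `te_age_hist` tibble: `family_id, bin_low, bin_high, count`.
#' @export
te_age_distribution <- function(alignments, bin_width = 0.01) {
  if (nrow(alignments) == 0) {
    return(new_te_age_hist(tibble(
      family_id = character(), bin_low = numeric(),
      bin_high = numeric(), count = integer()
    ), bin_width))
  }
  p <- purrr::map2_dbl(alignments$copy, alignments$consensus, p_distance)
  saturated <- !is.na(p) & p >= 0.75
  d <- rep(NA_real_, length(p))
  d[!saturated] <- jc_distance(p[!saturated])
  bin <- floor(d / bin_width)
  tb <- tibble(
    family_id = alignments$family_id,
    bin_low = ifelse(saturated, Inf, bin * bin_width),
    bin_high = ifelse(saturated, Inf, (bin + 1) * bin_width)
  ) |>
    dplyr::count(.data$family_id, .data$bin_low, .data$bin_high, name = "count") |>
    arrange(.data$family_id, .data$bin_low)
  new_te_age_hist(tb, bin_width)
}

new_te_age_hist <- function(x, bin_width) {
  attr(x, "bin_width") <- bin_width
  class(x) <- unique(c("te_age_hist", class(as_tibble(x))))
  x
}

# --- Nei-Gojobori (1986) ---------------------------------------------------

codon_table <- function() {
  if (is.null(the$codon_table)) {
    gc <- Biostrings::GENETIC_CODE
    the$codon_table <- setNames(unname(gc), names(gc))
  }
  the$codon_table
}
the <- new.env(parent = emptyenv())

is_stop <- function(codon) codon_table()[codon] == "*"

# Synonymous site count of one codon: at each position, the fraction of the
# three possible changes that are synonymous; changes to stop codons are not
# counted as synonymous (the denominator stays 3, so S + N = 3 per codon).
syn_sites_codon <- function(codon) {
  tab <- codon_table()
  aa <- tab[codon]
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (nb in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nb
      if (tab[alt] != "*" && tab[alt] == aa) s <- s + 1 / 3
    }
  }
  unname(s)
}

syn_sites_cache <- function() {
  if (is.null(the$syn_sites)) {
    codons <- names(codon_table())
    the$syn_sites <- setNames(vapply(codons, syn_sites_codon, numeric(1)), codons)
  }
  the$syn_sites
}

# Average synonymous/nonsynonymous differences between two codons over all
# orderings of the single-nucleotide steps, excluding pathways through stop
# codons (falling back to all pathways if every ordering hits a stop).
codon_path_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  tab <- codon_table()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- all_permutations(pos)
  count_path <- function(order, allow_stop) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && tab[nxt] == "*") return(NULL)
      if (tab[nxt] == tab[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- purrr::compact(lapply(perms, count_path, allow_stop = FALSE))
  if (length(paths) == 0) {
    paths <- purrr::compact(lapply(perms, count_path, allow_stop = TRUE))
  }
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

split_codons <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

validate_codon_pair <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("codon alignment lengths differ")
  if (nchar(a) %% 3 != 0) stop("alignment length not divisible by 3")
  if (grepl("-", paste0(a, b), fixed = TRUE)) stop("codon alignment must be gapless")
  if (grepl("[^ACGT]", paste0(a, b))) stop("ambiguity codes not allowed in codon alignment")
  for (s in list(a, b)) {
    if (any(is_stop(split_codons(s)))) stop("stop codon in coding sequence")
  }
  list(a = a, b = b)
}

#' Nei-Gojobori (1986) Ka/Ks for a codon-aligned pair
#'
#' Classical unweighted counting: per-codon synonymous site fractions are
#' averaged across the two sequences; synonymous/nonsynonymous differences
#' at multi-position codon changes are averaged over all orderings of the
#' single-nucleotide steps, excluding pathways through stop codons. The
#' proportions ps = Sd/S and pn = Nd/N are Jukes-Cantor corrected to give
#' Ks and Ka.
#'
#' @param a,b Gapless, stop-free coding sequences of equal length divisible
#'   by 3.
#' @return One-row tibble: `Ka, Ks, ka_ks, S_sites, N_sites, Sd, Nd, ps, pn`.
#'   `S_sites + N_sites` always equals the aligned length.
#' @export
ng86_ka_ks <- function(a, b) {
  v <- validate_codon_pair(a, b)
  ca <- split_codons(v$a)
  cb <- split_codons(v$b)
  ss <- syn_sites_cache()
  S_sites <- (sum(ss[ca]) + sum(ss[cb])) / 2
  N_sites <- 3 * length(ca) - S_sites
  diffs <- purrr::map2(ca, cb, codon_path_diffs)
  Sd <- sum(vapply(diffs, `[[`, numeric(1), "sd"))
  Nd <- sum(vapply(diffs, `[[`, numeric(1), "nd"))
  ps <- if (S_sites > 0) Sd / S_sites else 0
  pn <- if (N_sites > 0) Nd / N_sites else 0
  if (ps >= 0.75) stop("saturated synonymous distance (ps >= 0.75)")
  if (pn >= 0.75) stop("saturated nonsynonymous distance (pn >= 0.75)")
  Ks <- jc_distance(ps)
  Ka <- jc_distance(pn)
  tibble(
    Ka = Ka, Ks = Ks, ka_ks = ifelse(Ks > 0, Ka / Ks, NA_real_),
    S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd, ps = ps, pn = pn
  )
}

#' Percent identity of an aligned pair
#'
#' Matches divided by aligned columns, excluding terminal gap overhangs
#' (columns within the leading/trailing gap run of either sequence); internal
#' gap columns count as mismatches.
#'
#' @param a,b Aligned sequences of equal length.
#' @return Identity in \[0, 1\].
#' @export
percent_identity <- function(a, b) {
  av <- toupper(strsplit(a, "")[[1]])
  bv <- toupper(strsplit(b, "")[[1]])
  if (length(av) != length(bv)) stop("aligned sequences differ in length")
  if (length(av) == 0) stop("empty alignment")
  span <- function(v) {
    non_gap <- which(v != "-")
    if (length(non_gap) == 0) stop("all-gap sequence in alignment")
    c(non_gap[1], non_gap[length(non_gap)])
  }
  sa <- span(av); sb <- span(bv)
  lo <- max(sa[1], sb[1]); hi <- min(sa[2], sb[2])
  if (lo > hi) stop("alignments do not overlap after trimming terminal gaps")
  idx <- lo:hi
  mean(av[idx] == bv[idx] & av[idx] != "-")
}
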