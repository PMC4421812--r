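#' GC content of nucleotide sequences
#'
#' (G+C) / (A+C+G+T); `N` and other ambiguity characters are excluded from
#' the denominator.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @return Numeric vector of GC fractions; `NaN` where a sequence has no
#'   unambiguous base.
#' @export
gc_content <- function(sequence) {
  s <- toupper(sequence)
  gc <- stringr::str_count(s, "[GC]")
  acgt <- stringr::str_count(s, "[ACGT]")
  ifelse(acgt > 0, gc / acgt, NaN)
}

#' Open-reading-frame density of a contig
#'
#' ORFs are searched in all six frames as ATG-to-stop spans (stop codon
#' included; an ATG run without a terminating stop is not an ORF) of at
#' least `min_orf_len` nucleotides. Overlapping spans are unioned on the
#' contig coordinate line before summing, so the density — union length
#' divided by contig length — never exceeds 1. A stop-to-stop mode (longest
#' stop-free span per frame, no ATG requirement) is available via `mode`.
#'
#' @param sequence A nucleotide string (length >= 3).
#' @param min_orf_len Minimum ORF length in nt (default 300, i.e. 100
#'   codons — long enough that random non-coding sequence rarely qualifies).
#' @param mode `"atg"` (default) or `"stop"`.
#' @return ORF density in \[0, 1\].
#' @export
orf_density <- function(sequence, min_orf_len = 300, mode = c("atg", "stop")) {
  mode <- match.arg(mode)
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < 3) stop("sequence shorter than one codon")
  fwd <- orf_spans_strand(s, min_orf_len, mode)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev_spans <- orf_spans_strand(rc, min_orf_len, mode)
  if (nrow(rev_spans) > 0) {
    rev_spans <- tibble(start = L - rev_spans$end, end = L - rev_spans$start)
  }
  spans <- bind_rows(fwd, rev_spans)
  if (nrow(spans) == 0) return(0)
  union_length(spans) / L
}

# 0-based half-open ORF spans on one strand (three frames).
orf_spans_strand <- function(s, min_orf_len, mode) {
  L <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (f in 0:2) {
    n_codon <- (L - f) %/% 3
    if (n_codon < 2) next
    cods <- substring(s, f + seq(1, by = 3, length.out = n_codon),
                      f + seq(3, by = 3, length.out = n_codon))
    stop_at <- which(cods %in% stops)
    prev <- 0L
    for (t in stop_at) {
      first <- if (mode == "atg") {
        if (t - 1L >= prev + 1L) {
          seg <- (prev + 1L):(t - 1L)
          atg <- which(cods[seg] == "ATG")
          if (length(atg) > 0) seg[atg[1]] else NA_integer_
        } else NA_integer_
      } else {
        prev + 1L
      }
      if (!is.na(first)) {
        span_nt <- 3L * (t - first + 1L)
        if (span_nt >= min_orf_len) {
          out[[length(out) + 1]] <- tibble(
            start = f + 3L * (first - 1L), end = f + 3L * t
          )
        }
      }
      prev <- t
    }
  }
  if (length(out) == 0) {
    tibble(start = integer(), end = integer())
  } else {
    list_rbind(out)
  }
}

union_length <- function(spans) {
  spans <- arrange(spans, .data$start)
  cur_s <- spans$start[1]; cur_e <- spans$end[1]
  total <- 0
  for (i in seq_len(nrow(spans))[-1]) {
    if (spans$start[i] <= cur_e) {
      cur_e <- max(cur_e, spans$end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- spans$start[i]; cur_e <- spans$end[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Contamination filter for candidate bacterial contigs
#'
#' Applies the assembly-cleaning rule: a contig is removed iff its taxonomy
#' hint is `candidate_bacterial` AND (ORF density >= `orf_cut` OR GC content
#' strictly above `gc_high` OR strictly below `gc_low`). Contigs hinted
#' `authentic` or `unknown` are always kept — the rule's scope is the
#' candidate set only. Boundary semantics are deliberate: the ORF cut is
#' inclusive, the GC band strict.
#'
#' @param contigs Tibble with columns `contig_id`, `sequence`, and `hint`
#'   (one of `candidate_bacterial`, `authentic`, `unknown`).
#' @param orf_cut ORF-density removal threshold (default 0.60, inclusive).
#' @param gc_low,gc_high Permitted GC band (defaults 0.40/0.60, strict).
#' @param min_orf_len,mode Passed to [orf_density()].
#' @param quiet Suppress the summary message.
#' @return The input tibble with `gc`, `orf_density` and `filtered` columns.
#' @export
filter_contigs <- function(contigs, orf_cut = 0.60, gc_low = 0.40,
                           gc_high = 0.60, min_orf_len = 300,
                           mode = "atg", quiet = FALSE) {
  stopifnot(all(c("contig_id", "sequence", "hint") %in% names(contigs)))
  bad_hint <- setdiff(
    unique(contigs$hint), c("candidate_bacterial", "authentic", "unknown")
  )
  if (length(bad_hint) > 0) {
    stop("unknown taxonomy hint(s): ", paste(bad_hint, collapse = ", "))
  }
  out <- contigs |>
    mutate(
      gc = gc_content(.data$sequence),
      orf_density = purrr::map_dbl(
        .data$sequence, orf_density, min_orf_len = min_orf_len, mode = mode
      ),
      filtered = .data$hint == "candidate_bacterial" &
        (.data$orf_density >= orf_cut | .data$gc > gc_high | .data$gc < gc_low)
    )
  if (!quiet) {
    message(
      "filter_contigs: removed ", sum(out$filtered), " of ", nrow(out),
      " contig(s) (", sum(out$hint == "candidate_bacterial"),
      " candidate bacterial)"
    )
  }
  out
}
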