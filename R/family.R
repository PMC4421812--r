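#' Fisher exact test for gene-family expansion between two genomes
#'
#' Two-sided exact test on the 2x2 table
#' `[count_A, total_A - count_A; count_B, total_B - count_B]` by the
#' minimum-likelihood rule: the p-value sums the hypergeometric
#' probabilities of all tables (at fixed margins) no more probable than the
#' observed one. Delegates to [stats::fisher.test()], which implements
#' exactly this convention.
#'
#' @param count_A,total_A Family size and genome-wide gene total in genome A.
#' @param count_B,total_B Same for genome B.
#' @return Two-sided p-value in (0, 1].
#' @export
expansion_test <- function(count_A, total_A, count_B, total_B) {
  if (any(c(count_A, total_A, count_B, total_B) < 0)) {
    stop("negative counts")
  }
  if (count_A > total_A || count_B > total_B) {
    stop("family count exceeds genome total")
  }
  tab <- matrix(
    c(count_A, total_A - count_A, count_B, total_B - count_B),
    nrow = 2, byrow = TRUE
  )
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Family-expansion scan over a count table
#'
#' Applies [expansion_test()] to every family, after the conventional
#' pre-filter keeping large families only (>= `min_family_size` genes summed
#' across the two genomes), and corrects for multiple testing.
#'
#' @param counts Tibble with columns `family_id`, `count_A`, `count_B`.
#' @param total_A,total_B Genome-wide gene totals.
#' @param min_family_size Size pre-filter on `count_A + count_B` (default
#'   10).
#' @param method Correction method for [adjust_pvalues()].
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return Tibble of tested families with `p_value`, `adjusted_p`,
#'   `direction` (`"A"`/`"B"`/`"none"`, by odds of the 2x2 table), and
#'   `significant`.
#' @export
expansion_scan <- function(counts, total_A, total_B, min_family_size = 10,
                           method = c("BH", "bonferroni"), alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(all(c("family_id", "count_A", "count_B") %in% names(counts)))
  tested <- counts |>
    filter(.data$count_A + .data$count_B >= min_family_size)
  if (nrow(tested) == 0) {
    return(tested |> mutate(
      p_value = numeric(0), adjusted_p = numeric(0),
      direction = character(0), significant = logical(0)
    ))
  }
  p <- purrr::map2_dbl(
    tested$count_A, tested$count_B,
    function(a, b) expansion_test(a, total_A, b, total_B)
  )
  prop_A <- tested$count_A / total_A
  prop_B <- tested$count_B / total_B
  tested |>
    mutate(
      p_value = p,
      adjusted_p = adjust_pvalues(p, method = method),
      direction = dplyr::case_when(
        prop_A > prop_B ~ "A",
        prop_B > prop_A ~ "B",
        TRUE ~ "none"
      ),
      significant = .data$adjusted_p < alpha
    )
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up (default) or Bonferroni, preserving input
#' order; a thin validated wrapper over [stats::p.adjust()].
#'
#' @param p P-values in (0, 1].
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = method)
}

#' Tandem-duplication clusters
#'
#' Builds a graph over same-scaffold gene pairs whose sequence identity is
#' at least `identity_threshold` and that have at most `max_intervening`
#' genes between them in coordinate order; clusters are the connected
#' components of size >= 2, reported with members in coordinate order. High
#' identity plus physical adjacency is the signature of recent tandem
#' duplication.
#'
#' @param gene_coords Tibble `gene_id, chrom, start, end` (e.g. from
#'   [read_gene_bed()]).
#' @param identity_matrix Symmetric numeric matrix in \[0, 1\] with gene ids
#'   as dimnames; typically from [percent_identity()] over gene pairs.
#' @param identity_threshold Minimum pairwise identity (default 0.85).
#' @param max_intervening Maximum genes between a linked pair (default 5).
#' @return Tibble `cluster, scaffold, n_members, min_identity` (minimum over
#'   the linked pairs, hence always >= the threshold) with list-column
#'   `gene_ids`.
#' @export
tandem_clusters <- function(gene_coords, identity_matrix,
                            identity_threshold = 0.85, max_intervening = 5) {
  ids <- rownames(identity_matrix)
  if (is.null(ids)) stop("identity matrix must carry gene ids as dimnames")
  missing <- setdiff(ids, gene_coords$gene_id)
  if (length(missing) > 0) {
    stop(
      "gene(s) in identity matrix absent from coordinates: ",
      paste(missing, collapse = ", ")
    )
  }
  coords <- gene_coords |>
    filter(.data$gene_id %in% ids) |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup()
  idx <- match(coords$gene_id, ids)

  edges <- list()
  n <- nrow(coords)
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      if (coords$chrom[i] != coords$chrom[j]) next
      if (abs(coords$rank[i] - coords$rank[j]) - 1 > max_intervening) next
      pid <- identity_matrix[idx[i], idx[j]]
      if (pid >= identity_threshold) {
        edges[[length(edges) + 1]] <- list(
          a = coords$gene_id[i], b = coords$gene_id[j], identity = pid
        )
      }
    }
  }
  if (length(edges) == 0) {
    return(tibble(
      cluster = integer(), scaffold = character(), n_members = integer(),
      min_identity = numeric(), gene_ids = list()
    ))
  }
  edge_tb <- list_rbind(purrr::map(edges, as_tibble))
  g <- igraph::graph_from_edgelist(
    cbind(edge_tb$a, edge_tb$b), directed = FALSE
  )
  comp <- igraph::components(g)
  membership <- comp$membership
  out <- purrr::map(seq_len(comp$no), function(ci) {
    members <- names(membership)[membership == ci]
    ordered <- coords |>
      filter(.data$gene_id %in% members) |>
      arrange(.data$start) |>
      pull("gene_id")
    in_comp <- edge_tb$a %in% members & edge_tb$b %in% members
    tibble(
      scaffold = coords$chrom[match(ordered[1], coords$gene_id)],
      n_members = length(ordered),
      min_identity = min(edge_tb$identity[in_comp]),
      gene_ids = list(ordered)
    )
  }) |>
    list_rbind() |>
    arrange(.data$scaffold, purrr::map_chr(.data$gene_ids, 1)) |>
    mutate(cluster = dplyr::row_number()) |>
    select("cluster", "scaffold", "n_members", "min_identity", "gene_ids")
  out
}
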