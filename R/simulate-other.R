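#' Simulate repeat copies diverged from a family consensus
#'
#' Each copy derives from a random consensus by i.i.d. per-site substitution
#' with probability `p = (3/4)(1 - exp(-4d/3))` — the inverse of the
#' Jukes-Cantor correction — where `d` is the copy's true age in expected
#' substitutions per site; a substitution draws a uniformly chosen different
#' nucleotide. Copies may be truncated to a contiguous fragment
#' (`fragment_fraction` of the consensus), with the removed flanks recorded
#' as gap columns in the alignment.
#'
#' @param consensus_length Consensus length in bp.
#' @param copy_ages Numeric vector of true ages `d >= 0`, one per copy.
#' @param fragment_fraction Retained fraction in (0, 1]; default 1 (full
#'   length).
#' @param family_id Family name attached to every copy.
#' @param seed Integer seed.
#' @return A list: `alignments` (tibble `copy_id, family_id, copy,
#'   consensus`) and `truth` (tibble with the seed and per-copy true `d`,
#'   `p`, and fragment coordinates).
#' @export
simulate_te_decay <- function(consensus_length = 1000, copy_ages,
                              fragment_fraction = 1, family_id = "TE-1",
                              seed = NULL) {
  if (any(copy_ages < 0)) stop("negative repeat age")
  stopifnot(fragment_fraction > 0, fragment_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  consensus <- sample(bases, consensus_length, replace = TRUE)
  cons_str <- paste(consensus, collapse = "")
  frag_len <- max(1L, round(fragment_fraction * consensus_length))
  n <- length(copy_ages)
  copies <- character(n)
  frag_start <- integer(n)
  for (i in seq_len(n)) {
    p <- jc_p_from_d(copy_ages[i])
    hit <- runif(consensus_length) < p
    copy <- consensus
    if (any(hit)) {
      copy[hit] <- vapply(
        consensus[hit],
        function(b) sample(setdiff(bases, b), 1),
        character(1)
      )
    }
    s <- if (frag_len < consensus_length) {
      sample.int(consensus_length - frag_len + 1L, 1)
    } else 1L
    frag_start[i] <- s
    aligned <- rep("-", consensus_length)
    aligned[s:(s + frag_len - 1L)] <- copy[s:(s + frag_len - 1L)]
    copies[i] <- paste(aligned, collapse = "")
  }
  alignments <- tibble(
    copy_id = paste0(family_id, "_copy", seq_len(n)),
    family_id = family_id,
    copy = copies,
    consensus = cons_str
  )
  truth <- tibble(
    copy_id = alignments$copy_id,
    family_id = family_id,
    true_d = copy_ages,
    true_p = jc_p_from_d(copy_ages),
    frag_start = frag_start,
    frag_len = frag_len,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  list(alignments = alignments, truth = truth)
}

#' Simulate Dollo-compatible gene-family evolution on a species tree
#'
#' Each family is gained exactly once, on a branch chosen uniformly from the
#' tree's branches plus the root stem; loss events are Poisson with mean
#' `loss_rate x branch length` on every branch strictly below the gain, and
#' a loss silences its entire subtree. Single origin (Dollo compatibility)
#' holds by construction.
#'
#' @param species_tree Rooted [ape::phylo] tree with branch lengths.
#' @param n_families Number of families to simulate.
#' @param loss_rate Loss events per unit branch length (>= 0).
#' @param seed Integer seed.
#' @return A list: `presence` (logical matrix families x taxa), `counts`
#'   (integer 0/1 version), `truth` (tibble `family_id, gain_node,
#'   gain_label, loss_nodes` list-column), and `tree`.
#' @export
simulate_family_evolution <- function(species_tree, n_families,
                                      loss_rate = 0.02, seed = NULL) {
  if (!ape::is.rooted(species_tree)) {
    stop("Dollo-style family evolution requires a rooted species tree")
  }
  if (is.null(species_tree$edge.length)) {
    stop("species tree must have branch lengths")
  }
  stopifnot(loss_rate >= 0, n_families >= 1)
  if (!is.null(seed)) set.seed(seed)
  tree <- species_tree
  tips <- tree$tip.label
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  edge_len <- setNames(tree$edge.length, tree$edge[, 2])
  node_label <- c(tips, paste0("node_", (n_tip + 1L):n_node))

  # descendant tips per node
  desc <- matrix(FALSE, n_node, n_tip)
  desc[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (nd in rev(root:n_node)) {
    for (ch in kids[[as.character(nd)]]) desc[nd, ] <- desc[nd, ] | desc[ch, ]
  }

  gain_options <- c(root, tree$edge[, 2])  # root stem + every branch
  presence <- matrix(
    FALSE, n_families, n_tip,
    dimnames = list(paste0("fam", seq_len(n_families)), tips)
  )
  gain_node <- integer(n_families)
  loss_nodes <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    g <- gain_options[sample.int(length(gain_options), 1)]
    gain_node[f] <- g
    pv <- desc[g, ]
    losses <- integer(0)
    if (g > n_tip) {
      stack <- kids[[as.character(g)]]
      while (length(stack) > 0) {
        nd <- stack[1]; stack <- stack[-1]
        if (rpois(1, loss_rate * edge_len[[as.character(nd)]]) > 0) {
          losses <- c(losses, nd)
          pv <- pv & !desc[nd, ]
        } else if (nd > n_tip) {
          stack <- c(stack, kids[[as.character(nd)]])
        }
      }
    }
    presence[f, ] <- pv
    loss_nodes[[f]] <- sort(losses)
  }
  truth <- tibble(
    family_id = rownames(presence),
    gain_node = gain_node,
    gain_label = node_label[gain_node],
    loss_nodes = loss_nodes,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  counts <- presence + 0L
  storage.mode(counts) <- "integer"
  list(presence = presence, counts = counts, truth = truth, tree = tree)
}

#' Simulate host and contaminant bacterial contigs
#'
#' Host-like contigs are i.i.d. nucleotide draws at `host_gc`; bacterial
#' contigs carry an elevated GC content and dense stop-free open reading
#' frames covering about `coding_density` of their length (ATG-initiated,
#' stop-terminated blocks separated by random spacer). Taxonomy hints
#' (`candidate_bacterial` / `authentic`) are emitted alongside, emulating
#' best-hit classification, so the contamination filter can be validated
#' against the recorded labels.
#'
#' @param n_host,n_bacterial Numbers of contigs.
#' @param host_gc,bacterial_gc GC fractions in (0, 1).
#' @param coding_density Target ORF coverage of bacterial contigs in \[0, 1\].
#' @param length_range Two increasing positive integers: contig length range.
#' @param seed Integer seed.
#' @return A tibble `contig_id, sequence, hint, true_origin, length`.
#' @export
simulate_contigs <- function(n_host = 50, n_bacterial = 50, host_gc = 0.5,
                             bacterial_gc = 0.65, coding_density = 0.8,
                             length_range = c(2000, 5000), seed = NULL) {
  stopifnot(
    host_gc > 0, host_gc < 1, bacterial_gc > 0, bacterial_gc < 1,
    coding_density >= 0, coding_density <= 1
  )
  if (length(length_range) != 2 || diff(length_range) < 0 || length_range[1] < 90) {
    stop("degenerate length_range")
  }
  if (!is.null(seed)) set.seed(seed)
  rand_seq <- function(n, gc) {
    paste(sample(
      c("A", "C", "G", "T"), n, replace = TRUE,
      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    ), collapse = "")
  }
  orf_block <- function(n_codons, gc) {
    stops <- c("TAA", "TAG", "TGA")
    body <- character(n_codons - 2L)
    for (k in seq_len(n_codons - 2L)) {
      repeat {
        cd <- rand_seq(3, gc)
        if (!cd %in% stops) break
      }
      body[k] <- cd
    }
    paste0("ATG", paste(body, collapse = ""), "TAA")
  }
  bact_seq <- function(len, gc, density) {
    out <- character(0)
    made <- 0L
    while (made < len) {
      cycle <- min(900L, len - made)
      orf_nt <- (round(cycle * density) %/% 3L) * 3L
      if (orf_nt >= 9L) {
        out <- c(out, orf_block(orf_nt %/% 3L, gc))
        made <- made + orf_nt
      }
      spacer <- cycle - orf_nt
      if (spacer > 0) {
        out <- c(out, rand_seq(spacer, gc))
        made <- made + spacer
      }
      if (orf_nt < 9L && spacer == 0) break
    }
    paste(out, collapse = "")
  }
  draw_len <- function(n) {
    length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n, replace = TRUE)
  }
  lens_h <- draw_len(n_host)
  lens_b <- draw_len(n_bacterial)
  host <- vapply(lens_h, rand_seq, character(1), gc = host_gc)
  bact <- vapply(lens_b, bact_seq, character(1),
                 gc = bacterial_gc, density = coding_density)
  ids <- function(prefix, n) {
    if (n > 0) paste0(prefix, seq_len(n)) else character(0)
  }
  tibble(
    contig_id = c(ids("host_", n_host), ids("bact_", n_bacterial)),
    sequence = c(host, bact),
    hint = c(
      rep("authentic", n_host), rep("candidate_bacterial", n_bacterial)
    ),
    true_origin = c(rep("host", n_host), rep("bacterial", n_bacterial)),
    length = nchar(c(host, bact))
  )
}

#' Simulate codon-aligned paralog pairs with known Ka and Ks
#'
#' Starting from a random stop-free coding sequence, applies synonymous and
#' nonsynonymous single-nucleotide substitutions (at most one per codon,
#' never creating a stop) in numbers Poisson-distributed around
#' `p_s x S_sites` and `p_n x N_sites`, where `p_s`/`p_n` invert the
#' Jukes-Cantor correction of `true_ks`/`true_ka`. Nei-Gojobori counting on
#' the resulting pair recovers the true rates up to sampling noise.
#'
#' @param n_pairs Number of independent pairs.
#' @param true_ks,true_ka True synonymous/nonsynonymous rates (<= 1; multiple
#'   hits must stay rare for the construction to be faithful).
#' @param codon_count Codons per sequence (>= 100).
#' @param seed Integer seed.
#' @return A list: `pairs` (tibble `pair_id, seq_a, seq_b`) and `truth`.
#' @export
simulate_paralog_pairs <- function(n_pairs = 50, true_ks = 0.4, true_ka = 0,
                                   codon_count = 2000, seed = NULL) {
  stopifnot(codon_count >= 100, true_ks >= 0, true_ka >= 0)
  if (true_ks > 1 || true_ka > 1) {
    stop("rates above 1 violate the rare-multiple-hit assumption")
  }
  if (!is.null(seed)) set.seed(seed)
  tab <- codon_table()
  sense <- names(tab)[tab != "*"]
  ss <- syn_sites_cache()
  ps <- jc_p_from_d(true_ks)
  pn <- jc_p_from_d(true_ka)
  bases <- c("A", "C", "G", "T")

  mutate_one <- function(codon, synonymous) {
    opts <- list()
    for (pos in 1:3) {
      for (nb in setdiff(bases, substr(codon, pos, pos))) {
        alt <- codon
        substr(alt, pos, pos) <- nb
        if (tab[alt] == "*") next
        same <- tab[alt] == tab[codon]
        if (same == synonymous) opts[[length(opts) + 1]] <- alt
      }
    }
    if (length(opts) == 0) NULL else opts[[sample.int(length(opts), 1)]]
  }

  pair_ids <- paste0("pair", seq_len(n_pairs))
  seq_a <- character(n_pairs)
  seq_b <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    anc <- sample(sense, codon_count, replace = TRUE)
    S_sites <- sum(ss[anc])
    N_sites <- 3 * codon_count - S_sites
    n_syn <- rpois(1, ps * S_sites)
    n_non <- rpois(1, pn * N_sites)
    if (n_syn + n_non > codon_count) {
      stop("substitution load exceeds one change per codon; shorten rates")
    }
    der <- anc
    order_all <- sample.int(codon_count)
    placed_s <- 0L; placed_n <- 0L
    for (cd in order_all) {
      if (placed_s < n_syn) {
        alt <- mutate_one(der[cd], synonymous = TRUE)
        if (!is.null(alt) && der[cd] == anc[cd]) {
          der[cd] <- alt; placed_s <- placed_s + 1L; next
        }
      }
      if (placed_s >= n_syn && placed_n >= n_non) break
    }
    for (cd in sample.int(codon_count)) {
      if (placed_n >= n_non) break
      if (der[cd] != anc[cd]) next
      alt <- mutate_one(der[cd], synonymous = FALSE)
      if (!is.null(alt)) { der[cd] <- alt; placed_n <- placed_n + 1L }
    }
    if (placed_s < n_syn || placed_n < n_non) {
      stop("could not place all substitutions without stop codons")
    }
    seq_a[i] <- paste(anc, collapse = "")
    seq_b[i] <- paste(der, collapse = "")
  }
  pairs <- tibble(pair_id = pair_ids, seq_a = seq_a, seq_b = seq_b)
  truth <- tibble(
    pair_id = pair_ids, true_ks = true_ks, true_ka = true_ka,
    codon_count = codon_count,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  list(pairs = pairs, truth = truth)
}
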