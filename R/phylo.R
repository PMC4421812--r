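#' Pairwise p-distance matrix from homozygous SNPs
#'
#' For each pair of samples, the genetic distance is the proportion of
#' differing sites among sites where both samples carry homozygous calls
#' (hom-ref or hom-alt); a heterozygous or missing call in either sample
#' excludes the site for that pair. This is the p-distance convention used
#' for accession-level trees from resequencing data.
#'
#' @param variants A `variant_tbl`.
#' @param samples Optional sample subset (>= 2).
#' @return Symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
snp_distance_matrix <- function(variants, samples = NULL) {
  samples <- samples %||% variant_samples(variants)
  if (length(samples) < 2) stop("need >= 2 samples for a distance matrix")
  unknown <- setdiff(samples, variant_samples(variants))
  if (length(unknown) > 0) {
    stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  }
  g <- as.matrix(variants[, samples, drop = FALSE])
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  hom <- !is.na(g) & (g == 0L | g == 2L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- hom[, i] & hom[, j]
      n_ok <- sum(ok)
      if (n_ok == 0) {
        stop(
          "no comparable homozygous sites between ",
          samples[i], " and ", samples[j]
        )
      }
      d[i, j] <- d[j, i] <- sum(g[ok, i] != g[ok, j]) / n_ok
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Classical Saitou-Nei agglomeration: repeatedly join the pair minimising
#' the Q-criterion, with branch lengths from the standard three-point
#' formulas. Ties in Q are broken towards the lexicographically smallest
#' label pair, so the result is invariant to input row order. Negative
#' branch lengths are clamped to zero with the deficit transferred to the
#' sister branch (total path length preserved).
#'
#' @param d Symmetric distance matrix with labels and zero diagonal (>= 3).
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  if (nrow(d) < 3) stop("neighbour joining needs >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")

  labels <- rownames(d)
  frag <- labels                     # newick fragment per active node
  key <- labels                      # lexicographic tie-break key per node
  clamp <- function(l1, l2) {
    if (l1 < 0) { l2 <- l2 + l1; l1 <- 0 }
    if (l2 < 0) { l1 <- l1 + l2; l2 <- 0 }
    c(max(l1, 0), max(l2, 0))
  }
  fmt <- function(x) sprintf("%.15g", x)

  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 & upper.tri(q), arr.ind = TRUE)
    pair_key <- apply(cand, 1, function(ij) {
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(pair_key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    ll <- clamp(li, lj)
    new_frag <- paste0(
      "(", frag[i], ":", fmt(ll[1]), ",", frag[j], ":", fmt(ll[2]), ")"
    )
    new_key <- min(key[i], key[j])
    d_new <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d_new <- d_new[-c(i, j)]
    d <- rbind(cbind(d, d_new), c(d_new, 0))
    frag <- c(frag[-c(i, j)], new_frag)
    key <- c(key[-c(i, j)], new_key)
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- paste0(
    "(", frag[1], ":", fmt(max(la, 0)),
    ",", frag[2], ":", fmt(max(lb, 0)),
    ",", frag[3], ":", fmt(max(lc, 0)), ");"
  )
  ape::read.tree(text = newick)
}

#' Neighbour-joining tree with bootstrap support
#'
#' Builds the full-data homozygous-SNP NJ tree, then resamples SNP columns
#' with replacement `n_replicates` times, recomputing the distance matrix
#' and NJ tree per replicate; per-bipartition support (0-100) is attached to
#' the full-data tree's internal nodes. Replicates in which some pair has no
#' comparable site are skipped and counted.
#'
#' @param variants A `variant_tbl`.
#' @param samples Optional sample subset.
#' @param n_replicates Number of bootstrap replicates (default 1000, the
#'   conventional choice for accession trees).
#' @param seed Integer seed.
#' @return A `kelp_nj` list: `tree` (phylo, support as `node.label`),
#'   `support`, `n_valid`, `n_skipped`.
#' @export
bootstrap_support <- function(variants, samples = NULL, n_replicates = 1000,
                              seed = NULL) {
  stopifnot(n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  samples <- samples %||% variant_samples(variants)
  main_tree <- neighbor_joining(snp_distance_matrix(variants, samples))
  n_sites <- nrow(variants)
  reps <- vector("list", n_replicates)
  n_skipped <- 0L
  for (b in seq_len(n_replicates)) {
    idx <- sample.int(n_sites, n_sites, replace = TRUE)
    vt <- variants[idx, , drop = FALSE]
    tr <- tryCatch(
      neighbor_joining(snp_distance_matrix_unsorted(vt, samples)),
      error = function(e) NULL
    )
    if (is.null(tr)) n_skipped <- n_skipped + 1L else reps[[b]] <- tr
  }
  reps <- purrr::compact(reps)
  n_valid <- length(reps)
  if (n_valid == 0) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(main_tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_valid, 1)
  tree <- main_tree
  tree$node.label <- as.character(support)
  out <- list(
    tree = tree, support = support, n_valid = n_valid, n_skipped = n_skipped
  )
  class(out) <- "kelp_nj"
  out
}

# Bootstrap resampling duplicates positions, so skip the sortedness check.
snp_distance_matrix_unsorted <- function(variants, samples) {
  vt <- variants
  vt$pos <- seq_len(nrow(vt))  # synthetic strictly-increasing positions
  snp_distance_matrix(new_variant_tbl(vt), samples)
}

#' @export
print.kelp_nj <- function(x, ...) {
  cat(
    "Neighbour-joining tree with bootstrap support\n",
    "  taxa: ", length(x$tree$tip.label),
    ";  valid replicates: ", x$n_valid,
    ";  skipped: ", x$n_skipped, "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy kelp_nj
#' @export
tidy.kelp_nj <- function(x, ...) {
  tr <- x$tree
  n_tip <- length(tr$tip.label)
  child <- tr$edge[, 2]
  is_tip <- child <= n_tip
  label <- character(length(child))
  label[is_tip] <- tr$tip.label[child[is_tip]]
  label[!is_tip] <- paste0("node_", child[!is_tip])
  support <- rep(NA_real_, length(child))
  support[!is_tip] <-
    suppressWarnings(as.numeric(tr$node.label[child[!is_tip] - n_tip]))
  tibble(
    parent = tr$edge[, 1],
    node = child,
    label = label,
    branch_length = tr$edge.length,
    support = support
  )
}

#' @method glance kelp_nj
#' @export
glance.kelp_nj <- function(x, ...) {
  tibble(
    n_taxa = length(x$tree$tip.label),
    n_valid_replicates = x$n_valid,
    n_skipped_replicates = x$n_skipped,
    min_support = min(x$support),
    mean_support = mean(x$support)
  )
}
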