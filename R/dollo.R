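#' Dollo parsimony gain/loss reconstruction of gene families
#'
#' Under Dollo parsimony each family is gained exactly once and can only be
#' lost thereafter. For every family the gain is placed on the branch above
#' the most recent common ancestor of all possessing taxa, and the losses
#' are the minimal set of branches — the roots of the maximal absent
#' subtrees under the gain node — explaining all absences. This single-gain
#' placement is the unique minimal-loss reconstruction.
#'
#' Branches are identified by their child node: tip labels for terminal
#' branches, `node_<k>` for internal ones; a gain above the root is reported
#' on the root's own node id (the "root branch").
#'
#' @param presence Logical (or 0/1) matrix, families x taxa; taxon columns
#'   must match the tree's leaf set exactly. Counts are accepted and
#'   converted with [as_presence()].
#' @param tree Rooted [ape::phylo] species tree.
#' @return A `dollo_map` list: `per_family` (tibble with `family_id`,
#'   `gain_node`, `gain_label`, `n_losses`, `loss_nodes` list-column),
#'   `per_branch` (tibble `node`, `label`, `n_gained`, `n_lost`), `tree`,
#'   and `n_skipped` (families absent everywhere).
#' @export
dollo_reconstruct <- function(presence, tree) {
  if (!ape::is.rooted(tree)) stop("Dollo reconstruction requires a rooted tree")
  presence <- as_presence(as.matrix(presence))
  tips <- tree$tip.label
  if (!setequal(colnames(presence), tips)) {
    stop("presence matrix taxa do not match the tree's leaf set")
  }
  presence <- presence[, tips, drop = FALSE]
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])

  # postorder tip-descendant bitmap per node
  desc <- matrix(FALSE, n_node, n_tip)
  desc[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (nd in rev(root:n_node)) {
    for (ch in kids[[as.character(nd)]]) desc[nd, ] <- desc[nd, ] | desc[ch, ]
  }
  parent <- integer(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  node_label <- c(tips, paste0("node_", (n_tip + 1L):n_node))

  fam_ids <- rownames(presence) %||% paste0("fam", seq_len(nrow(presence)))
  gain_node <- integer(nrow(presence))
  loss_nodes <- vector("list", nrow(presence))
  skip <- logical(nrow(presence))
  for (f in seq_len(nrow(presence))) {
    pv <- presence[f, ]
    if (!any(pv)) { skip[f] <- TRUE; next }
    g <- if (sum(pv) == 1) which(pv) else mrca_node(tree, which(pv), desc, root)
    gain_node[f] <- g
    # maximal absent subtrees strictly below the gain node
    losses <- integer(0)
    if (g > n_tip) {
      stack <- kids[[as.character(g)]]
      while (length(stack) > 0) {
        nd <- stack[1]; stack <- stack[-1]
        if (!any(pv & desc[nd, ])) {
          losses <- c(losses, nd)
        } else if (nd > n_tip) {
          stack <- c(stack, kids[[as.character(nd)]])
        }
      }
    }
    loss_nodes[[f]] <- sort(losses)
  }
  if (any(skip)) {
    warning(sum(skip), " family(ies) absent from all taxa skipped")
  }
  keep <- !skip
  per_family <- tibble(
    family_id = fam_ids[keep],
    gain_node = gain_node[keep],
    gain_label = node_label[gain_node[keep]],
    n_losses = lengths(loss_nodes[keep]),
    loss_nodes = loss_nodes[keep]
  )
  all_losses <- unlist(per_family$loss_nodes)
  per_branch <- tibble(
    node = seq_len(n_node),
    label = node_label,
    n_gained = tabulate(per_family$gain_node, nbins = n_node),
    n_lost = tabulate(all_losses, nbins = n_node)
  )
  out <- list(
    per_family = per_family, per_branch = per_branch,
    tree = tree, n_skipped = sum(skip)
  )
  class(out) <- "dollo_map"
  out
}

# MRCA via the tip-descendant bitmap: smallest clade containing all tips.
mrca_node <- function(tree, tip_idx, desc, root) {
  n_tip <- length(tree$tip.label)
  cover <- which(apply(desc[, tip_idx, drop = FALSE], 1, all))
  cover[which.min(rowSums(desc[cover, , drop = FALSE]))]
}

#' @export
print.dollo_map <- function(x, ...) {
  cat(
    "Dollo gain/loss reconstruction\n",
    "  families: ", nrow(x$per_family),
    ";  total losses: ", sum(x$per_family$n_losses),
    ";  skipped (absent everywhere): ", x$n_skipped, "\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy dollo_map
#' @export
tidy.dollo_map <- function(x, ...) x$per_branch

#' @method glance dollo_map
#' @export
glance.dollo_map <- function(x, ...) {
  tibble(
    n_families = nrow(x$per_family),
    total_gains = sum(x$per_branch$n_gained),
    total_losses = sum(x$per_branch$n_lost),
    n_skipped = x$n_skipped
  )
}
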