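# Independent oracles used across the suite. Each re-derives a quantity by a
# route the implementation does not take: brute force, enumeration, or closed
# form.

# Mean pairwise difference count over all haplotype pairs (no missing data).
oracle_pairwise_pi <- function(hap) {
  n <- nrow(hap)
  if (n < 2) return(NA_real_)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(hap[i, ] != hap[j, ])
    }
  }
  total / choose(n, 2)
}

# Two-sided Fisher p by exhaustive hypergeometric enumeration over the
# tables compatible with the observed margins (minimum-likelihood rule,
# with the standard relative-error tie tolerance).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up, executed literally.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Minimal-loss single-gain Dollo reconstruction by exhaustive search over
# every possible gain branch (root stem + all edges).
oracle_dollo <- function(tree, present_tips) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- matrix(FALSE, n_node, n_tip)
  desc[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (nd in rev(root:n_node)) {
    for (ch in kids[[as.character(nd)]]) desc[nd, ] <- desc[nd, ] | desc[ch, ]
  }
  pv <- logical(n_tip)
  pv[present_tips] <- TRUE
  losses_under <- function(g) {
    if (any(pv & !desc[g, ])) return(NULL)  # a possessing tip outside the clade
    n_loss <- 0L
    if (g > n_tip) {
      stack <- kids[[as.character(g)]]
      while (length(stack) > 0) {
        nd <- stack[1]; stack <- stack[-1]
        if (!any(pv & desc[nd, ])) {
          n_loss <- n_loss + 1L
        } else if (nd > n_tip) {
          stack <- c(stack, kids[[as.character(nd)]])
        }
      }
    } else if (!pv[g]) {
      return(NULL)
    }
    n_loss
  }
  cand <- unique(c(root, tree$edge[, 2]))
  best_gain <- NA_integer_
  best_losses <- Inf
  for (g in cand) {
    nl <- losses_under(g)
    if (!is.null(nl) && nl < best_losses) {
      best_losses <- nl
      best_gain <- g
    }
  }
  list(gain = best_gain, n_losses = best_losses)
}

# NG86 re-derivation (independent coding of sites + pathway averaging).
oracle_ng86 <- function(a, b) {
  gcode <- Biostrings::GENETIC_CODE
  codons <- function(s) {
    substring(toupper(s), seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  syn_frac <- function(cd) {
    s <- 0
    for (pos in 1:3) {
      for (nb in setdiff(c("A", "C", "G", "T"), substr(cd, pos, pos))) {
        alt <- cd
        substr(alt, pos, pos) <- nb
        if (gcode[[alt]] != "*" && gcode[[alt]] == gcode[[cd]]) s <- s + 1
      }
    }
    s / 3
  }
  path_counts <- function(c1, c2) {
    if (c1 == c2) return(c(0, 0))
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    perms <- if (length(pos) == 1) list(pos) else {
      if (length(pos) == 2) {
        list(pos, rev(pos))
      } else {
        out <- list()
        for (i in 1:3) for (j in setdiff(1:3, i)) {
          out[[length(out) + 1]] <- pos[c(i, j, setdiff(1:3, c(i, j)))]
        }
        out
      }
    }
    eval_path <- function(ord, allow_stop) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (!allow_stop && gcode[[nxt]] == "*") return(NULL)
        if (gcode[[nxt]] == gcode[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- Filter(Negate(is.null), lapply(perms, eval_path, allow_stop = FALSE))
    if (length(res) == 0) {
      res <- Filter(Negate(is.null), lapply(perms, eval_path, allow_stop = TRUE))
    }
    colMeans(do.call(rbind, res))
  }
  ca <- codons(a); cb <- codons(b)
  S <- mean(c(sum(vapply(ca, syn_frac, 0)), sum(vapply(cb, syn_frac, 0))))
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca), function(i) path_counts(ca[i], cb[i]),
                      numeric(2)))
  ps <- d[1] / S
  pn <- d[2] / N
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(Sd = d[1], Nd = d[2], S = S, N = N, Ks = jc(ps), Ka = jc(pn))
}

# Additive distance matrix of a random unrooted tree (path-length metric);
# caller controls the RNG state.
oracle_additive_metric <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.1, 2))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# Sort-and-interpolate empirical quantile (linear between order statistics).
oracle_quantile <- function(x, q) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Interval overlap by brute force on integer coordinates.
oracle_overlaps <- function(region, genes) {
  hits <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != region$chrom) next
    cells_g <- seq(g$start, g$end - 1)
    cells_r <- seq(region$start, region$end - 1)
    if (length(intersect(cells_g, cells_r)) > 0) hits <- c(hits, g$gene_id)
  }
  hits
}
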