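test_that("homozygous-SNP distances follow the site-enumeration rule", {
  # 4 sites: (hom-ref/hom-alt), (het/hom-ref), (hom-alt/hom-alt),
  # (missing/hom-ref) -> comparable {1,3}, one difference -> 1/2
  vt <- kelpscan:::new_variant_tbl(tibble::tibble(
    chrom = "c", pos = 0:3, ref = "A", alt = "T",
    x = c(0L, 1L, 2L, NA), y = c(2L, 0L, 2L, 0L)
  ))
  d <- snp_distance_matrix(vt)
  expect_equal(d["x", "y"], 0.5)
  expect_equal(d["y", "x"], 0.5)
  expect_equal(diag(d), c(x = 0, y = 0))

  same <- kelpscan:::new_variant_tbl(tibble::tibble(
    chrom = "c", pos = 0:2, ref = "A", alt = "T",
    x = c(0L, 2L, 0L), y = c(0L, 2L, 0L)
  ))
  expect_true(all(snp_distance_matrix(same) == 0))

  none <- kelpscan:::new_variant_tbl(tibble::tibble(
    chrom = "c", pos = 0:1, ref = "A", alt = "T",
    x = c(1L, NA), y = c(0L, 0L)
  ))
  expect_error(snp_distance_matrix(none), "x and y")
})

test_that("distance matrices are symmetric with zero diagonal on random data", {
  sim <- simulate_coalescent(12, theta = 8, n_windows = 10, seed = 119)
  d <- snp_distance_matrix(sim$variants)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_true(all(is.finite(d)))
})

test_that("three-taxon NJ solves the three-point equations", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 2, C = 3))
})

test_that("NJ exactly recovers additive metrics (consistency property)", {
  skip_if_not_installed("phangorn")
  set.seed(1234)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    truth <- oracle_additive_metric(n)
    est <- neighbor_joining(truth$d)
    expect_equal(phangorn::RF.dist(est, truth$tree), 0)
    labs <- rownames(truth$d)
    expect_equal(ape::cophenetic.phylo(est)[labs, labs], truth$d,
                 tolerance = 1e-9)
  }
})

test_that("NJ agrees with the reference implementation on additive input", {
  set.seed(77)
  truth <- oracle_additive_metric(8)
  mine <- neighbor_joining(truth$d)
  reference <- ape::nj(truth$d)
  expect_equal(as.numeric(ape::dist.topo(mine, reference)), 0)
})

test_that("NJ output is invariant to input label order", {
  set.seed(303)
  truth <- oracle_additive_metric(7)
  perm <- sample(rownames(truth$d))
  t1 <- neighbor_joining(truth$d)
  t2 <- neighbor_joining(truth$d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
})

test_that("NJ rejects degenerate matrices and clamps negative branches", {
  bad <- matrix(c(0, 1, 2, 9, 0, 1, 2, 1, 0), 3, 3)
  expect_error(neighbor_joining(bad), "symmetric")
  expect_error(neighbor_joining(matrix(0, 2, 2)), ">= 3")
  # non-additive matrix engineered to push a length negative: all lengths >= 0
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["a", "c"] <- d["c", "a"] <- 1
  d["b", "c"] <- d["c", "b"] <- 0.2
  d["a", "d"] <- d["d", "a"] <- 1
  d["b", "d"] <- d["d", "b"] <- 1
  d["c", "d"] <- d["d", "c"] <- 0.15
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap gives full support to the cultivated/wild split", {
  tp <- simulate_two_pop(
    n_wild = 5, n_cultivated = 4, theta = 8, n_windows = 120, seed = 131
  )
  bs <- bootstrap_support(tp$variants, n_replicates = 50, seed = 132)
  cult <- tp$pops$sample[tp$pops$population == "cultivated"]
  node <- ape::getMRCA(bs$tree, cult)
  clade_tips <- bs$tree$tip.label[
    phangorn::Descendants(bs$tree, node, "tips")[[1]]
  ]
  expect_setequal(clade_tips, cult)  # cultivated samples are monophyletic
  n_tip <- length(bs$tree$tip.label)
  expect_equal(bs$support[node - n_tip], 100)
})

test_that("single-replicate supports are 0/100 and seeds reproduce exactly", {
  sim <- simulate_coalescent(10, theta = 10, n_windows = 30, seed = 141)
  one <- bootstrap_support(sim$variants, n_replicates = 1, seed = 5)
  expect_true(all(one$support %in% c(0, 100)))
  a <- bootstrap_support(sim$variants, n_replicates = 20, seed = 6)
  b <- bootstrap_support(sim$variants, n_replicates = 20, seed = 6)
  expect_identical(a$support, b$support)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
})

test_that("tidy/glance expose the NJ tree as tables", {
  sim <- simulate_coalescent(8, theta = 10, n_windows = 20, seed = 151)
  bs <- bootstrap_support(sim$variants, n_replicates = 10, seed = 7)
  td <- tidy(bs)
  expect_true(all(c("parent", "node", "branch_length", "support") %in% names(td)))
  expect_equal(nrow(td), nrow(bs$tree$edge))
  gl <- glance(bs)
  expect_equal(gl$n_valid_replicates, 10)
})

test_that("Dollo places trivial families on the expected branches", {
  tree <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  pres <- rbind(
    all  = c(A = TRUE, B = TRUE, C = TRUE, D = TRUE),
    one  = c(A = FALSE, B = FALSE, C = TRUE, D = FALSE),
    abd  = c(A = TRUE, B = TRUE, C = FALSE, D = TRUE)
  )
  dm <- dollo_reconstruct(pres, tree)
  root <- ape::Ntip(tree) + 1L
  expect_equal(dm$per_family$gain_node[1], root)
  expect_equal(dm$per_family$n_losses[1], 0L)
  expect_equal(dm$per_family$gain_label[2], "C")
  expect_equal(dm$per_family$gain_node[3], root)
  expect_equal(dm$per_family$n_losses[3], 1L)
  expect_equal(dm$per_family$loss_nodes[[3]], which(tree$tip.label == "C"))
  # matches exhaustive single-gain search
  oc <- oracle_dollo(tree, which(pres["abd", ]))
  expect_equal(dm$per_family$gain_node[3], oc$gain)
  expect_equal(dm$per_family$n_losses[3], oc$n_losses)
})

test_that("Dollo equals exhaustive minimal-loss search on random trees", {
  set.seed(2025)
  for (rep in 1:60) {
    n <- sample(5:8, 1)
    tree <- ape::rtree(n)
    n_present <- sample(1:n, 1)
    present <- sort(sample(n, n_present))
    pres <- matrix(FALSE, 1, n, dimnames = list("f", tree$tip.label))
    pres[1, present] <- TRUE
    dm <- suppressWarnings(dollo_reconstruct(pres, tree))
    oc <- oracle_dollo(tree, present)
    expect_equal(dm$per_family$gain_node, oc$gain)
    expect_equal(dm$per_family$n_losses, oc$n_losses)
  }
})

test_that("Dollo recovers simulated gains at low loss intensity", {
  tree <- read_newick(paste0(
    "(((Sjap:0.3,Esil:0.3):0.3,Ngad:0.3):0.3,",
    "((Ptri:0.3,Tpse:0.3):0.3,(Fcyl:0.3,Pmul:0.3):0.3):0.3);"
  ))
  fam <- simulate_family_evolution(tree, 2000, loss_rate = 0.01, seed = 161)
  dm <- suppressWarnings(dollo_reconstruct(fam$presence, tree))
  truth <- fam$truth[match(dm$per_family$family_id, fam$truth$family_id), ]
  recovery <- mean(dm$per_family$gain_node == truth$gain_node)
  expect_gte(recovery, 0.99)
  # conservation: one gain per surviving family
  expect_equal(sum(tidy(dm)$n_gained), nrow(dm$per_family))
})

test_that("families absent everywhere are skipped with a warning", {
  tree <- read_newick("((A:1,B:1):1,C:2);")
  pres <- matrix(c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE), 2, 3,
                 byrow = TRUE, dimnames = list(c("gone", "ab"), c("A", "B", "C")))
  expect_warning(dm <- dollo_reconstruct(pres, tree), "skipped")
  expect_equal(nrow(dm$per_family), 1)
  expect_equal(dm$n_skipped, 1L)
  expect_error(dollo_reconstruct(pres, ape::unroot(tree)), "rooted")
})
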