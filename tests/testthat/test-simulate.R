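test_that("segregating sites match Watterson's expectation E[S] = theta a1", {
  # n = 2: a1 = 1, so E[S] = theta exactly
  sim2 <- simulate_coalescent(2, theta = 5, n_windows = 2000, seed = 101)
  s2 <- sim2$truth$S
  se2 <- sd(s2) / sqrt(length(s2))
  expect_lt(abs(mean(s2) - 5), 5 * se2)

  # n = 10, theta = 10: E[S] = 10 * a1(10)
  sim10 <- simulate_coalescent(10, theta = 10, n_windows = 2000, seed = 102)
  a1 <- sum(1 / (1:9))
  s10 <- sim10$truth$S
  se10 <- sd(s10) / sqrt(length(s10))
  expect_lt(abs(mean(s10) - 10 * a1), 5 * se10)
})

test_that("coalescent output is byte-identical under a fixed seed", {
  a <- simulate_coalescent(6, theta = 4, n_windows = 10, seed = 9)
  b <- simulate_coalescent(6, theta = 4, n_windows = 10, seed = 9)
  expect_identical(a$haplotypes, b$haplotypes)
  expect_identical(as.data.frame(a$variants), as.data.frame(b$variants))

  c1 <- simulate_coalescent(6, theta = 4, n_windows = 10, seed = 10)
  expect_false(identical(a$haplotypes, c1$haplotypes))
  expect_identical(names(a$truth), names(c1$truth))  # same truth schema
})

test_that("mutation columns are polymorphic with positions inside the window", {
  sim <- simulate_coalescent(12, theta = 8, n_windows = 30, seed = 77,
                             window_length = 500)
  for (hap in sim$haplotypes) {
    if (ncol(hap) == 0) next
    counts <- colSums(hap)
    expect_true(all(counts >= 1 & counts <= nrow(hap) - 1))
    pos <- attr(hap, "positions")
    expect_true(all(pos >= 0 & pos < 500))
    expect_false(is.unsorted(pos, strictly = TRUE))
  }
})

test_that("exchangeable populations show no diversity contrast at severity 1", {
  tp <- simulate_two_pop(
    n_wild = 5, n_cultivated = 5, theta = 5, bottleneck_severity = 1,
    split_time = 0.1, n_windows = 500, seed = 21
  )
  lens <- setNames(rep(10000, 500), paste0("w", 1:500))
  pw <- sliding_scan(tp$variants, 10000, 10000,
                     samples = tp$pops$sample[tp$pops$population == "wild"],
                     chrom_lengths = lens)
  pc <- sliding_scan(tp$variants, 10000, 10000,
                     samples = tp$pops$sample[tp$pops$population == "cultivated"],
                     chrom_lengths = lens)
  diff_pi <- mean(pw$pi) - mean(pc$pi)
  se <- sd(pw$pi - pc$pi) / sqrt(nrow(pw))
  expect_lt(abs(diff_pi), 5 * se)
})

test_that("a severe bottleneck depresses cultivated diversity", {
  tp <- simulate_two_pop(n_windows = 200, seed = 31)  # defaults: severity 0.05
  lens <- setNames(rep(10000, 200), paste0("w", 1:200))
  pw <- sliding_scan(tp$variants, 10000, 10000,
                     samples = tp$pops$sample[tp$pops$population == "wild"],
                     chrom_lengths = lens)
  pc <- sliding_scan(tp$variants, 10000, 10000,
                     samples = tp$pops$sample[tp$pops$population == "cultivated"],
                     chrom_lengths = lens)
  expect_lt(mean(pc$pi), mean(pw$pi))
})

test_that("TE decay substitutes at the Jukes-Cantor-inverse rate", {
  te0 <- simulate_te_decay(500, copy_ages = c(0, 0), seed = 5)
  expect_identical(te0$alignments$copy[1], te0$alignments$consensus[1])

  te <- simulate_te_decay(10000, copy_ages = rep(0.10, 5), seed = 6)
  p_expected <- 0.75 * (1 - exp(-0.4 / 3))
  p_obs <- vapply(
    seq_len(5),
    function(i) p_distance(te$alignments$copy[i], te$alignments$consensus[i]),
    numeric(1)
  )
  se <- sqrt(p_expected * (1 - p_expected) / 10000)
  expect_lt(abs(mean(p_obs) - p_expected), 3 * se)

  expect_error(simulate_te_decay(100, copy_ages = -0.1), "negative")
})

test_that("TE fragments are gap-flanked to the requested fraction", {
  te <- simulate_te_decay(1000, copy_ages = rep(0.05, 4),
                          fragment_fraction = 0.4, seed = 8)
  n_gap <- stringr::str_count(te$alignments$copy, stringr::fixed("-"))
  expect_true(all(n_gap == 600))
  # p-distance unaffected by truncation (gap columns excluded)
  p <- p_distance(te$alignments$copy[1], te$alignments$consensus[1])
  expect_true(p >= 0 && p < 0.2)
})

test_that("family evolution without loss places families exactly on clades", {
  tree <- default_species_tree()
  fam <- simulate_family_evolution(tree, 200, loss_rate = 0, seed = 12)
  desc_tips <- function(node) {
    if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
    tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
  }
  for (f in seq_len(200)) {
    clade <- desc_tips(fam$truth$gain_node[f])
    expect_setequal(colnames(fam$presence)[fam$presence[f, ]], clade)
  }
})

test_that("root gains with zero loss give an all-ones presence row", {
  tree <- default_species_tree()
  fam <- simulate_family_evolution(tree, 400, loss_rate = 0, seed = 13)
  root <- ape::Ntip(tree) + 1L
  at_root <- fam$truth$gain_node == root
  expect_gt(sum(at_root), 0)
  expect_true(all(fam$presence[at_root, ]))
  expect_error(
    simulate_family_evolution(ape::unroot(tree), 10, seed = 1), "rooted"
  )
})

test_that("simulated host contigs match the target GC content", {
  ct <- simulate_contigs(n_host = 30, n_bacterial = 5, host_gc = 0.5,
                         seed = 15)
  host_gc <- gc_content(ct$sequence[ct$true_origin == "host"])
  expect_lt(abs(mean(host_gc) - 0.5), 0.02)
  expect_error(simulate_contigs(length_range = c(500, 100)), "length_range")
})

test_that("fully coding bacterial contigs have ORF density near 1", {
  # lengths are whole ORF blocks, so the construction is exactly coding
  ct <- simulate_contigs(n_host = 1, n_bacterial = 5, coding_density = 1,
                         length_range = c(1800, 1800), seed = 16)
  dens <- vapply(ct$sequence[ct$true_origin == "bacterial"], orf_density,
                 numeric(1))
  expect_true(all(dens >= 0.99))
})

test_that("paralog pairs with only synonymous divergence give Ka = 0 exactly", {
  pp <- simulate_paralog_pairs(n_pairs = 3, true_ks = 0.4, true_ka = 0,
                               codon_count = 300, seed = 17)
  for (i in 1:3) {
    res <- ng86_ka_ks(pp$pairs$seq_a[i], pp$pairs$seq_b[i])
    expect_identical(res$Ka, 0)
    expect_gt(res$Ks, 0)
  }
  same <- simulate_paralog_pairs(n_pairs = 2, true_ks = 0, true_ka = 0,
                                 codon_count = 150, seed = 18)
  expect_identical(same$pairs$seq_a, same$pairs$seq_b)
})
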