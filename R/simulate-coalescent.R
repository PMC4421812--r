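#' Piecewise-constant demography
#'
#' Describes the (relative) population size history used by the coalescent
#' simulator, as epochs looking backwards in time in coalescent units of the
#' reference size. `demography()` with no arguments is the constant-size
#' equilibrium model.
#'
#' @param time Epoch start times (backwards from the present); must begin at 0
#'   and be strictly increasing.
#' @param size Relative population sizes per epoch; all positive.
#' @return A tibble with class `demography`.
#' @export
demography <- function(time = 0, size = 1) {
  stopifnot(length(time) == length(size))
  if (time[1] != 0) stop("first epoch must start at time 0")
  if (any(diff(time) <= 0)) stop("epoch times must be strictly increasing")
  if (any(size <= 0)) stop("population sizes must be positive")
  out <- tibble(time = as.numeric(time), size = as.numeric(size))
  class(out) <- c("demography", class(out))
  out
}

# Simulate one Kingman genealogy for k lineages under a piecewise-constant
# size history. Returns a tibble of branches: each row one branch with its
# length and the set of leaves below it (the MRCA's "branch" is not included).
sim_genealogy <- function(k, demog = demography()) {
  stopifnot(k >= 2)
  lineages <- lapply(seq_len(k), identity)   # leaf sets
  starts <- numeric(k)
  t_now <- 0
  epoch_times <- c(demog$time, Inf)
  epoch <- findInterval(t_now, demog$time)
  br_sets <- vector("list", 2 * k - 2)
  br_len <- numeric(2 * k - 2)
  nb <- 0L
  while (length(lineages) > 1) {
    kk <- length(lineages)
    rate <- kk * (kk - 1) / 2 / demog$size[epoch]
    wait <- rexp(1, rate)
    if (t_now + wait > epoch_times[epoch + 1]) {
      t_now <- epoch_times[epoch + 1]
      epoch <- epoch + 1L
      next
    }
    t_now <- t_now + wait
    pair <- sample.int(kk, 2)
    i <- min(pair); j <- max(pair)
    for (idx in c(i, j)) {
      nb <- nb + 1L
      br_sets[[nb]] <- lineages[[idx]]
      br_len[nb] <- t_now - starts[idx]
    }
    lineages[[i]] <- c(lineages[[i]], lineages[[j]])
    starts[i] <- t_now
    lineages <- lineages[-j]
    starts <- starts[-j]
  }
  tibble(length = br_len[seq_len(nb)], leaves = br_sets[seq_len(nb)])
}

# Structured genealogy: two demes without migration that merge (backwards in
# time) at split_time. Deme 1 = wild (size 1), deme 2 = cultivated
# (size = severity). Leaves 1..k1 are wild, k1+1..k1+k2 cultivated.
sim_genealogy_2pop <- function(k1, k2, severity, split_time) {
  stopifnot(k1 >= 1, k2 >= 1, severity > 0, split_time > 0)
  lineages <- lapply(seq_len(k1 + k2), identity)
  deme <- c(rep(1L, k1), rep(2L, k2))
  starts <- numeric(k1 + k2)
  t_now <- 0
  merged <- FALSE
  br_sets <- list()
  br_len <- numeric(0)
  sizes <- c(1, severity)
  while (length(lineages) > 1) {
    k_by <- tabulate(deme, nbins = 2L)
    rates <- k_by * (k_by - 1) / 2 / sizes
    total <- sum(rates)
    wait <- if (total > 0) rexp(1, total) else Inf
    if (!merged && t_now + wait > split_time) {
      t_now <- split_time
      deme[] <- 1L
      merged <- TRUE
      next
    }
    t_now <- t_now + wait
    d <- sample.int(2L, 1, prob = rates / total)
    members <- which(deme == d)
    pair <- members[sample.int(length(members), 2)]
    i <- min(pair); j <- max(pair)
    for (idx in c(i, j)) {
      br_sets[[length(br_sets) + 1L]] <- lineages[[idx]]
      br_len <- c(br_len, t_now - starts[idx])
    }
    lineages[[i]] <- c(lineages[[i]], lineages[[j]])
    starts[i] <- t_now
    lineages <- lineages[-j]
    starts <- starts[-j]
    deme <- deme[-j]
  }
  tibble(length = br_len, leaves = br_sets)
}

# Drop infinite-sites mutations on a genealogy: Poisson(theta/2 * total
# length) mutations, each on a branch chosen proportionally to length, at
# distinct uniform positions. Returns a haplotype matrix (k x S).
drop_mutations <- function(branches, k, theta, window_length) {
  total_len <- sum(branches$length)
  n_mut <- rpois(1, theta / 2 * total_len)
  if (n_mut > window_length) {
    stop(
      "infinite-sites violation: ", n_mut, " mutations in a window of ",
      window_length, " sites"
    )
  }
  if (n_mut == 0) {
    hap <- matrix(integer(), nrow = k, ncol = 0)
    attr(hap, "positions") <- integer()
    return(hap)
  }
  pos <- sort(sample.int(window_length, n_mut)) - 1L
  which_branch <- sample.int(
    nrow(branches), n_mut, replace = TRUE, prob = branches$length
  )
  hap <- matrix(0L, nrow = k, ncol = n_mut)
  for (m in seq_len(n_mut)) {
    hap[branches$leaves[[which_branch[m]]], m] <- 1L
  }
  attr(hap, "positions") <- pos
  hap
}

#' Simulate neutral coalescent windows
#'
#' Standard Kingman coalescent under an optional piecewise-constant
#' demography, with infinite-sites mutation at rate theta/2 per unit branch
#' length, one independent genealogy per window. Windows are emitted as
#' separate chromosomes (`w1`, `w2`, ...) so the whole simulation can flow
#' through [sliding_scan()] unchanged. For even `n_alleles`, consecutive
#' haplotypes are paired into diploid genotypes and a variant table is
#' returned alongside the haplotype matrices.
#'
#' @param n_alleles Number of sampled allele copies per window (>= 2).
#' @param theta Population mutation rate per window (> 0).
#' @param demog A [demography()]; default constant size.
#' @param n_windows Number of independent windows.
#' @param window_length Window length in bp (infinite-sites capacity).
#' @param seed Integer seed; required for reproducible output.
#' @param sample_prefix Prefix for diploid sample names.
#' @return A list with elements `haplotypes` (list of per-window matrices),
#'   `variants` (a `variant_tbl`, or `NULL` when `n_alleles` is odd),
#'   and `truth` (tibble recording seed, theta and per-window S).
#' @export
simulate_coalescent <- function(n_alleles, theta, demog = demography(),
                                n_windows = 1, window_length = 10000,
                                seed = NULL, sample_prefix = "s") {
  stopifnot(n_alleles >= 2, theta > 0, n_windows >= 1)
  if (!is.null(seed)) set.seed(seed)
  haps <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    branches <- sim_genealogy(n_alleles, demog)
    hap <- drop_mutations(branches, n_alleles, theta, window_length)
    attr(hap, "chrom") <- paste0("w", w)
    haps[[w]] <- hap
  }
  variants <- NULL
  if (n_alleles %% 2 == 0) {
    sample_ids <- paste0(sample_prefix, seq_len(n_alleles %/% 2))
    variants <- purrr::map(haps, haplotypes_to_variants, sample_ids = sample_ids) |>
      list_rbind()
    variants <- new_variant_tbl(variants)
  }
  truth <- tibble(
    window = seq_len(n_windows),
    chrom = paste0("w", seq_len(n_windows)),
    theta = theta,
    n_alleles = n_alleles,
    S = vapply(haps, ncol, integer(1)),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  list(haplotypes = haps, variants = variants, truth = truth)
}

#' Simulate a wild and a recently bottlenecked cultivated population
#'
#' Joint structured coalescent for two populations of one species: a wild
#' population at equilibrium (relative size 1) and a cultivated lineage that
#' split from it `split_time` coalescent units ago and has since had relative
#' size `bottleneck_severity`. There is no migration after the split. The
#' severe recent bottleneck makes cultivated within-population diversity
#' lower than wild diversity, the contrast the sweep scan is designed around.
#'
#' @param n_wild,n_cultivated Numbers of diploid individuals (defaults: the
#'   9 wild and 7 cultivated individuals of a kelp resequencing design).
#' @param theta Population mutation rate per window for the wild/reference
#'   size.
#' @param bottleneck_severity Cultivated relative size in (0, 1].
#' @param split_time Time of the split, coalescent units (> 0).
#' @param n_windows,window_length,seed As in [simulate_coalescent()].
#' @return A list: `variants` (combined `variant_tbl`, samples `wild1..`,
#'   `cult1..`), `pops` (tibble sample/population), `haplotypes` (per-window
#'   matrices over all allele copies), and `truth`.
#' @export
simulate_two_pop <- function(n_wild = 9, n_cultivated = 7, theta = 10,
                             bottleneck_severity = 0.05, split_time = 0.1,
                             n_windows = 200, window_length = 10000,
                             seed = NULL) {
  stopifnot(
    n_wild >= 1, n_cultivated >= 1, theta > 0,
    bottleneck_severity > 0, bottleneck_severity <= 1, split_time > 0
  )
  if (!is.null(seed)) set.seed(seed)
  k1 <- 2L * n_wild
  k2 <- 2L * n_cultivated
  k <- k1 + k2
  sample_ids <- c(
    paste0("wild", seq_len(n_wild)), paste0("cult", seq_len(n_cultivated))
  )
  haps <- vector("list", n_windows)
  for (w in seq_len(n_windows)) {
    branches <- sim_genealogy_2pop(k1, k2, bottleneck_severity, split_time)
    hap <- drop_mutations(branches, k, theta, window_length)
    attr(hap, "chrom") <- paste0("w", w)
    haps[[w]] <- hap
  }
  variants <- purrr::map(haps, haplotypes_to_variants, sample_ids = sample_ids) |>
    list_rbind()
  variants <- new_variant_tbl(variants)
  pops <- tibble(
    sample = sample_ids,
    population = c(rep("wild", n_wild), rep("cultivated", n_cultivated))
  )
  truth <- tibble(
    n_wild = n_wild, n_cultivated = n_cultivated, theta = theta,
    bottleneck_severity = bottleneck_severity, split_time = split_time,
    n_windows = n_windows, window_length = window_length,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  list(variants = variants, pops = pops, haplotypes = haps, truth = truth)
}
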