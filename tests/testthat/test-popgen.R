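test_that("Tajima constants match independent arithmetic", {
  # n = 2: degenerate variance
  k2 <- tajima_constants(2)
  expect_equal(k2$a1, 1, tolerance = 1e-12)
  expect_equal(k2$a2, 1, tolerance = 1e-12)
  expect_equal(abs(k2$c1) + abs(k2$c2) + abs(k2$e1) + abs(k2$e2), 0,
               tolerance = 1e-12)

  # n = 4 by hand
  k4 <- tajima_constants(4)
  a1 <- 1 + 1 / 2 + 1 / 3
  a2 <- 1 + 1 / 4 + 1 / 9
  b1 <- 5 / 9
  b2 <- 2 * (16 + 4 + 3) / (9 * 4 * 3)
  c1 <- b1 - 1 / a1
  c2 <- b2 - 6 / (a1 * 4) + a2 / a1^2
  expect_equal(k4$a1, a1, tolerance = 1e-12)
  expect_equal(k4$a2, a2, tolerance = 1e-12)
  expect_equal(k4$c1, c1, tolerance = 1e-12)
  expect_equal(k4$c2, c2, tolerance = 1e-12)
  expect_equal(k4$e1, c1 / a1, tolerance = 1e-12)
  expect_equal(k4$e2, c2 / (a1^2 + a2), tolerance = 1e-12)

  # n = 100: harmonic asymptotics, positive variance coefficients
  k100 <- tajima_constants(100)
  expect_gt(k100$e1, 0)
  expect_gt(k100$e2, 0)
  expect_lt(abs(k100$a1 - (log(99) + 0.5772156649)) / k100$a1, 0.01)

  expect_error(tajima_constants(1), ">= 2")
})

test_that("window pi equals the brute-force all-pairs mean", {
  hap <- matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L), nrow = 4, byrow = TRUE)
  expect_equal(window_pi(hap), 8 / 6)
  expect_equal(window_pi(hap), oracle_pairwise_pi(hap))

  expect_equal(window_pi(matrix(0L, 5, 3)), 0)  # identical haplotypes
  expect_equal(window_pi(matrix(integer(), 4, 0)), 0)

  all_missing <- matrix(NA_integer_, 4, 2)
  all_missing[1, ] <- 0L
  expect_true(is.nan(window_pi(all_missing)))
})

test_that("frequency-form pi equals pairwise-form pi on complete windows", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    s <- sample(1:30, 1)
    hap <- matrix(rbinom(n * s, 1, runif(1, 0.1, 0.9)), nrow = n)
    storage.mode(hap) <- "integer"
    expect_equal(window_pi(hap), oracle_pairwise_pi(hap), tolerance = 1e-10)
  }
})

test_that("Watterson's theta is S over the harmonic number", {
  expect_equal(window_theta_w(0, 10), 0)
  expect_equal(window_theta_w(5, 2), 5)
  expect_equal(window_theta_w(11, 4), 6)
})

test_that("Tajima's D matches direct formula evaluation", {
  expect_equal(tajimas_d(6 / 11 * 2, 2, 4), 0)  # pi == theta_w
  k <- tajima_constants(4)
  expected <- (4 / 3 - 2 / k$a1) / sqrt(k$e1 * 2 + k$e2 * 2 * 1)
  expect_equal(tajimas_d(4 / 3, 2, 4), expected, tolerance = 1e-12)
  expect_equal(round(expected, 2), 1.89)
  expect_true(is.na(tajimas_d(1, 0, 10)))
  expect_true(is.na(tajimas_d(1, 3, 2)))
})

test_that("neutral equilibrium windows give mean D near zero and unbiased pi", {
  sim <- simulate_coalescent(20, theta = 10, n_windows = 2000, seed = 401)
  lens <- setNames(rep(10000, 2000), paste0("w", 1:2000))
  scan <- sliding_scan(sim$variants, 10000, 10000, chrom_lengths = lens)
  expect_equal(nrow(scan), 2000)
  d <- scan$D[is.finite(scan$D)]
  expect_gt(mean(d), -0.15)
  expect_lt(mean(d), 0.15)
  # pi unbiased for theta
  se_pi <- sd(scan$pi) / sqrt(nrow(scan))
  expect_lt(abs(mean(scan$pi) - 10), 5 * se_pi)
  # theta_w unbiased for theta
  se_tw <- sd(scan$theta_w) / sqrt(nrow(scan))
  expect_lt(abs(mean(scan$theta_w) - 10), 5 * se_tw)
})

test_that("window tiling follows the start-step rule with partials kept", {
  vt <- kelpscan:::new_variant_tbl(tibble::tibble(
    chrom = "c", pos = c(100L, 12000L, 19000L), ref = "A", alt = "T",
    s1 = c(0L, 2L, 0L), s2 = c(2L, 0L, 2L)
  ))
  one <- sliding_scan(vt, 10000, 10000, chrom_lengths = c(c = 10000))
  expect_equal(nrow(one), 1)

  three <- sliding_scan(vt, 10000, 5000, chrom_lengths = c(c = 20000))
  expect_equal(three$start, c(0, 5000, 10000, 15000))
  expect_equal(three$end, c(10000, 15000, 20000, 20000))
  expect_equal(three$partial, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(three$S, c(1L, 1L, 2L, 1L))

  expect_error(sliding_scan(vt, 100, 200), "window_size")
  expect_error(sliding_scan(vt, samples = "nope"), "unknown sample")
})

test_that("scan on bottleneck data shows the wild > cultivated pi ordering", {
  tp <- simulate_two_pop(n_windows = 80, seed = 55)
  lens <- setNames(rep(10000, 80), paste0("w", 1:80))
  scan_w <- sliding_scan(tp$variants, 10000, 10000,
                         samples = tp$pops$sample[tp$pops$population == "wild"],
                         chrom_lengths = lens)
  scan_c <- sliding_scan(
    tp$variants, 10000, 10000,
    samples = tp$pops$sample[tp$pops$population == "cultivated"],
    chrom_lengths = lens
  )
  expect_lt(mean(scan_c$pi), mean(scan_w$pi))
})

test_that("empirical thresholds use linear interpolation between order stats", {
  thr <- empirical_thresholds(as.numeric(1:100), 0.05)
  expect_equal(unname(thr["low"]), oracle_quantile(1:100, 0.05))
  expect_equal(unname(thr["high"]), oracle_quantile(1:100, 0.95))
  expect_equal(unname(thr["low"]), 5.95)
  expect_equal(unname(thr["high"]), 95.05)

  sym <- c(-(1:50), 1:50) / 10
  thr2 <- empirical_thresholds(sym, 0.1)
  expect_equal(unname(thr2["low"]), -unname(thr2["high"]))

  expect_error(empirical_thresholds(rep(NaN, 30)), "finite")
  expect_error(empirical_thresholds(rnorm(10)), ">= 20")
})

test_that("candidate regions merge runs and label tails by population", {
  scan <- tibble::tibble(
    chrom = "c",
    start = seq(0, by = 1000, length.out = 20),
    end = seq(1000, by = 1000, length.out = 20),
    D = c(
      0, 0, -3, -3, -3, 0, 0, 0, 0, 0,
      0, 0, 0, 0, 3, 0, 0, 0, 0, 0
    )
  )
  regions <- candidate_regions(scan, low = -2, high = 2, population_label = "C")
  expect_equal(nrow(regions), 2)
  cn <- regions[regions$label == "CN", ]
  expect_equal(cn$start, 2000)
  expect_equal(cn$end, 5000)
  expect_equal(cn$n_windows, 3L)
  cp <- regions[regions$label == "CP", ]
  expect_equal(cp$start, 14000)
  expect_equal(cp$end, 15000)

  # no window beyond thresholds -> empty
  none <- candidate_regions(scan, low = -10, high = 10)
  expect_equal(nrow(none), 0)

  # idempotence: region-shaped input returns identical regions
  again <- candidate_regions(
    regions |> dplyr::mutate(D = ifelse(label == "CN", -3, 3)),
    low = -2, high = 2, population_label = "C"
  )
  expect_equal(again$start, regions$start)
  expect_equal(again$end, regions$end)
  expect_equal(again$label, regions$label)

  expect_error(candidate_regions(scan, low = 2, high = -2), "low threshold")
})

test_that("overlapping candidate windows merge into one region", {
  scan <- tibble::tibble(
    chrom = "c", start = c(0, 5000, 10000), end = c(10000, 15000, 20000),
    D = c(-3, -3, 0)
  )
  r <- candidate_regions(scan, -2, 2, "W")
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 0)
  expect_equal(r$end, 15000)
  expect_equal(r$label, "WN")
})

test_that("gene overlap respects half-open intervals and counts unique genes", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    chrom = c("c", "c", "c", "c", "c"),
    start = c(100L, 900L, 1000L, 1500L, 5000L),
    end = c(200L, 1000L, 1100L, 2600L, 5100L)
  )
  regions <- tibble::tibble(
    chrom = "c", start = c(0L, 2500L), end = c(1000L, 3000L),
    label = c("CN", "CP"), n_windows = c(1L, 1L), mean_D = c(-3, 3)
  )
  res <- genes_in_regions(regions, genes)
  # g2 ends exactly at region end (half-open) -> in; g3 starts there -> out
  expect_setequal(res$gene_ids[[1]], c("g1", "g2"))
  expect_setequal(res$gene_ids[[1]],
                  oracle_overlaps(regions[1, ], genes))
  expect_setequal(res$gene_ids[[2]], "g4")
  expect_equal(attr(res, "n_genes"), 3)

  # gene spanning two regions counted once in the unique total
  both <- tibble::tibble(
    chrom = "c", start = c(1500L, 2000L), end = c(1700L, 2600L),
    label = c("CN", "CN"), n_windows = c(1L, 1L), mean_D = c(-3, -3)
  )
  res2 <- genes_in_regions(both, genes)
  expect_equal(attr(res2, "n_genes"), 1)

  expect_warning(
    genes_in_regions(
      tibble::tibble(chrom = "zz", start = 0L, end = 10L,
                     label = "CN", n_windows = 1L, mean_D = -3),
      genes
    ),
    "absent"
  )
})
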