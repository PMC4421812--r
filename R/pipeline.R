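#' Pipeline run configuration
#'
#' Collects every tunable of the demo pipeline with its default. Values the
#' caller overrides are recorded as user-set in the serialized manifest, so
#' a run directory documents its own provenance.
#'
#' @param ... Named overrides of the defaults (see Details).
#' @details Fields: `seed` (top-level seed; every stage derives its own from
#'   it by a fixed rule); `n_wild`, `n_cultivated`, `theta`,
#'   `bottleneck_severity`, `split_time`, `n_windows`, `window_length`
#'   (simulation); `window_size`, `step`, `tail_fraction`, `pool_populations`
#'   (scan and region calling); `n_bootstrap` (tree); `n_families`,
#'   `loss_rate` (Dollo); `te_ages`, `te_length` (repeat ages);
#'   `n_host`, `n_bacterial` (contamination filter); `identity_threshold`,
#'   `max_intervening` (tandem clusters).
#' @return A `kelpscan_config` list.
#' @export
kelpscan_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_wild = 9L, n_cultivated = 7L, theta = 10,
    bottleneck_severity = 0.05, split_time = 0.1,
    n_windows = 60L, window_length = 10000L,
    window_size = 10000L, step = 5000L,
    tail_fraction = 0.05, pool_populations = FALSE,
    n_bootstrap = 100L,
    n_families = 500L, loss_rate = 0.02,
    te_ages = c(rep(0.02, 60), rep(0.20, 60)), te_length = 2000L,
    n_host = 30L, n_bacterial = 30L,
    identity_threshold = 0.85, max_intervening = 5L
  )
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  cfg$provenance <- ifelse(
    names(defaults) %in% names(user), "user", "default"
  ) |> setNames(names(defaults))
  class(cfg) <- "kelpscan_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks all range constraints at once and reports every violation
#' together rather than stopping at the first.
#'
#' @param config A `kelpscan_config`.
#' @return Invisibly `TRUE` if valid; otherwise an error listing all
#'   problems.
#' @export
validate_config <- function(config) {
  errors <- character(0)
  add <- function(msg) errors <<- c(errors, msg)
  if (is.null(config$seed) || is.na(config$seed)) add("seed is required")
  if (config$tail_fraction <= 0 || config$tail_fraction >= 0.5) {
    add("tail_fraction out of range (0, 0.5)")
  }
  if (config$window_size < config$step) add("window_size must be >= step")
  if (config$step < 1) add("step must be >= 1")
  if (config$bottleneck_severity <= 0 || config$bottleneck_severity > 1) {
    add("bottleneck_severity out of range (0, 1]")
  }
  if (config$split_time <= 0) add("split_time must be positive")
  if (config$theta <= 0) add("theta must be positive")
  if (config$n_wild < 1 || config$n_cultivated < 1) {
    add("population sizes must be >= 1")
  }
  if (config$identity_threshold < 0 || config$identity_threshold > 1) {
    add("identity_threshold out of range [0, 1]")
  }
  if (config$n_bootstrap < 1) add("n_bootstrap must be >= 1")
  if (length(errors) > 0) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  }
  invisible(TRUE)
}

#' Run the demo pipeline end to end
#'
#' Simulates the two-population dataset, scans both populations, calls
#' candidate sweep regions from the empirical Tajima's D tails, builds the
#' bootstrap NJ tree, reconstructs Dollo gains/losses for a simulated family
#' matrix on the bundled species tree, computes the TE age histogram, and
#' runs the contamination filter — writing each stage's artifact plus a
#' manifest into `out_dir`. Reruns with the same config are byte-identical.
#'
#' @param config A [kelpscan_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = kelpscan_config(), out_dir, quiet = FALSE) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("kelpscan: ", ...)

  # stage 1: simulate two populations --------------------------------------
  say("simulating two-population dataset")
  sim <- simulate_two_pop(
    n_wild = config$n_wild, n_cultivated = config$n_cultivated,
    theta = config$theta, bottleneck_severity = config$bottleneck_severity,
    split_time = config$split_time, n_windows = config$n_windows,
    window_length = config$window_length, seed = derive_seed(config$seed, 1L)
  )
  write_vcf(sim$variants, file.path(out_dir, "sim.vcf"))
  readr::write_tsv(sim$pops, file.path(out_dir, "pops.tsv"), progress = FALSE)

  # stage 2: per-population scans ------------------------------------------
  say("scanning windows")
  chrom_lengths <- setNames(
    rep(config$window_length, config$n_windows),
    paste0("w", seq_len(config$n_windows))
  )
  pops <- split(sim$pops$sample, sim$pops$population)
  scans <- purrr::imap(pops, function(smp, pop) {
    sliding_scan(
      sim$variants, window_size = config$window_size, step = config$step,
      samples = smp, chrom_lengths = chrom_lengths
    ) |> mutate(population = pop, .before = 1)
  })
  scan_tb <- list_rbind(scans)
  readr::write_tsv(scan_tb, file.path(out_dir, "scan.tsv"), progress = FALSE)

  # stage 3: thresholds + candidate regions --------------------------------
  say("calling candidate regions")
  if (config$pool_populations) {
    thr_all <- empirical_thresholds(scan_tb$D, config$tail_fraction)
    thresholds <- list(cultivated = thr_all, wild = thr_all)
  } else {
    thresholds <- purrr::map(
      scans, function(s) empirical_thresholds(s$D, config$tail_fraction)
    )
  }
  regions <- purrr::imap(scans, function(s, pop) {
    thr <- thresholds[[pop]]
    candidate_regions(
      s, thr["low"], thr["high"],
      population_label = toupper(substr(pop, 1, 1))
    )
  }) |> list_rbind()
  readr::write_tsv(regions, file.path(out_dir, "regions.tsv"), progress = FALSE)

  # stage 4: NJ tree with bootstrap ----------------------------------------
  say("building NJ tree (", config$n_bootstrap, " bootstrap replicates)")
  nj <- bootstrap_support(
    sim$variants, n_replicates = config$n_bootstrap,
    seed = derive_seed(config$seed, 2L)
  )
  write_newick(nj$tree, file.path(out_dir, "tree.nwk"))

  # stage 5: Dollo gain/loss on the bundled species tree --------------------
  say("Dollo gain/loss reconstruction")
  sp_tree <- default_species_tree()
  fam <- simulate_family_evolution(
    sp_tree, n_families = config$n_families, loss_rate = config$loss_rate,
    seed = derive_seed(config$seed, 3L)
  )
  dollo <- dollo_reconstruct(fam$presence, sp_tree)
  readr::write_tsv(
    tidy(dollo), file.path(out_dir, "gainloss.tsv"), progress = FALSE
  )

  # stage 6: TE age distribution --------------------------------------------
  say("TE age distribution")
  te <- simulate_te_decay(
    consensus_length = config$te_length, copy_ages = config$te_ages,
    seed = derive_seed(config$seed, 4L)
  )
  te_hist <- te_age_distribution(te$alignments)
  readr::write_tsv(te_hist, file.path(out_dir, "te_ages.tsv"), progress = FALSE)

  # stage 7: contamination filter -------------------------------------------
  say("contamination filter")
  contigs <- simulate_contigs(
    n_host = config$n_host, n_bacterial = config$n_bacterial,
    seed = derive_seed(config$seed, 5L)
  )
  qc <- filter_contigs(contigs, quiet = TRUE)
  readr::write_tsv(
    qc |> select(-"sequence"), file.path(out_dir, "qc_report.tsv"),
    progress = FALSE
  )

  # manifest -----------------------------------------------------------------
  pi_by_pop <- scan_tb |>
    group_by(.data$population) |>
    summarise(mean_pi = mean(.data$pi), .groups = "drop")
  manifest <- list(
    tool = "kelpscan",
    version = as.character(utils::packageVersion("kelpscan")),
    config = config[setdiff(names(config), "provenance")],
    provenance = as.list(config$provenance),
    summary = list(
      n_snvs = nrow(sim$variants),
      mean_pi_wild = pi_by_pop$mean_pi[pi_by_pop$population == "wild"],
      mean_pi_cultivated =
        pi_by_pop$mean_pi[pi_by_pop$population == "cultivated"],
      thresholds = purrr::map(thresholds, as.list),
      n_regions = nrow(regions),
      n_bacterial_removed = sum(qc$filtered),
      dollo_total_losses = sum(tidy(dollo)$n_lost)
    )
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    sim = sim, scan = scan_tb, thresholds = thresholds, regions = regions,
    nj = nj, dollo = dollo, te_hist = te_hist, qc = qc, manifest = manifest
  ))
}

#' Bundled demo species tree
#'
#' A rooted seven-taxon heterokont-style species tree (two kelp-like sister
#' taxa, a picoalgal lineage, and a diatom clade) with 0.5-unit branches,
#' used by the family-evolution demo and tests.
#'
#' @return A rooted [ape::phylo] tree with branch lengths.
#' @export
default_species_tree <- function() {
  read_newick(paste0(
    "(((Sjap:0.5,Esil:0.5):0.5,Ngad:0.5):0.5,",
    "((Ptri:0.5,Tpse:0.5):0.5,(Fcyl:0.5,Pmul:0.5):0.5):0.5);"
  ))
}
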