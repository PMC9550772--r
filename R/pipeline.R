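#' Default pipeline configuration
#'
#' The configuration schema consumed by [run_pipeline()]: a global seed,
#' an output directory, the simulator parameters, the classification
#' `thresholds` block, the transcript-state detection threshold, the
#' comparison and enrichment settings. The bundled demo configuration
#' (`system.file("extdata", "demo_config.yaml", package = "monoallelix")`)
#' is this object rendered to YAML.
#'
#' @param seed global seed; each stochastic stage receives a recorded
#'   sub-seed derived from it.
#' @param out_dir output directory.
#' @return nested list.
#' @export
default_config <- function(seed = 1L, out_dir = "monoallelix_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    populations = c("popA", "popB"),
    simulate = list(
      n_genes = 600L,
      class_proportions = list(biallelic = 0.72, DeMA_mat = 0.055,
                               DeMA_pat = 0.01, RaMA = 0.015,
                               not_expressed = 0.20),
      mean_expression = list(log_mean = log(100), log_sd = 1),
      nb_dispersion = 0.1,
      n_replicates = 3L,
      n_cells = 80L,
      dropout = 0.3,
      leak = 0.005,
      nascent_only_frac = 0.314,
      mature_only_frac = 0.605
    ),
    thresholds = list(min_total = 5L, mono_fraction = 0.98, min_cells = 5L,
                      rama_min_cells = 3L, max_biallelic_frac = 0.10,
                      min_expressed_frac = 0.05),
    transcript = list(min_detect = 1L),
    compare = list(n_boot = 2000L),
    enrich = list(n_terms = 12L, term_size = 25L,
                  n_background_draws = 500L)
  )
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

validate_config <- function(cfg) {
  required <- c("seed", "out_dir", "populations", "simulate", "thresholds",
                "transcript", "compare", "enrich")
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    stop("config validation failed; missing block(s): ",
         paste(miss, collapse = ", "))
  if (length(cfg$populations) < 2L)
    stop("config validation failed; `populations` needs >= 2 labels")
  th_fields <- c("min_total", "mono_fraction", "min_cells", "rama_min_cells",
                 "max_biallelic_frac", "min_expressed_frac")
  miss_th <- setdiff(th_fields, names(cfg$thresholds))
  if (length(miss_th))
    stop("config validation failed; thresholds missing: ",
         paste(miss_th, collapse = ", "))
  invisible(cfg)
}

config_params <- function(cfg, seed) {
  s <- cfg$simulate
  sim_params(n_genes = s$n_genes,
             class_proportions = unlist(s$class_proportions),
             mean_expression = c(s$mean_expression$log_mean,
                                 s$mean_expression$log_sd),
             nb_dispersion = s$nb_dispersion,
             n_replicates = s$n_replicates,
             n_cells = s$n_cells,
             dropout = s$dropout,
             leak = s$leak,
             nascent_only_frac = s$nascent_only_frac,
             mature_only_frac = s$mature_only_frac,
             seed = seed)
}

config_thresholds <- function(cfg) {
  t <- cfg$thresholds
  call_thresholds(min_total = t$min_total, mono_fraction = t$mono_fraction,
                  min_cells = t$min_cells, rama_min_cells = t$rama_min_cells,
                  max_biallelic_frac = t$max_biallelic_frac,
                  min_expressed_frac = t$min_expressed_frac)
}

log_stage <- function(stage, ...) {
  message(sprintf("[monoallelix] %s: %s", stage, sprintf(...)))
}

#' Run the full synthetic analysis pipeline
#'
#' Wires the five stages end to end on simulated data: (1) simulate —
#' bulk replicates plus one single-cell population per configured label,
#' written in the B/C TSV dialect with truth tables; (2) classify — bulk
#' DeMA filter and per-population single-cell filter; (3)
#' transcript_state — nascent/mature census of the bulk cohort; (4)
#' compare — maternal:paternal imbalance, status changes and exclusive
#' intersections between the single-cell populations; (5) enrich —
#' Fisher/BH/combined score of the first population's DeMA_mat genes
#' against a seeded synthetic term collection. Every stage's sub-seed is
#' derived from the global seed and recorded; rerunning with the same
#' configuration reproduces byte-identical outputs.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @param force overwrite an existing manifest (default FALSE: a
#'   completed run directory is refused so partial artifacts are not
#'   silently mixed).
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), force = FALSE) {
  cfg <- validate_config(read_config(config))
  out <- cfg$out_dir
  manifest_path <- file.path(out, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("run directory already contains a manifest; use force = TRUE to redo")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  th <- config_thresholds(cfg)
  pops <- cfg$populations
  seeds <- list(bulk = cfg$seed, cells = cfg$seed + seq_along(pops),
                transcript = cfg$seed + 101L, enrich = cfg$seed + 201L,
                compare = cfg$seed + 301L)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  # stage 1: simulate
  bulk <- simulate_bulk(config_params(cfg, seeds$bulk), population = "bulk")
  write_allele_counts(bulk$counts, file.path(out, "bulk_counts.tsv"),
                      file.path(out, "bulk_meta.tsv"))
  utils::write.table(bulk$truth$table, file.path(out, "bulk_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add(c("bulk_counts.tsv", "bulk_meta.tsv", "bulk_truth.tsv"))
  sc <- list()
  for (i in seq_along(pops)) {
    sc[[pops[i]]] <- simulate_cells(config_params(cfg, seeds$cells[i]),
                                    population = pops[i])
    write_allele_counts(sc[[pops[i]]]$counts,
                        file.path(out, paste0(pops[i], "_counts.tsv")),
                        file.path(out, paste0(pops[i], "_meta.tsv")))
    add(paste0(pops[i], c("_counts.tsv", "_meta.tsv")))
  }
  log_stage("simulate", "bulk %d genes x %d replicates; %d cell populations",
            cfg$simulate$n_genes, cfg$simulate$n_replicates, length(pops))

  # stage 2: classify
  bulk_classes <- classify_bulk(bulk$counts, th)
  write_gene_classes(bulk_classes, file.path(out, "bulk_classes.tsv"))
  add("bulk_classes.tsv")
  sc_classes <- list()
  for (p in pops) {
    sc_classes[[p]] <- classify_population(sc[[p]]$counts, th)
    write_gene_classes(sc_classes[[p]], file.path(out, paste0(p, "_classes.tsv")))
    add(paste0(p, "_classes.tsv"))
  }
  tallies <- lapply(c(list(bulk = bulk_classes), sc_classes),
                    function(cl) as.list(table(cl$class)))
  log_stage("classify", "per-class tallies written for %d populations",
            length(tallies))

  # stage 3: transcript state
  ts <- simulate_transcript_states(config_params(cfg, seeds$transcript),
                                   bulk$truth)
  states <- transcript_states(ts$states$gene, ts$states$nascent_count,
                              ts$states$mature_count,
                              min_detect = cfg$transcript$min_detect)
  utils::write.table(states, file.path(out, "transcript_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  add("transcript_states.tsv")
  census <- state_census(states)
  log_stage("transcript_state", "mature-only %.3f, active-only %.3f",
            census$mature_only_frac, census$active_only_frac)

  # stage 4: compare
  imb <- imbalance_ratio(bulk_classes, n_boot = cfg$compare$n_boot,
                         seed = seeds$compare)
  chg <- status_change(sc_classes[[pops[1L]]], sc_classes[[pops[2L]]])
  xs <- intersect_classes(sc_classes, c("DeMA_mat", "DeMA_pat"))
  compare_out <- list(
    imbalance = list(population = imb$population, n_mat = imb$n_mat,
                     n_pat = imb$n_pat, ratio = imb$ratio, ci = imb$ci),
    status_change = list(counts = as.list(chg$counts),
                         switched_alleles = chg$switched_alleles,
                         n_excluded = chg$n_excluded),
    intersections = xs$combos)
  jsonlite::write_json(compare_out, file.path(out, "compare.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add("compare.json")
  log_stage("compare", "imbalance %s, %d allele-switch outliers",
            format(imb$ratio), length(chg$switched_alleles))

  # stage 5: enrich — synthetic term collection seeded from the run
  query <- sc_classes[[pops[1L]]]$gene[sc_classes[[pops[1L]]]$class == "DeMA_mat"]
  universe <- sc[[pops[1L]]]$counts$gene_ids
  set.seed(seeds$enrich)
  n_terms <- cfg$enrich$n_terms
  term_size <- min(cfg$enrich$term_size, length(universe))
  sets <- lapply(seq_len(n_terms), function(i) sample(universe, term_size))
  names(sets) <- sprintf("TERM_%02d", seq_len(n_terms))
  if (length(query) >= 2L)
    sets[["TERM_ENRICHED"]] <- unique(c(
      query, sample(universe, max(0L, term_size - length(query)))))
  gs <- gene_sets(sets, universe = universe)
  if (length(query)) {
    enr <- fisher_enrich(query, gs, universe = universe)
    enr <- combined_score(enr, n_background_draws = cfg$enrich$n_background_draws,
                          seed = seeds$enrich)
    write_enrich_result(enr, file.path(out, "enrichment.tsv"))
    add("enrichment.tsv")
    log_stage("enrich", "%d terms tested, top term %s", nrow(enr), enr$term[1L])
  } else {
    log_stage("enrich", "no DeMA_mat query genes; stage skipped")
  }

  yaml::write_yaml(cfg, file.path(out, "config_resolved.yaml"))
  add("config_resolved.yaml")
  hashes <- tools::md5sum(file.path(out, files))
  manifest <- list(
    package_version = as.character(utils::packageVersion("monoallelix")),
    stages = c("simulate", "classify", "transcript_state", "compare",
               "enrich"),
    seed = cfg$seed,
    stage_seeds = seeds,
    class_tallies = tallies,
    files = lapply(stats::setNames(files, files),
                   function(f) list(md5 = unname(hashes[file.path(out, f)]))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
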