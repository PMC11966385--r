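#' Default run configuration
#'
#' One nested list drives the whole pipeline; every parameter mirrors the
#' default of the function it is passed to. Configurations round-trip through
#' YAML ([load_config()]) and the resolved configuration is written into
#' every run directory for auditability.
#'
#' @return A named list of per-stage parameter lists.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = TRUE,
    # when simulate is FALSE, an `input` list supplies nuclear_vcf, samples
    # and (optionally) cp_vcf paths
    sim = list(n_chrom = 9L, chrom_len_bp = 3e7, n_sites_per_chrom = 5556L,
               fixed_diff_fraction = 0.3, recomb_rate = 1.5,
               n_pure_A = 20L, n_pure_B = 20L,
               n_candidates = 20L, n_distractors = 5L,
               clone_group_size = 5L, somatic_rate = 1e-4,
               block_mean_bp = 5e6,
               error_rate = 0.005, missing_rate = 0.02,
               cp_n_sites = 200L, cp_mut_rate = 0.001),
    prep = list(max_missing = 0.2, min_maf = 0.01,
                ld_prune = TRUE, ld_r2 = 0.9, window_sites = 50L,
                step_sites = 5L),
    paint = list(window_bp = 5e5, min_sites = 10L, state_threshold = 0.8,
                 min_panel_n = 3L, max_alt_freq = 0.05),
    relate = list(k = 2L),
    hapshare = list(enabled = TRUE, switch_cost = 1.0, mismatch_cost = 0.5),
    parentage = list(informative_only = TRUE)
  )
}

#' Load a YAML run configuration, merged over the defaults
#'
#' @param path YAML file; missing fields fall back to [default_config()].
#' @return A configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(), user)
}

#' The bundled demo configuration
#'
#' A down-scaled cohort that runs the full pipeline end to end in well under
#' a minute.
#'
#' @return A configuration list.
#' @export
demo_config <- function() {
  load_config(system.file("extdata", "demo_config.yaml",
                          package = "hybriseek", mustWork = TRUE))
}

sim_from_config <- function(cfg) {
  s <- cfg$sim
  model <- founder_model(n_chrom = s$n_chrom, chrom_len_bp = s$chrom_len_bp,
                         n_sites_per_chrom = s$n_sites_per_chrom,
                         fixed_diff_fraction = s$fixed_diff_fraction,
                         recomb_rate = s$recomb_rate)
  admix <- c(0, 0.10, rep_len(c(0, 0.05, 0.10, 0.15, 0.20),
                              max(s$n_candidates - 2L, 0L)))
  names(admix) <- sprintf("cand%02d", seq_along(admix))
  dist <- rep_len(c(0.05, 0.15), s$n_distractors)
  names(dist) <- sprintf("dist%02d", seq_along(dist))
  ped <- pedigree_spec(n_pure_A = s$n_pure_A, n_pure_B = s$n_pure_B,
                       candidate_admix = admix,
                       seed_parent = "cand01", pollen_parent = "cand02",
                       clone_group_size = s$clone_group_size,
                       somatic_rate = s$somatic_rate,
                       distractor_admix = dist,
                       error_rate = s$error_rate, missing_rate = s$missing_rate,
                       block_mean_bp = s$block_mean_bp,
                       cp_n_sites = s$cp_n_sites, cp_mut_rate = s$cp_mut_rate)
  list(model = model, ped = ped)
}

#' Run the full parentage-inference pipeline
#'
#' Stages, in dependency order: simulate (or load inputs), site
#' filtering/LD pruning, diagnostic-SNP genome painting, IBD + PCA
#' relatedness, haplotype-sharing matrix, trio ranking + chloroplast
#' orientation, and the final origin report. All stage outputs, the resolved
#' configuration and a manifest (parameters, seed, versions, input checksums)
#' are written under `outdir`. Reruns with identical configuration and seed
#' are byte-identical.
#'
#' A missing chloroplast input degrades gracefully: the parent pair is still
#' reported with orientation `"undetermined"`.
#'
#' @param config a configuration list (see [default_config()]).
#' @param outdir run directory (created; reused if present).
#' @param seed overrides `config$seed`.
#' @return Invisibly, a list with the stage results (`report`, `rank`,
#'   `ibd`, `pca`, `panel`, `track`, `sharing`, `cp`, `sim`).
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- "simulate/load"
  res <- try({
    sim <- NULL; truth <- NULL; cp <- NULL
    if (isTRUE(config$simulate)) {
      parts <- sim_from_config(config)
      sim <- simulate_cohort(parts$model, parts$ped, seed = config$seed)
      write_dataset(sim, file.path(outdir, "data"))
      gm <- sim$gm; cp <- sim$cp; sheet <- sim$sheet; truth <- sim$truth
    } else {
      sheet <- read_sample_sheet(config$input$samples)
      gm <- read_vcf(config$input$nuclear_vcf, sheet)
      if (!is.null(config$input$cp_vcf) && file.exists(config$input$cp_vcf))
        cp <- read_vcf(config$input$cp_vcf)
    }
    query <- sheet$id[sheet$role == "query"][1]
    clones <- sheet$id[startsWith(sheet$role, "clone_group:")]
    candidates <- sheet$id[sheet$role == "candidate_parent"]
    cohort <- sheet$id[sheet$panel == "none"]   # the mandarin-lineage cohort

    stage <- "prep"
    gm_f <- filter_sites(gm, config$prep$max_missing, config$prep$min_maf)
    gm_p <- if (isTRUE(config$prep$ld_prune))
      ld_prune(gm_f, config$prep$ld_r2, config$prep$window_sites,
               config$prep$step_sites) else gm_f

    stage <- "paint"
    panel <- ascertain_diagnostic(gm_f, sheet, config$paint$min_panel_n,
                                  config$paint$max_alt_freq)
    track <- paint_genome(gm_f, panel, config$paint$window_bp,
                          config$paint$min_sites, config$paint$state_threshold)
    utils::write.table(panel, file.path(outdir, "diagnostic_panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(track, file.path(outdir, "painting_windows.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "relate"
    # IBD expectations need frequencies from a homogeneous population: use
    # the species-A reference panel, not the structured cultivar cohort
    ibd <- ibd_matrix(gm_p, samples = cohort,
                      freq = allele_freq(gm_p, sheet$id[sheet$panel == "species_A"]))
    pca <- pca_genotypes(gm_f, k = config$relate$k)
    utils::write.table(ibd$pairs, file.path(outdir, "ibd_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(id = rownames(pca$scores), pca$scores),
                       file.path(outdir, "pca_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "hapshare"
    sharing <- NULL
    if (isTRUE(config$hapshare$enabled) && is_phased(gm_f)) {
      sharing <- sharing_matrix(gm_f, query, candidates,
                                switch_cost = config$hapshare$switch_cost,
                                mismatch_cost = config$hapshare$mismatch_cost)
      utils::write.table(data.frame(recipient = rownames(sharing), sharing),
                         file.path(outdir, "sharing_matrix.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "parentage"
    rank <- rank_parent_pairs(gm_f, query, candidates,
                              informative_only = config$parentage$informative_only)
    cp_res <- if (!is.null(cp)) cp_maternal_assign(cp, query, candidates)
    report <- decide_origin(rank, cp_res, ibd, offspring = query)
    utils::write.table(rank, file.path(outdir, "trio_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cp_res))
      writeLines(cp_res$newick, file.path(outdir, "cp_nj.nwk"))
    jsonlite::write_json(
      list(best_pair = report$best_pair, coincidence = report$coincidence,
           dispersion = report$dispersion, orientation = report$orientation,
           seed_parent = report$seed_parent, pollen_parent = report$pollen_parent,
           cp_distances = as.list(report$cp_distances),
           ibd1 = as.list(report$ibd1)),
      file.path(outdir, "origin_report.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    txt <- utils::capture.output(print(report))
    writeLines(txt, file.path(outdir, "origin_report.txt"))

    list(report = report, rank = rank, ibd = ibd, pca = pca, panel = panel,
         track = track, sharing = sharing, cp = cp_res, sim = sim,
         gm_filtered = gm_f, gm_pruned = gm_p, sheet = sheet, truth = truth,
         query = query, candidates = candidates, clones = clones)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message)
  data_files <- list.files(file.path(outdir, "data"), full.names = TRUE)
  manifest <- list(
    package = "hybriseek",
    version = as.character(utils::packageVersion("hybriseek")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config,
    input_md5 = as.list(tools::md5sum(data_files)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  yaml::write_yaml(config, file.path(outdir, "config_resolved.yaml"))
  invisible(res)
}

#' Run the bundled end-to-end demo
#'
#' @param outdir run directory.
#' @param seed RNG seed.
#' @return Invisibly, the [run_pipeline()] result list.
#' @export
run_demo <- function(outdir = file.path(tempdir(), "hybriseek_demo"), seed = 1) {
  run_pipeline(demo_config(), outdir, seed = seed)
}
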