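#' Pipeline configuration
#'
#' Either real inputs (`vcf` + `popmap` + `partition`, optionally `fasta` +
#' `gff`) or a [synth_scenario], not both unset. The presence filter
#' defaults to "present in at least half of the populations", the
#' configuration used when every sample is its own population.
#'
#' @param vcf,popmap,partition,fasta,gff Input file paths (or `NULL`).
#' @param scenario A [synth_scenario] to simulate instead of reading files.
#' @param min_pops Presence-filter threshold (default: half the populations).
#' @param min_sample_fraction Presence-filter per-population typed fraction.
#' @param two_group_merge,two_group_name Groups merged into one side of the
#'   2-group (East/West-Japan analogue) marker search.
#' @param purity_threshold Passed to [classify_introgression()].
#' @param min_typed_per_group Passed to the marker searches.
#' @param pseudocount Passed to [estimate_group_frequencies()].
#' @param replicates Known technical-replicate sample ids to exclude from
#'   marker searches (filled automatically for synthetic data).
#' @param seed Integer seed (drives the scenario when simulating).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, popmap = NULL, partition = NULL,
                            fasta = NULL, gff = NULL, scenario = NULL,
                            min_pops = NULL, min_sample_fraction = 0,
                            two_group_merge = c("west", "kyushu"),
                            two_group_name = "westjapan",
                            purity_threshold = 0.9, min_typed_per_group = 3,
                            pseudocount = 0.5, replicates = character(),
                            seed = 1) {
  if (is.null(scenario) && (is.null(vcf) || is.null(popmap) ||
                            is.null(partition))) {
    stop("provide either a scenario or vcf + popmap + partition paths")
  }
  structure(list(vcf = vcf, popmap = popmap, partition = partition,
                 fasta = fasta, gff = gff, scenario = scenario,
                 min_pops = min_pops,
                 min_sample_fraction = min_sample_fraction,
                 two_group_merge = two_group_merge,
                 two_group_name = two_group_name,
                 purity_threshold = purity_threshold,
                 min_typed_per_group = min_typed_per_group,
                 pseudocount = pseudocount, replicates = replicates,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages run in order: presence filter, PCA/MDS, fixation indices (group
#' pairwise, within-group accession pairwise with rank-sum comparisons),
#' leave-one-out ancestry with introgression calls, diagnostic-marker
#' searches (2-group and 3-group), and region/effect annotation. Each
#' stage's tab-separated outputs are written under `outdir` before the next
#' stage begins; identical config and seed give byte-identical tables. A
#' stage failure aborts with the stage name after writing a partial-results
#' manifest. Without FASTA/GFF inputs the annotation section is marked
#' skipped.
#'
#' @param config A [pipeline_config].
#' @param outdir Output directory.
#' @return A list of class `radpop_report` with one element per section
#'   plus `log` and `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  manifest <- tibble::tibble(stage = character(), status = character())
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(...))
    log <<- c(log, line)
  }
  finish_stage <- function(name) {
    manifest <<- dplyr::bind_rows(manifest,
                                  tibble::tibble(stage = name, status = "ok"))
    readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  }
  run_stage <- function(name, expr) {
    say("stage ", name, " started")
    tryCatch(expr, error = function(e) {
      manifest <<- dplyr::bind_rows(manifest,
                                    tibble::tibble(stage = name, status = "failed"))
      readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
      writeLines(log, file.path(outdir, "run.log"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list(outdir = outdir)

  # --- input / simulation ---
  inputs <- run_stage("input", {
    if (!is.null(config$scenario)) {
      ds <- simulate_dataset(config$scenario)
      paths <- write_dataset(ds, file.path(outdir, "data"))
      say("simulated dataset: ", n_samples(ds$gm), " samples x ",
          n_sites(ds$gm), " sites (seed ", config$scenario$seed, ")")
      list(gm = ds$gm, pm = ds$popmap, partition = ds$partition,
           fasta = paths$fasta, gff = paths$gff,
           replicates = ds$truth$replicates$replicate, truth = ds$truth)
    } else {
      gm <- read_vcf(config$vcf)
      say("read ", n_samples(gm), " samples x ", n_sites(gm), " sites")
      list(gm = gm, pm = read_popmap(config$popmap),
           partition = read_partition(config$partition),
           fasta = config$fasta, gff = config$gff,
           replicates = config$replicates, truth = NULL)
    }
  })
  finish_stage("input")

  gm <- run_stage("filter", {
    out <- filter_by_presence(inputs$gm, inputs$pm, config$min_pops,
                              config$min_sample_fraction)
    say("presence filter kept ", n_sites(out), "/", n_sites(inputs$gm),
        " sites")
    out
  })
  finish_stage("filter")
  pm <- inputs$pm; partition <- inputs$partition

  report$popstruct <- run_stage("popstruct", {
    pca <- genotype_pca(gm, n_components = 10)
    coords <- dplyr::mutate(pca$coordinates,
                            group = unname(sample_groups(pm, partition)[.data$sample]),
                            .after = "sample")
    readr::write_tsv(coords, file.path(outdir, "pca_coordinates.tsv"))
    readr::write_tsv(tibble::tibble(component = seq_along(pca$explained_fraction),
                                    explained_fraction = pca$explained_fraction),
                     file.path(outdir, "pca_explained.tsv"))
    mds <- classical_mds(ibs_distance(gm), k = 3)
    readr::write_tsv(mds, file.path(outdir, "mds_coordinates.tsv"))
    say("PCA explained (PC1-3): ",
        paste(round(100 * utils::head(pca$explained_fraction, 3), 1),
              collapse = "/"), "%")
    list(pca = pca, mds = mds)
  })
  finish_stage("popstruct")

  report$fst <- run_stage("fst", {
    grp <- pairwise_group_fst(gm, pm, partition)
    readr::write_tsv(grp, file.path(outdir, "fst_groups.tsv"))
    within <- within_group_pairwise_fst(gm, pm, partition)
    readr::write_tsv(within, file.path(outdir, "fst_within.tsv"))
    means <- fst_within_means(within)
    readr::write_tsv(means, file.path(outdir, "fst_within_means.tsv"))
    comps <- fst_within_comparisons(within)
    readr::write_tsv(comps, file.path(outdir, "fst_within_ranksum.tsv"))
    say("group pairwise theta: ",
        paste(sprintf("%s-%s=%.3f", grp$group1, grp$group2, grp$theta),
              collapse = ", "))
    list(groups = grp, within = within, means = means, comparisons = comps)
  })
  finish_stage("fst")

  report$ancestry <- run_stage("ancestry", {
    est <- estimate_ancestry_all(gm, pm, partition,
                                 pseudocount = config$pseudocount)
    cls <- classify_introgression(est, config$purity_threshold)
    readr::write_tsv(cls, file.path(outdir, "ancestry.tsv"))
    say(sum(cls$call == "admixed"), " admixed, ",
        sum(cls$call == "transplant-candidate"), " transplant-candidate ",
        "sample(s)")
    cls
  })
  finish_stage("ancestry")

  report$markers <- run_stage("markers", {
    impure <- report$ancestry$sample[!startsWith(report$ancestry$call, "pure")]
    blacklist <- union(inputs$replicates, impure)
    say("marker search excludes ", length(blacklist),
        " sample(s) (replicates + non-pure)")
    part2 <- collapse_partition(partition, config$two_group_merge,
                                config$two_group_name)
    two <- find_two_group_diagnostic(gm, pm, part2,
                                     config$min_typed_per_group,
                                     exclude_samples = blacklist)
    readr::write_tsv(two, file.path(outdir, "markers_two_group.tsv"))
    write_marker_bed(two, file.path(outdir, "markers_two_group.bed"))
    three <- find_k_group_diagnostic_set(gm, pm, partition,
                                         min_typed_per_group = config$min_typed_per_group,
                                         exclude_samples = blacklist)
    readr::write_tsv(three, file.path(outdir, "markers_three_group.tsv"))
    say(nrow(two), " two-group diagnostic site(s); ",
        length(unique(three$solution)), " minimal three-group set(s)")
    list(two_group = two, three_group = three, blacklist = blacklist)
  })
  finish_stage("markers")

  report$annotation <- run_stage("annotation", {
    if (is.null(inputs$fasta) || is.null(inputs$gff)) {
      say("annotation skipped (no FASTA/GFF)")
      "skipped"
    } else {
      index <- build_annotation_index(inputs$gff)
      fasta <- read_genome_fasta(inputs$fasta)
      summ <- summarize_regions(report$markers$two_group, index, fasta)
      readr::write_tsv(summ$counts, file.path(outdir, "annotation_counts.tsv"))
      readr::write_tsv(summ$details, file.path(outdir, "annotation_details.tsv"))
      say("marker regions: ",
          paste(summ$counts$category, summ$counts$n, sep = "=",
                collapse = ", "))
      summ
    }
  })
  finish_stage("annotation")

  say("pipeline complete")
  report$log <- log
  report$truth <- inputs$truth
  report$parameters <- config
  writeLines(log, file.path(outdir, "run.log"))
  writeLines(c(paste0("radpopgen ", as.character(utils::packageVersion("radpopgen"))),
               paste0("R ", R.version.string),
               paste0("seed ", config$seed),
               utils::capture.output(utils::str(config, give.attr = FALSE))),
             file.path(outdir, "parameters.txt"))
  class(report) <- "radpop_report"
  report
}

#' @export
print.radpop_report <- function(x, ...) {
  cat("<radpop_report> sections:",
      paste(setdiff(names(x), c("outdir", "log", "truth", "parameters")),
            collapse = ", "), "\n  outputs in", x$outdir, "\n")
  invisible(x)
}
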