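## End-to-end orchestration: simulate (or load) -> detect -> traits -> MGE ->
## network -> phylo -> statistics, collected into one machine-readable report.

#' Run the full analysis pipeline on simulated or supplied inputs
#'
#' Stages run in dependency order; a failing stage aborts with its name. With
#' `simulate = TRUE` (the default) all inputs come from the synthetic-data
#' generator under the given seed, which makes two runs with the same
#' configuration and seed byte-identical.
#'
#' @param config a [simulation_config()]; its `seed` drives every stochastic
#'   stage.
#' @param simulate generate inputs with [simulate_replicons()]; supplying
#'   `inputs` instead (a list with `annotations`, `metadata`, `trait_hits`)
#'   skips the generator.
#' @param inputs optional pre-loaded input list (see `simulate`).
#' @param n_tree_tips tips of the compartment tree analyzed in the
#'   phylogenetic stage (default 60).
#' @param outdir optional directory; when given, all tabular artifacts and
#'   the JSON report are written there.
#' @return list of class `pipeline_report`: `dataset`, `clusters`,
#'   `island_inventory`, `cohort`, `mge`, `network`, `phylo`, `tests`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = simulation_config(), simulate = TRUE,
                         inputs = NULL, n_tree_tips = 60L, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sim <- stage("simulate", {
    if (simulate) simulate_replicons(config)
    else if (is.null(inputs)) stop("inputs required when simulate = FALSE")
    else inputs
  })

  thresholds <- detection_thresholds()
  clusters <- stage("detect", scan_clusters(sim$annotations, thresholds))
  islands <- stage("detect", find_isolated_genes(sim$annotations, clusters))
  compdist <- summarize_component_distribution(clusters)

  profiles <- stage("traits", profile_traits(sim$metadata, sim$trait_hits))
  plasmids <- profiles[profiles$kind == "plasmid", , drop = FALSE]
  groups <- assign_t6ss_group(plasmids$replicon_id, clusters, islands)
  cohort <- stage("traits", cohort_summary(plasmids, groups))

  neighborhoods <- stage("mge", scan_all_neighborhoods(clusters, sim$annotations))
  mge_assoc <- if (nrow(neighborhoods) &&
                   length(unique(attr(neighborhoods, "locus_summary")$classification)) > 1L)
    stage("mge", family_association(neighborhoods)) else NULL

  ## transfer network over T6SS-positive replicons (planted communities by
  ## shared near-identical proteins)
  positive <- unique(clusters$replicon_id)
  network <- NULL; communities <- NULL
  if (length(positive) >= 2L) {
    spec <- list(list(replicons = positive[seq_len(ceiling(length(positive) / 2))],
                      shared = 10L),
                 list(replicons = positive[-seq_len(ceiling(length(positive) / 2))],
                      shared = 10L))
    spec <- Filter(function(s) length(s$replicons) > 0L, spec)
    hpc <- stage("network", simulate_hpc_table(spec, noise = 1, seed = config$seed))
    network <- stage("network", build_bipartite(hpc, sim$metadata))
    communities <- stage("network",
                         detect_communities(network, seed = config$seed))
  }

  phylo <- stage("phylo", {
    ct <- simulate_compartment_tree(n_tree_tips, branch_rate = 1,
                                    switch_rate = 0.1, seed = config$seed)
    rec <- ancestral_states(ct$tree, ct$tip_states)
    trans <- count_transitions(rec)
    list(n_tips = n_tree_tips, pi = rec$pi,
         planted_transitions = nrow(ct$transitions),
         inferred_counts = trans$counts)
  })

  tests <- stage("stats", {
    tb <- cohort$tables
    lapply(tb, function(m) {
      r <- fisher_exact(m)
      list(table = m, p = r$p, odds_ratio = r$odds_ratio)
    })
  })

  report <- structure(list(
    dataset = list(
      n_plasmids = sum(sim$metadata$kind == "plasmid"),
      n_chromosomes = sum(sim$metadata$kind == "chromosome"),
      n_genes = nrow(sim$annotations)),
    clusters = list(
      calls = as.data.frame(clusters),
      by_classification = table(clusters$classification),
      component_histogram = compdist$histogram),
    island_inventory = islands$inventory,
    cohort = cohort,
    mge = list(neighborhoods = neighborhoods, association = mge_assoc),
    network = list(communities = communities),
    phylo = phylo,
    tests = tests,
    provenance = list(seed = config$seed,
                      thresholds = unclass(thresholds),
                      package_version = as.character(utils::packageVersion("t6sscope")))),
    class = "pipeline_report")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(as.data.frame(clusters), file.path(outdir, "clusters.tsv"))
    write_tsv(islands$inventory, file.path(outdir, "island_inventory.tsv"))
    write_tsv(profiles, file.path(outdir, "profiles.tsv"))
    if (!is.null(communities))
      write_tsv(communities, file.path(outdir, "communities.tsv"))
    jsonlite::write_json(report_to_json(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

report_to_json <- function(report) {
  list(dataset = report$dataset,
       clusters_by_classification = as.list(report$clusters$by_classification),
       island_inventory = report$island_inventory,
       cohort_counts = report$cohort$counts,
       transitions = as.list(report$phylo$inferred_counts),
       tests = lapply(report$tests, function(t)
         list(p = t$p, odds_ratio = t$odds_ratio)),
       provenance = report$provenance)
}

#' Render a pipeline report as text
#'
#' Deterministic plain-text summary; percentages print to one decimal.
#'
#' @param report a [run_pipeline()] result.
#' @return character vector of lines, invisibly printed.
#' @export
render_summary <- function(report) {
  fmt_pct <- function(x) ifelse(is.na(x), "undefined", sprintf("%.1f%%", x))
  lines <- c(
    "== t6sscope pipeline report ==",
    sprintf("replicons: %d plasmids, %d chromosomes",
            report$dataset$n_plasmids, report$dataset$n_chromosomes),
    sprintf("clusters: %s",
            paste(sprintf("%s=%d", names(report$clusters$by_classification),
                          report$clusters$by_classification), collapse = ", ")),
    "island inventory:",
    sprintf("  %-14s %4d islands on %4d replicons",
            report$island_inventory$island_type,
            report$island_inventory$n_islands,
            report$island_inventory$n_replicons),
    "cohort:",
    sprintf("  %-14s n=%4d megaplasmid=%s conjugative=%s",
            report$cohort$counts$group, report$cohort$counts$n,
            fmt_pct(report$cohort$counts$pct_megaplasmid),
            fmt_pct(100 * report$cohort$counts$prop_conjugative)),
    if (is.null(report$network$communities))
      "communities: none detected"
    else sprintf("communities: %d (%d mixed)",
                 nrow(report$network$communities),
                 sum(report$network$communities$compartment_mix == "mixed")),
    sprintf("compartment transitions: P->C=%d, C->P=%d (planted %d)",
            report$phylo$inferred_counts[["plasmid_to_chromosome"]],
            report$phylo$inferred_counts[["chromosome_to_plasmid"]],
            report$phylo$planted_transitions),
    sprintf("tests: %s",
            paste(sprintf("%s p=%.3g", names(report$tests),
                          vapply(report$tests, `[[`, numeric(1L), "p")),
                  collapse = "; ")))
  lines
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}
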