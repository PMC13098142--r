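## Synthetic annotated replicons, trees, and protein-cluster tables with
## known ground truth. Gene order is the coordinate system (0-based ordinals,
## half-open spans); physical bp lengths are synthesized only for size
## bookkeeping. Each replicon consumes its own pseudo-random stream derived
## from (seed, replicon id), so adding replicons never perturbs existing
## ones.

default_taxonomy_pool <- function() {
  data.frame(
    species = c("Escherichia coli", "Klebsiella pneumoniae",
                "Campylobacter jejuni", "Campylobacter coli",
                "Vibrio cholerae", "Rhizobium leguminosarum",
                "Burkholderia cenocepacia", "Yersinia enterocolitica"),
    genus = c("Escherichia", "Klebsiella", "Campylobacter", "Campylobacter",
              "Vibrio", "Rhizobium", "Burkholderia", "Yersinia"),
    family = c("Enterobacteriaceae", "Enterobacteriaceae",
               "Campylobacteraceae", "Campylobacteraceae", "Vibrionaceae",
               "Rhizobiaceae", "Burkholderiaceae", "Yersiniaceae"),
    order_ = c("Enterobacterales", "Enterobacterales", "Campylobacterales",
               "Campylobacterales", "Vibrionales", "Hyphomicrobiales",
               "Burkholderiales", "Enterobacterales"),
    class_ = c("Gammaproteobacteria", "Gammaproteobacteria",
               "Epsilonproteobacteria", "Epsilonproteobacteria",
               "Gammaproteobacteria", "Alphaproteobacteria",
               "Betaproteobacteria", "Gammaproteobacteria"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Parameters of the synthetic replicon generator. Defaults emulate a cohort
#' of T6SS-relevant plasmids and host chromosomes: roughly a third of
#' plasmids carry a planted complete system, a quarter carry an orphan
#' island, plasmid GC runs a few percentage points below the host chromosome,
#' and half of the planted loci have a mobile-element gene in their
#' 20-gene neighborhood.
#'
#' @param n_plasmids,n_chromosomes replicon counts (their sum must be >= 1).
#' @param genes_per_replicon list `meanlog`, `sdlog`, `min`: log-normal gene
#'   count per replicon, floored at `min`.
#' @param p_complete_cluster probability that a replicon carries one planted
#'   complete cluster (8-14 distinct components).
#' @param p_orphan_island probability of one planted orphan island.
#' @param island_type_weights named nonnegative weights over the multi-gene
#'   island types (`hcp-vgrG`, `hcp-PAAR`, `vgrG-PAAR`, `hcp-vgrG-PAAR`,
#'   `hcp-hcp`, `vgrG-vgrG`).
#' @param p_isolated_gene probability of one planted isolated hcp or vgrG.
#' @param mge_neighbor_prob probability that a planted locus receives an IS
#'   gene in its 20-gene window.
#' @param trait_probs named probabilities for `relaxase`, `mpf` (conditional
#'   on a relaxase), `partition`, `ta`, `amr`, `vf` on plasmids.
#' @param gc_host_mean,gc_host_sd host chromosome GC fraction distribution.
#' @param gc_plasmid_offset_mean,gc_plasmid_offset_sd plasmid GC offset from
#'   the host chromosome (fraction; default mean -0.035).
#' @param size_params list of `plasmid` and `chromosome` log-normal bp-size
#'   parameters (`meanlog`, `sdlog`).
#' @param taxonomy_pool data frame of host taxonomies (`species`, `genus`,
#'   `family`, `order_`, `class_`).
#' @param family_medians named vector of median genome sizes (bp) per host
#'   family, used for megaplasmid bookkeeping in the metadata.
#' @param seed integer master seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_plasmids = 40L, n_chromosomes = 15L,
    genes_per_replicon = list(meanlog = log(150), sdlog = 0.3, min = 90L),
    p_complete_cluster = 0.30, p_orphan_island = 0.25,
    island_type_weights = c("hcp-vgrG" = 0.35, "hcp-PAAR" = 0.15,
                            "vgrG-PAAR" = 0.15, "hcp-vgrG-PAAR" = 0.10,
                            "hcp-hcp" = 0.15, "vgrG-vgrG" = 0.10),
    p_isolated_gene = 0.15, mge_neighbor_prob = 0.5,
    trait_probs = c(relaxase = 0.45, mpf = 0.70, partition = 0.80,
                    ta = 0.75, amr = 0.10, vf = 0.20),
    gc_host_mean = 0.50, gc_host_sd = 0.05,
    gc_plasmid_offset_mean = -0.035, gc_plasmid_offset_sd = 0.015,
    size_params = list(plasmid = list(meanlog = log(150e3), sdlog = 0.9),
                       chromosome = list(meanlog = log(4.5e6), sdlog = 0.2)),
    taxonomy_pool = default_taxonomy_pool(),
    family_medians = c(Enterobacteriaceae = 5.0e6, Campylobacteraceae = 1.7e6,
                       Vibrionaceae = 4.9e6, Rhizobiaceae = 6.9e6,
                       Burkholderiaceae = 7.0e6, Yersiniaceae = 4.8e6),
    seed = 1L) {
  n_plasmids <- check_count(n_plasmids, "n_plasmids")
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  if (n_plasmids + n_chromosomes < 1L)
    stop_field("n_plasmids", "n_plasmids + n_chromosomes must be >= 1")
  for (f in c("p_complete_cluster", "p_orphan_island", "p_isolated_gene",
              "mge_neighbor_prob"))
    check_prob(get(f), f)
  for (f in names(trait_probs)) check_prob(trait_probs[[f]], paste0("trait_probs.", f))
  if (any(island_type_weights < 0) || sum(island_type_weights) == 0)
    stop_field("island_type_weights", "weights must be nonnegative, not all zero")
  check_prob(gc_host_mean, "gc_host_mean")
  seed <- check_count(seed, "seed")
  fields <- names(formals(simulation_config))
  structure(mget(fields), class = "simulation_config")
}

island_components <- function(type) {
  switch(type,
         "hcp-vgrG" = c("tssD", "tssI"),
         "hcp-PAAR" = c("tssD", "evpJ"),
         "vgrG-PAAR" = c("tssI", "evpJ"),
         "hcp-vgrG-PAAR" = c("tssD", "tssI", "evpJ"),
         "hcp-hcp" = c("tssD", "tssD"),
         "vgrG-vgrG" = c("tssI", "tssI"),
         stop("unknown island type: ", type, call. = FALSE))
}

is_families <- c("IS3", "IS5", "IS110", "IS200/IS605", "ISAs1", "IS6")

## Place feature blocks (vectors of component labels with internal gaps) on a
## gene order of length n, separated by > max_gap background genes.
place_features <- function(n, blocks, max_gap = 20L) {
  if (!length(blocks)) return(structure(list(), n_genes = n))
  k <- length(blocks)
  lens <- vapply(blocks, function(b) b$span_len, integer(1L))
  sep <- max_gap + 5L                 # > max_gap so features never merge
  need <- sum(lens) + sep * (k + 1L)
  n <- max(n, need)
  free <- n - need
  u <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
  out <- vector("list", k)
  acc <- 0L
  for (i in seq_len(k)) {
    out[[i]] <- c(blocks[[i]], list(start = sep * i + acc + u[i]))
    acc <- acc + lens[i]
  }
  attr(out, "n_genes") <- n
  out
}

make_block <- function(components, gaps) {
  ords <- integer(length(components))
  o <- 0L
  for (i in seq_along(components)) {
    ords[i] <- o
    o <- o + 1L + if (i < length(components)) gaps[i] else 0L
  }
  list(components = components, offsets = ords,
       span_len = ords[length(ords)] + 1L)
}

#' Simulate annotated replicons with planted T6SS features
#'
#' Generates an ordered gene table per replicon with optional planted
#' complete clusters, orphan islands, and isolated hcp/vgrG genes (separated
#' by more than the detection gap so distinct features are never merged),
#' IS genes in locus neighborhoods, per-plasmid mobility and maintenance
#' traits, replicon metadata (size, GC, taxonomy, family median genome size),
#' and a ground-truth record of everything planted. Background genes never
#' carry T6SS labels.
#'
#' @param config a [simulation_config()].
#' @return list with elements `annotations` (gene table: `replicon_id`,
#'   `ordinal`, `strand`, `label`, `category`), `metadata` (replicon table),
#'   `trait_hits` (for [profile_traits()]), and `truth` (list of
#'   `planted_clusters`, `planted_islands`, `planted_isolated`,
#'   `planted_traits`, `planted_mge`).
#' @export
simulate_replicons <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  vocab <- t6ss_vocabulary()
  ids <- c(if (config$n_plasmids) sprintf("P%04d", seq_len(config$n_plasmids)),
           if (config$n_chromosomes) sprintf("C%04d", seq_len(config$n_chromosomes)))
  kinds <- c(rep("plasmid", config$n_plasmids),
             rep("chromosome", config$n_chromosomes))

  ann <- list(); meta <- list(); hits <- list()
  t_clusters <- list(); t_islands <- list(); t_isolated <- list()
  t_traits <- list(); t_mge <- list()

  for (i in seq_along(ids)) {
    id <- ids[i]; kind <- kinds[i]
    res <- with_seed(derive_seed(config$seed, id), {
      ## host assignment and chromosome GC come first in the replicon stream
      tax_idx <- sample.int(nrow(config$taxonomy_pool), 1L)
      gc_host <- min(max(stats::rnorm(1, config$gc_host_mean, config$gc_host_sd),
                         0.25), 0.75)
      gp <- config$genes_per_replicon
      n <- max(gp$min, round(stats::rlnorm(1, gp$meanlog, gp$sdlog)))

      blocks <- list()
      if (stats::runif(1) < config$p_complete_cluster) {
        k <- sample(8:14, 1L)
        comps <- sample(vocab$components, k)
        blocks[[length(blocks) + 1L]] <- c(
          make_block(comps, sample(0:3, k - 1L, replace = TRUE)),
          list(role = "complete"))
      }
      if (stats::runif(1) < config$p_orphan_island) {
        type <- sample(names(config$island_type_weights), 1L,
                       prob = config$island_type_weights)
        comps <- island_components(type)
        blocks[[length(blocks) + 1L]] <- c(
          make_block(comps, sample(0:3, length(comps) - 1L, replace = TRUE)),
          list(role = "island", island_type = type))
      }
      if (stats::runif(1) < config$p_isolated_gene) {
        comp <- sample(c("tssD", "tssI"), 1L)
        blocks[[length(blocks) + 1L]] <- c(
          make_block(comp, integer(0)), list(role = "isolated"))
      }
      placed <- place_features(n, blocks,
                               max_gap = detection_thresholds()$max_intervening_genes)
      n <- attr(placed, "n_genes") %||% n

      labels <- sprintf("gene%05d", seq_len(n))
      category <- rep("other", n)
      planted <- list(clusters = NULL, islands = NULL, isolated = NULL,
                      mge = NULL)
      for (b in placed) {
        ords <- b$start + b$offsets
        labels[ords + 1L] <- b$components
        category[ords + 1L] <- "T6SS"
        span <- c(b$start, b$start + b$span_len)
        if (b$role == "complete")
          planted$clusters <- rbind(planted$clusters, data.frame(
            replicon_id = id, start = span[1L], end = span[2L],
            classification = "complete", stringsAsFactors = FALSE))
        else if (b$role == "island")
          planted$islands <- rbind(planted$islands, data.frame(
            replicon_id = id, start = span[1L], end = span[2L],
            island_type = b$island_type, stringsAsFactors = FALSE))
        else
          planted$isolated <- rbind(planted$isolated, data.frame(
            replicon_id = id, ordinal = span[1L], component = b$components,
            stringsAsFactors = FALSE))
        if (stats::runif(1) < config$mge_neighbor_prob) {
          side <- sample(c(-1L, 1L), 1L)
          off <- sample.int(20L, 1L)
          ord <- if (side < 0L) span[1L] - off else span[2L] - 1L + off
          if (ord >= 0L && ord < n && category[ord + 1L] == "other") {
            fam <- sample(is_families, 1L)
            labels[ord + 1L] <- fam
            category[ord + 1L] <- "IS"
            planted$mge <- rbind(planted$mge, data.frame(
              replicon_id = id, ordinal = ord, family = fam,
              locus_start = span[1L], stringsAsFactors = FALSE))
          }
        }
      }
      strand <- sample(c("+", "-"), n, replace = TRUE)

      sz <- config$size_params[[kind]]
      length_bp <- round(stats::rlnorm(1, sz$meanlog, sz$sdlog))
      gc <- if (kind == "chromosome") gc_host else
        min(max(gc_host + stats::rnorm(1, config$gc_plasmid_offset_mean,
                                       config$gc_plasmid_offset_sd), 0.2), 0.8)

      trait <- NULL
      if (kind == "plasmid") {
        tp <- config$trait_probs
        relaxase <- stats::runif(1) < tp[["relaxase"]]
        mpf <- relaxase && stats::runif(1) < tp[["mpf"]]
        mob <- if (relaxase)
          sample(c("MOB_F", "MOB_Q", "MOB_P", "MOB_H", "MOB_C", "MOB_V"), 1L,
                 prob = c(0.30, 0.22, 0.16, 0.16, 0.08, 0.08)) else NA
        mpf_type <- if (mpf)
          sample(c("MPF_F", "MPF_T", "MPF_I", "MPF_G"), 1L,
                 prob = c(0.38, 0.36, 0.14, 0.12)) else NA
        trait <- list(
          mob = mob, mpf = mpf_type,
          partition = if (stats::runif(1) < tp[["partition"]])
            sample(c("I", "II", "III"), 1L + stats::rpois(1, 0.6),
                   replace = TRUE, prob = c(0.8, 0.15, 0.05)) else character(0),
          ta = if (stats::runif(1) < tp[["ta"]]) 1L + stats::rpois(1, 2) else 0L,
          amr = if (stats::runif(1) < tp[["amr"]]) 1L + stats::rpois(1, 1.5) else 0L,
          vf = if (stats::runif(1) < tp[["vf"]])
            sample(c("flgG", "fliI", "flgI", "cheW", "fliP", "cheR"),
                   1L + stats::rpois(1, 1), replace = TRUE) else character(0))
      }
      list(n = n, labels = labels, category = category, strand = strand,
           length_bp = length_bp, gc = gc, gc_host = gc_host,
           tax_idx = tax_idx, planted = planted, trait = trait)
    })

    ann[[i]] <- data.frame(replicon_id = id, ordinal = seq_len(res$n) - 1L,
                           strand = res$strand, label = res$labels,
                           category = res$category, stringsAsFactors = FALSE)
    meta[[i]] <- data.frame(replicon_id = id, kind = kind,
                            length = res$length_bp, gc = res$gc,
                            host_id = sprintf("H%04d", i),
                            config$taxonomy_pool[res$tax_idx, , drop = FALSE],
                            family_median_genome = unname(
                              config$family_medians[
                                config$taxonomy_pool$family[res$tax_idx]]),
                            host_chromosome_gc = res$gc_host,
                            stringsAsFactors = FALSE)
    t_clusters[[i]] <- res$planted$clusters
    t_islands[[i]] <- res$planted$islands
    t_isolated[[i]] <- res$planted$isolated
    t_mge[[i]] <- res$planted$mge

    if (!is.null(res$trait)) {
      tr <- res$trait
      hit <- function(cat, lab) if (length(lab))
        data.frame(replicon_id = id, category = cat, label = lab,
                   stringsAsFactors = FALSE)
      hits[[i]] <- rbind(
        if (!is.na(tr$mob)) hit("relaxase", tr$mob),
        if (!is.na(tr$mpf)) hit("mpf", tr$mpf),
        hit("partition", tr$partition),
        if (tr$ta > 0) hit("ta", paste0("TA", seq_len(tr$ta))),
        if (tr$amr > 0) hit("amr", paste0("amr", seq_len(tr$amr))),
        hit("vf", tr$vf))
      t_traits[[i]] <- data.frame(
        replicon_id = id, mob_class = ifelse(is.na(tr$mob), "none", tr$mob),
        mpf_type = ifelse(is.na(tr$mpf), "none", tr$mpf),
        transmissibility = classify_transmissibility(!is.na(tr$mob), !is.na(tr$mpf)),
        n_partition = length(tr$partition), ta_count = tr$ta,
        amr_count = tr$amr, vf_count = length(tr$vf),
        stringsAsFactors = FALSE)
    }
  }

  bind <- function(lst) {
    out <- do.call(rbind, lst)
    if (is.null(out)) out <- data.frame()
    rownames(out) <- NULL
    out
  }
  list(annotations = bind(ann), metadata = bind(meta),
       trait_hits = bind(hits),
       truth = list(planted_clusters = bind(t_clusters),
                    planted_islands = bind(t_islands),
                    planted_isolated = bind(t_isolated),
                    planted_traits = bind(t_traits),
                    planted_mge = bind(t_mge)))
}

#' Simulate a tree with a two-state compartment character
#'
#' Draws a random binary tree topology with exponential branch lengths and
#' evolves the plasmid/chromosome state along it as a continuous-time
#' two-state Markov chain with symmetric switch rate, recording every true
#' switch event per branch.
#'
#' @param n_tips number of tips (>= 2).
#' @param branch_rate rate of the exponential branch-length distribution
#'   (mean length = 1/rate).
#' @param switch_rate compartment switch rate per unit branch length.
#' @param seed integer seed.
#' @param root_state `"plasmid"`, `"chromosome"`, or `"random"` (stationary
#'   50/50 draw).
#' @return list with `tree` (`ape::phylo`), `tip_states` (named vector),
#'   `root_state`, and `transitions` (data frame `edge`, `parent`, `child`,
#'   `direction` in `{"P->C", "C->P"}`, one row per switch event).
#' @export
simulate_compartment_tree <- function(n_tips, branch_rate = 1,
                                      switch_rate = 0.1, seed = 1L,
                                      root_state = "random") {
  if (n_tips < 2L) stop("n_tips must be >= 2", call. = FALSE)
  if (branch_rate < 0 || switch_rate < 0)
    stop("rates must be nonnegative", call. = FALSE)
  with_seed(derive_seed(seed, "tree"), {
    tree <- ape::rtree(n_tips, br = function(n) stats::rexp(n, branch_rate))
    tree <- stats::reorder(tree, "cladewise")   # parents before children
    m <- n_tips + tree$Nnode
    state <- character(m)
    root <- n_tips + 1L
    state[root] <- if (root_state == "random")
      sample(compartment_states, 1L) else match.arg(root_state, compartment_states)
    events <- list()
    ## edges of ape trees are listed parent-before-child within each subtree
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
      s <- state[parent]; t_rem <- tree$edge.length[e]
      repeat {
        if (switch_rate == 0) break
        wait <- stats::rexp(1, switch_rate)
        if (wait >= t_rem) break
        t_rem <- t_rem - wait
        dir <- if (s == "plasmid") "P->C" else "C->P"
        s <- setdiff(compartment_states, s)
        events[[length(events) + 1L]] <- data.frame(
          edge = e, parent = parent, child = child, direction = dir,
          stringsAsFactors = FALSE)
      }
      state[child] <- s
    }
    transitions <- if (length(events)) do.call(rbind, events) else
      data.frame(edge = integer(), parent = integer(), child = integer(),
                 direction = character(), stringsAsFactors = FALSE)
    list(tree = tree,
         tip_states = stats::setNames(state[seq_len(n_tips)], tree$tip.label),
         root_state = state[root], transitions = transitions)
  })
}

#' Simulate a protein-cluster membership table with planted communities
#'
#' Every replicon of a planted community encodes one protein in each of the
#' community's shared homologous protein clusters; noise adds private
#' singleton clusters that never connect replicons.
#'
#' @param community_spec named list; each element is a list with `replicons`
#'   (character vector) and `shared` (count of shared HPCs).
#' @param noise expected number of private singleton clusters per replicon
#'   (Poisson; 0 adds none).
#' @param seed integer seed.
#' @return data frame `protein_id`, `replicon_id`, `hpc_id` plus attribute
#'   `"planted_communities"` (named vector replicon -> community id).
#' @export
simulate_hpc_table <- function(community_spec, noise = 0, seed = 1L) {
  if (!length(community_spec)) stop("community spec is empty", call. = FALSE)
  with_seed(derive_seed(seed, "hpc"), {
    rows <- list(); planted <- character(0)
    for (k in seq_along(community_spec)) {
      spec <- community_spec[[k]]
      nm <- names(community_spec)
      cname <- if (is.null(nm) || !nzchar(nm[k])) as.character(k) else nm[k]
      for (j in seq_len(spec$shared))
        for (r in spec$replicons)
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = sprintf("%s|%s_H%03d", r, cname, j),
            replicon_id = r, hpc_id = sprintf("%s_H%03d", cname, j),
            stringsAsFactors = FALSE)
      planted[spec$replicons] <- cname
      if (noise > 0) {
        for (r in spec$replicons) {
          np <- stats::rpois(1, noise)
          if (np > 0)
            for (j in seq_len(np))
              rows[[length(rows) + 1L]] <- data.frame(
                protein_id = sprintf("%s|priv%03d", r, j),
                replicon_id = r, hpc_id = sprintf("%s_priv%03d", r, j),
                stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "planted_communities") <- planted
    out
  })
}

#' Write simulation artifacts to a directory
#'
#' Writes the gene-annotation, metadata and trait-hit tables as TSV and the
#' ground truth as JSON.
#'
#' @param sim result of [simulate_replicons()].
#' @param dir output directory (created if absent).
#' @return invisible vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    annotations = file.path(dir, "annotations.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    trait_hits = file.path(dir, "trait_hits.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_tsv(sim$annotations, paths[["annotations"]])
  write_tsv(sim$metadata, paths[["metadata"]])
  write_tsv(sim$trait_hits, paths[["trait_hits"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
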