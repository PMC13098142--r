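## Bipartite replicon-protein networks, ANI networks, Louvain communities,
## core proteomes, and host-range grading.

#' Build a bipartite replicon-HPC network
#'
#' Nodes are replicons and homologous protein clusters (HPCs); an edge links
#' a replicon to an HPC when the replicon encodes at least one member of the
#' cluster (edge multiplicity 1 regardless of protein copy number).
#'
#' @param hpc_table data frame with columns `replicon_id` and `hpc_id`
#'   (one row per protein; a `protein_id` column is allowed and ignored).
#' @param metadata replicon metadata covering every replicon in the table
#'   (columns `replicon_id`, `kind`, taxonomy, optionally `ptu`).
#' @return igraph bipartite graph; replicon vertices carry `type = FALSE` and
#'   the metadata fields, HPC vertices `type = TRUE` and `member_count`.
#' @export
build_bipartite <- function(hpc_table, metadata) {
  missing_ids <- setdiff(unique(hpc_table$replicon_id), metadata$replicon_id)
  if (length(missing_ids))
    stop("replicon(s) missing from metadata: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  edges <- unique(hpc_table[, c("replicon_id", "hpc_id")])
  rep_ids <- metadata$replicon_id
  hpc_ids <- sort(unique(edges$hpc_id))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(rep_ids), name = rep_ids, type = FALSE)
  g <- igraph::add_vertices(g, length(hpc_ids), name = hpc_ids, type = TRUE)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(match(edges$replicon_id, rep_ids),
                                    length(rep_ids) + match(edges$hpc_id, hpc_ids)))
  for (col in setdiff(names(metadata), "replicon_id")) {
    vals <- rep(NA, igraph::vcount(g))
    vals[seq_along(rep_ids)] <- metadata[[col]]
    g <- igraph::set_vertex_attr(g, col, value = vals)
  }
  counts <- table(edges$hpc_id)
  mc <- rep(NA_integer_, igraph::vcount(g))
  mc[length(rep_ids) + seq_along(hpc_ids)] <- as.integer(counts[hpc_ids])
  igraph::set_vertex_attr(g, "member_count", value = mc)
}

#' Louvain communities of replicons sharing protein clusters
#'
#' Projects the bipartite network onto its replicon side (edge weight = number
#' of shared HPCs) and maximizes modularity with the Louvain heuristic.
#' Isolated replicons are reported as singleton communities.
#'
#' @param network bipartite graph from [build_bipartite()].
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed integer seed making the heuristic deterministic.
#' @return data frame, one row per community: `community`, `n_members`,
#'   `members` (comma-joined), `compartment_mix`
#'   (`plasmid_only`/`chromosome_only`/`mixed`), `ptus`, `host_range_grade`
#'   (`NA` for singletons), plus a per-replicon membership map as attribute
#'   `"membership"`.
#' @export
detect_communities <- function(network, resolution = 1, seed = 1L) {
  proj <- igraph::bipartite_projection(network, which = "false")
  memb <- with_seed(seed, igraph::membership(
    igraph::cluster_louvain(proj, weights = igraph::E(proj)$weight,
                            resolution = resolution)))
  ids <- igraph::V(proj)$name
  repl <- igraph::V(network)[!igraph::V(network)$type]
  kind <- igraph::vertex_attr(network, "kind", repl)
  ptu <- if ("ptu" %in% igraph::vertex_attr_names(network))
    igraph::vertex_attr(network, "ptu", repl) else rep(NA_character_, length(ids))
  tax_cols <- intersect(c("species", "genus", "family", "order_", "class_"),
                        igraph::vertex_attr_names(network))
  tax <- as.data.frame(lapply(tax_cols, function(cl)
    igraph::vertex_attr(network, cl, igraph::V(network)[!igraph::V(network)$type])),
    col.names = tax_cols, stringsAsFactors = FALSE)
  rows <- lapply(sort(unique(memb)), function(cid) {
    sel <- memb == cid
    kinds <- unique(kind[sel])
    mix <- if (identical(kinds, "plasmid")) "plasmid_only"
    else if (identical(kinds, "chromosome")) "chromosome_only" else "mixed"
    grade <- if (sum(sel) >= 2L && ncol(tax) == 5L)
      host_range_grade(tax[sel, , drop = FALSE]) else NA_character_
    data.frame(community = cid, n_members = sum(sel),
               members = paste(ids[sel], collapse = ","),
               compartment_mix = mix,
               ptus = paste(sort(unique(stats::na.omit(ptu[sel]))), collapse = ","),
               host_range_grade = grade, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "membership") <- stats::setNames(as.integer(memb), ids)
  out
}

#' Host-range grade of a set of taxonomies
#'
#' The grade is the shallowest taxonomic rank at which all members agree:
#' I same species (different strains), II same genus, III same family,
#' IV same order, V same class; `"beyond_V"` when members disagree even at
#' class rank.
#'
#' @param taxonomies data frame with columns `species`, `genus`, `family`,
#'   `order_`, `class_` (one row per member; at least two rows).
#' @return grade string.
#' @export
host_range_grade <- function(taxonomies) {
  if (nrow(taxonomies) < 2L)
    stop("need at least two taxonomies", call. = FALSE)
  ranks <- c(species = "I", genus = "II", family = "III",
             order_ = "IV", class_ = "V")
  for (r in names(ranks)) {
    if (length(unique(taxonomies[[r]])) == 1L) return(unname(ranks[[r]]))
  }
  warning("members disagree at class rank", call. = FALSE)
  "beyond_V"
}

#' Core proteome of a plasmid taxonomic unit
#'
#' @param hpc_table protein-cluster membership restricted to the PTU members
#'   (`replicon_id`, `hpc_id`).
#' @param members character vector of the PTU's replicon ids (>= 2).
#' @param threshold minimal fraction of members encoding the HPC
#'   (default 0.8, inclusive).
#' @return character vector of core HPC ids.
#' @export
core_proteome <- function(hpc_table, members, threshold = 0.8) {
  if (length(members) < 2L) stop("PTU needs at least 2 members", call. = FALSE)
  tab <- unique(hpc_table[hpc_table$replicon_id %in% members,
                          c("replicon_id", "hpc_id")])
  counts <- table(tab$hpc_id)
  names(counts)[counts / length(members) >= threshold]
}

#' Plasmid similarity network from pairwise ANI with a coverage gate
#'
#' An edge joins two replicons when the aligned fraction of the shorter
#' replicon reaches `min_cov` (inclusive); the edge weight is the ANI value.
#' Self-pairs are ignored.
#'
#' @param ani_table data frame `replicon_a`, `replicon_b`, `ani` (fraction),
#'   `coverage` (aligned fraction of the shorter replicon).
#' @param min_cov minimal coverage (default 0.5).
#' @return undirected igraph graph with `weight` = ANI.
#' @export
ani_network <- function(ani_table, min_cov = 0.5) {
  if (any(ani_table$ani < 0 | ani_table$ani > 1 |
          ani_table$coverage < 0 | ani_table$coverage > 1))
    stop("ANI and coverage values must lie in [0, 1]", call. = FALSE)
  tab <- ani_table[ani_table$replicon_a != ani_table$replicon_b, , drop = FALSE]
  ## symmetrize: keep one canonical orientation per pair
  key <- paste(pmin(tab$replicon_a, tab$replicon_b),
               pmax(tab$replicon_a, tab$replicon_b))
  tab <- tab[!duplicated(key), , drop = FALSE]
  keep <- tab$coverage >= min_cov
  nodes <- sort(unique(c(ani_table$replicon_a, ani_table$replicon_b)))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(match(tab$replicon_a[keep], nodes),
                                    match(tab$replicon_b[keep], nodes)),
                           weight = tab$ani[keep])
  g
}

#' Cross-tabulate community co-membership and shared IS families
#'
#' Counts, for every pair of genomic entities (PTU labels, `"PTU_NA"` for
#' unassigned plasmids, `"Chr"` for chromosomes), how many Louvain
#' communities contain both. A community is flagged `shared_is_family` when
#' some IS family occurs in the MGE window reports of members from both
#' compartments.
#'
#' @param communities result of [detect_communities()].
#' @param metadata replicon metadata (`replicon_id`, `kind`, `ptu`).
#' @param neighborhoods optional [scan_all_neighborhoods()] result whose rows
#'   carry `replicon_id` and `family`.
#' @return list with `pairs` (data frame `entity_a`, `entity_b`,
#'   `n_communities`) and `community_flags` (data frame `community`,
#'   `shared_is_family`).
#' @export
community_cross_tab <- function(communities, metadata, neighborhoods = NULL) {
  entity_of <- function(id) {
    i <- match(id, metadata$replicon_id)
    if (metadata$kind[i] == "chromosome") "Chr"
    else if (!is.null(metadata$ptu) && !is.na(metadata$ptu[i]) &&
             nzchar(metadata$ptu[i])) metadata$ptu[i]
    else "PTU_NA"
  }
  pair_rows <- list(); flag_rows <- list()
  for (k in seq_len(nrow(communities))) {
    ids <- strsplit(communities$members[k], ",", fixed = TRUE)[[1L]]
    ents <- sort(unique(vapply(ids, entity_of, character(1L))))
    if (length(ents) >= 2L) {
      cmb <- utils::combn(ents, 2L)
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(entity_a = cmb[1L, ], entity_b = cmb[2L, ],
                   stringsAsFactors = FALSE)
    }
    shared <- FALSE
    if (!is.null(neighborhoods) && nrow(neighborhoods)) {
      nb <- neighborhoods[neighborhoods$replicon_id %in% ids, , drop = FALSE]
      if (nrow(nb)) {
        nb$kind <- metadata$kind[match(nb$replicon_id, metadata$replicon_id)]
        fam_comp <- unique(nb[, c("family", "kind")])
        shared <- any(table(fam_comp$family) >= 2L)
      }
    }
    flag_rows[[k]] <- data.frame(community = communities$community[k],
                                 shared_is_family = shared,
                                 stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) {
    p <- do.call(rbind, pair_rows)
    stats::aggregate(n_communities ~ entity_a + entity_b,
                     cbind(p, n_communities = 1L), sum)
  } else data.frame(entity_a = character(), entity_b = character(),
                    n_communities = integer(), stringsAsFactors = FALSE)
  list(pairs = pairs, community_flags = do.call(rbind, flag_rows))
}
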