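## T6SS cluster detection and classification on ordered gene tables.
##
## The coordinate system is gene order: ordinals are 0-based indices into the
## annotation table of a replicon, spans are half-open [start, end). The scan
## groups consecutive T6SS hits whenever the number of genes strictly between
## them does not exceed the intervening-gene maximum, then filters groups by
## the number of distinct components.

#' Detection thresholds
#'
#' Parameters of the cluster scan and the completeness classification.
#'
#' @param max_intervening_genes maximum number of non-T6SS genes allowed
#'   between two consecutive T6SS hits of the same cluster (default 20).
#' @param min_distinct_genes minimum number of distinct components for a hit
#'   group to be reported as a cluster (default 2).
#' @param complete_min_distinct minimum number of distinct components for a
#'   cluster to be classified as a complete system (default 8).
#' @param phylo_min_distinct distinct-component count above which clusters are
#'   flagged for phylogenetic follow-up (default 10).
#' @return object of class `detection_thresholds`.
#' @export
detection_thresholds <- function(max_intervening_genes = 20L,
                                 min_distinct_genes = 2L,
                                 complete_min_distinct = 8L,
                                 phylo_min_distinct = 10L) {
  max_intervening_genes <- check_count(max_intervening_genes, "max_intervening_genes", 1L)
  min_distinct_genes <- check_count(min_distinct_genes, "min_distinct_genes", 1L)
  complete_min_distinct <- check_count(complete_min_distinct, "complete_min_distinct", 1L)
  phylo_min_distinct <- check_count(phylo_min_distinct, "phylo_min_distinct", 1L)
  if (complete_min_distinct < min_distinct_genes)
    stop_field("complete_min_distinct", "must be >= min_distinct_genes")
  structure(list(max_intervening_genes = max_intervening_genes,
                 min_distinct_genes = min_distinct_genes,
                 complete_min_distinct = complete_min_distinct,
                 phylo_min_distinct = phylo_min_distinct),
            class = "detection_thresholds")
}

## Orphan island combinations of distinct component sets, in canonical naming.
island_type_of <- function(components) {
  key <- paste(sort(unique(components)), collapse = "+")
  switch(key,
         "tssD+tssI" = "hcp-vgrG",
         "evpJ+tssD" = "hcp-PAAR",
         "evpJ+tssI" = "vgrG-PAAR",
         "evpJ+tssD+tssI" = "hcp-vgrG-PAAR",
         "none")
}

validate_gene_table <- function(genes) {
  need <- c("replicon_id", "ordinal", "label")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  dup <- stats::aggregate(ordinal ~ replicon_id, genes,
                          function(o) anyDuplicated(o) > 0L)
  bad <- dup$replicon_id[dup$ordinal]
  if (length(bad))
    stop("duplicate ordinal on replicon(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(genes)
}

#' Scan a gene table for T6SS clusters
#'
#' Groups consecutive T6SS hits on each replicon whenever the number of genes
#' strictly between them is at most `thresholds$max_intervening_genes`
#' (strand-agnostic, matching MacSyFinder's inter-gene-max-space semantics).
#' Groups with fewer than `min_distinct_genes` distinct components are
#' discarded and their members demoted to isolated-gene candidates. Each
#' retained group is classified with [classify_cluster()].
#'
#' @param genes data frame with columns `replicon_id`, `ordinal` (0-based gene
#'   index), `label`; a `category` column is used to warn about rows marked as
#'   T6SS whose label is not in the vocabulary.
#' @param thresholds a [detection_thresholds()] object.
#' @param circular if `TRUE`, a cluster spanning the origin is merged by
#'   wrap-around (requires `n_genes`). Default linear.
#' @param n_genes named integer vector of gene counts per replicon; only
#'   needed for circular merging. Defaults to `max(ordinal) + 1` per replicon.
#' @return data frame of class `t6ss_clusters`, one row per cluster, columns
#'   `replicon_id`, `start`, `end` (half-open ordinal span covering the first
#'   and last member hit), `n_hits`, `n_distinct`, `components` (comma-joined
#'   distinct canonical names), `labels` (comma-joined raw member labels),
#'   `classification`, `island_type`. Demoted sub-threshold members are
#'   attached as attribute `"demoted"` (data frame `replicon_id`, `ordinal`,
#'   `component`), member hits as attribute `"members"`.
#' @seealso [classify_cluster()], [find_isolated_genes()]
#' @export
scan_clusters <- function(genes, thresholds = detection_thresholds(),
                          circular = FALSE, n_genes = NULL) {
  stopifnot(inherits(thresholds, "detection_thresholds"))
  validate_gene_table(genes)
  genes <- genes[order(genes$replicon_id, genes$ordinal), , drop = FALSE]
  comp <- normalize_component(genes$label)
  if (!is.null(genes$category)) {
    odd <- !is.na(genes$category) & genes$category == "T6SS" & is.na(comp)
    if (any(odd))
      warning(sum(odd), " T6SS-category row(s) with unrecognized label ignored",
              call. = FALSE)
  }
  hits <- data.frame(replicon_id = genes$replicon_id[!is.na(comp)],
                     ordinal = genes$ordinal[!is.na(comp)],
                     label = genes$label[!is.na(comp)],
                     component = comp[!is.na(comp)],
                     stringsAsFactors = FALSE)

  clusters <- list(); members <- list(); demoted <- list()
  for (rep_id in unique(hits$replicon_id)) {
    h <- hits[hits$replicon_id == rep_id, , drop = FALSE]
    gap <- diff(h$ordinal) - 1L          # genes strictly between hits
    grp <- cumsum(c(0L, gap > thresholds$max_intervening_genes))
    if (circular && length(unique(grp)) > 1L) {
      ng <- if (!is.null(n_genes)) n_genes[[rep_id]] else max(h$ordinal) + 1L
      wrap_gap <- (ng - 1L - max(h$ordinal)) + min(h$ordinal)
      if (wrap_gap <= thresholds$max_intervening_genes)
        grp[grp == max(grp)] <- 0L       # merge origin-spanning group
    }
    for (g in unique(grp)) {
      m <- h[grp == g, , drop = FALSE]
      if (length(unique(m$component)) < thresholds$min_distinct_genes) {
        demoted[[length(demoted) + 1L]] <- m[, c("replicon_id", "ordinal", "component")]
      } else {
        cl <- classify_cluster(m, thresholds)
        clusters[[length(clusters) + 1L]] <- cl
        members[[length(members) + 1L]] <-
          cbind(m, cluster = nrow_clusters(clusters))
      }
    }
  }
  out <- if (length(clusters)) do.call(rbind, clusters) else empty_clusters()
  out <- out[order(out$replicon_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "demoted") <- if (length(demoted)) do.call(rbind, demoted) else
    data.frame(replicon_id = character(), ordinal = integer(),
               component = character(), stringsAsFactors = FALSE)
  attr(out, "members") <- if (length(members)) do.call(rbind, members) else NULL
  attr(out, "thresholds") <- thresholds
  class(out) <- c("t6ss_clusters", "data.frame")
  out
}

nrow_clusters <- function(lst) length(lst)

empty_clusters <- function() {
  data.frame(replicon_id = character(), start = integer(), end = integer(),
             n_hits = integer(), n_distinct = integer(), components = character(),
             labels = character(), classification = character(),
             island_type = character(), stringsAsFactors = FALSE)
}

#' Classify a hit group as complete, incomplete, or orphan island
#'
#' A cluster is complete when it holds at least `complete_min_distinct`
#' distinct components (multi-copy components are counted once). Otherwise it
#' is an orphan island when its distinct components are exactly one of the
#' combinations hcp-vgrG, hcp-PAAR, vgrG-PAAR, or hcp-vgrG-PAAR with no other
#' component present; anything else is incomplete.
#'
#' @param members data frame of member hits with columns `replicon_id`,
#'   `ordinal`, `label`, `component` (canonical names).
#' @param thresholds a [detection_thresholds()] object.
#' @return one-row data frame in the [scan_clusters()] layout.
#' @export
classify_cluster <- function(members, thresholds = detection_thresholds()) {
  distinct <- sort(unique(members$component))
  itype <- island_type_of(distinct)
  classification <- if (length(distinct) >= thresholds$complete_min_distinct)
    "complete"
  else if (itype != "none") "orphan_island"
  else "incomplete"
  if (classification != "orphan_island") itype <- "none"
  data.frame(replicon_id = members$replicon_id[1L],
             start = min(members$ordinal),
             end = max(members$ordinal) + 1L,
             n_hits = nrow(members),
             n_distinct = length(distinct),
             components = paste(distinct, collapse = ","),
             labels = paste(members$label, collapse = ","),
             classification = classification,
             island_type = itype,
             stringsAsFactors = FALSE)
}

#' Find isolated hcp/vgrG genes and build the island inventory
#'
#' Reports every tssD (hcp) or tssI (vgrG) hit lying outside all detected
#' cluster spans, including members of discarded sub-threshold groups. Two
#' isolated hits of the same component within `max_intervening_genes` of each
#' other form a homotypic island (hcp-hcp or vgrG-vgrG); remaining hits are
#' single-gene islands (hcp or vgrG).
#'
#' @param genes the gene table passed to [scan_clusters()].
#' @param clusters result of [scan_clusters()] on the same table.
#' @return list with elements `isolated` (data frame `replicon_id`, `ordinal`,
#'   `component`), `homotypic_islands` (data frame `replicon_id`, `start`,
#'   `end`, `island_type`), and `inventory` (data frame `island_type`,
#'   `n_islands`, `n_replicons` over all eight island types).
#' @export
find_isolated_genes <- function(genes, clusters) {
  thresholds <- attr(clusters, "thresholds") %||% detection_thresholds()
  comp <- normalize_component(genes$label)
  keep <- !is.na(comp) & comp %in% c("tssD", "tssI")
  cand <- data.frame(replicon_id = genes$replicon_id[keep],
                     ordinal = genes$ordinal[keep],
                     component = comp[keep], stringsAsFactors = FALSE)
  if (nrow(cand) && nrow(clusters)) {
    inside <- vapply(seq_len(nrow(cand)), function(i) {
      cl <- clusters[clusters$replicon_id == cand$replicon_id[i], , drop = FALSE]
      any(cand$ordinal[i] >= cl$start & cand$ordinal[i] < cl$end)
    }, logical(1L))
    cand <- cand[!inside, , drop = FALSE]
  }
  cand <- cand[order(cand$replicon_id, cand$ordinal), , drop = FALSE]
  rownames(cand) <- NULL

  ## pair same-component neighbours into homotypic islands
  homo <- list(); paired <- rep(FALSE, nrow(cand))
  if (nrow(cand) > 1L) {
    for (i in seq_len(nrow(cand) - 1L)) {
      if (paired[i]) next
      j <- which(!paired & cand$replicon_id == cand$replicon_id[i] &
                   cand$component == cand$component[i] &
                   cand$ordinal > cand$ordinal[i] &
                   cand$ordinal - cand$ordinal[i] - 1L <= thresholds$max_intervening_genes)
      if (length(j)) {
        j <- j[1L]
        paired[c(i, j)] <- TRUE
        homo[[length(homo) + 1L]] <- data.frame(
          replicon_id = cand$replicon_id[i],
          start = cand$ordinal[i], end = cand$ordinal[j] + 1L,
          island_type = if (cand$component[i] == "tssD") "hcp-hcp" else "vgrG-vgrG",
          stringsAsFactors = FALSE)
      }
    }
  }
  homo <- if (length(homo)) do.call(rbind, homo) else
    data.frame(replicon_id = character(), start = integer(), end = integer(),
               island_type = character(), stringsAsFactors = FALSE)
  singles <- cand[!paired, , drop = FALSE]

  island_levels <- c("hcp", "vgrG", "hcp-hcp", "vgrG-vgrG", "hcp-vgrG",
                     "hcp-PAAR", "vgrG-PAAR", "hcp-vgrG-PAAR")
  entries <- rbind(
    data.frame(replicon_id = singles$replicon_id,
               island_type = ifelse(singles$component == "tssD", "hcp", "vgrG"),
               stringsAsFactors = FALSE),
    homo[, c("replicon_id", "island_type"), drop = FALSE],
    if (nrow(clusters))
      clusters[clusters$classification == "orphan_island",
               c("replicon_id", "island_type"), drop = FALSE]
  )
  inventory <- data.frame(
    island_type = island_levels,
    n_islands = vapply(island_levels, function(t)
      sum(entries$island_type == t), integer(1L)),
    n_replicons = vapply(island_levels, function(t)
      length(unique(entries$replicon_id[entries$island_type == t])), integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL)

  list(isolated = cand, homotypic_islands = homo, inventory = inventory)
}

#' Assign a subtype via diagnostic marker labels
#'
#' @param cluster one row of a [scan_clusters()] result (its `labels` field is
#'   consulted).
#' @param marker_table data frame with columns `marker` and `subtype`
#'   (`"i"`, `"ii"`, `"iii"`), rows in priority order. Matching is
#'   case-insensitive on raw gene labels.
#' @return subtype string; `"unassigned"` when no marker matches (or the table
#'   is empty, with a one-time message).
#' @export
assign_subtype <- function(cluster, marker_table) {
  if (is.null(marker_table) || nrow(marker_table) == 0L) {
    message("empty marker table: all clusters unassigned")
    return("unassigned")
  }
  labels <- tolower(strsplit(cluster$labels, ",", fixed = TRUE)[[1L]])
  hit <- which(tolower(marker_table$marker) %in% labels)
  if (!length(hit)) return("unassigned")
  sub <- unique(marker_table$subtype[hit])
  if (length(sub) > 1L)
    warning("markers of multiple subtypes present; keeping first by priority",
            call. = FALSE)
  marker_table$subtype[hit[1L]]
}

#' Distribution of distinct-component counts and subcomplex presence
#'
#' @param clusters a [scan_clusters()] result.
#' @return list with `histogram` (named integer vector over bins 2..14 of
#'   distinct-component counts) and `subcomplex_presence` (logical data frame,
#'   one row per cluster, one column per structural subcomplex).
#' @export
summarize_component_distribution <- function(clusters) {
  bins <- 2:14
  histogram <- stats::setNames(integer(length(bins)), bins)
  if (nrow(clusters)) {
    tab <- table(factor(clusters$n_distinct, levels = bins))
    histogram[] <- as.integer(tab)
  }
  vocab <- t6ss_vocabulary()
  pres <- as.data.frame(
    do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
      comps <- strsplit(clusters$components[i], ",", fixed = TRUE)[[1L]]
      vapply(vocab$subcomplexes, function(set) any(set %in% comps), logical(1L))
    })))
  if (nrow(clusters) == 0L) {
    pres <- as.data.frame(matrix(logical(0), 0, length(vocab$subcomplexes)))
    names(pres) <- names(vocab$subcomplexes)
  }
  list(histogram = histogram, subcomplex_presence = pres)
}
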