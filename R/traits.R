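## Replicon-level classification: megaplasmid status, transmissibility,
## GC divergence, and maintenance/accessory trait profiles.

#' Megaplasmid classification
#'
#' A plasmid is a megaplasmid when its length is at least 5% of the median
#' genome size of the host's taxonomic family (inclusive boundary).
#'
#' @param length_bp plasmid length in bp (vectorized).
#' @param family_median_genome_bp median genome size of the host family in bp;
#'   `NA` yields `NA` (status unknown, excluded from tallies).
#' @param threshold size ratio defining a megaplasmid (default 0.05).
#' @return logical vector.
#' @examples
#' is_megaplasmid(250000, 5e6)   # TRUE: ratio exactly 0.05
#' @export
is_megaplasmid <- function(length_bp, family_median_genome_bp, threshold = 0.05) {
  if (any(length_bp <= 0, na.rm = TRUE))
    stop_field("length_bp", "must be positive")
  if (any(family_median_genome_bp <= 0, na.rm = TRUE))
    stop_field("family_median_genome_bp", "must be positive")
  length_bp / family_median_genome_bp >= threshold
}

#' Conjugative transmissibility classification
#'
#' Conjugative when both a relaxase and a mating-pair formation (MPF) system
#' are present; mobilizable when only a relaxase is present; non-transmissible
#' otherwise. An MPF system without a relaxase cannot initiate transfer and is
#' classified non-transmissible with a warning.
#'
#' @param relaxase_present,mpf_present logical vectors.
#' @return character vector in
#'   `c("conjugative", "mobilizable", "non_transmissible")`.
#' @export
classify_transmissibility <- function(relaxase_present, mpf_present) {
  if (any(!relaxase_present & mpf_present))
    warning("MPF system without relaxase: classified non_transmissible",
            call. = FALSE)
  ifelse(relaxase_present & mpf_present, "conjugative",
         ifelse(relaxase_present, "mobilizable", "non_transmissible"))
}

#' GC divergence of a plasmid from its host chromosome
#'
#' @param plasmid_gc,host_chromosome_gc GC fractions in (0, 1); a host with
#'   several chromosomes should supply the length-weighted mean.
#' @return signed difference in percentage points,
#'   `100 * (plasmid_gc - host_chromosome_gc)`; `NA` when the host chromosome
#'   GC is missing.
#' @export
gc_divergence <- function(plasmid_gc, host_chromosome_gc) {
  ok <- function(x) is.na(x) | (x > 0 & x < 1)
  if (!all(ok(plasmid_gc)) || !all(ok(host_chromosome_gc)))
    stop("GC fractions must lie in (0, 1)", call. = FALSE)
  100 * (plasmid_gc - host_chromosome_gc)
}

#' Aggregate trait hits into per-replicon profiles
#'
#' @param metadata replicon metadata data frame: `replicon_id`, `kind`
#'   (`"plasmid"`/`"chromosome"`), `length`, `gc`, `host_id`, taxonomy columns
#'   (`species`, `genus`, `family`, `order_`, `class_`),
#'   `family_median_genome`, optionally `ptu` and `host_chromosome_gc`.
#' @param trait_hits data frame of annotation hits: `replicon_id`, `category`
#'   (one of `"relaxase"`, `"mpf"`, `"partition"`, `"ta"`, `"amr"`, `"vf"`),
#'   `label` (e.g. the MOB class for relaxases, MPF type, partition type
#'   I/II/III, gene name for AMR/VF).
#' @param mob_precedence order used to pick the primary MOB class when a
#'   replicon carries several relaxases (all are retained in `mob_all`).
#' @return data frame with one row per replicon: megaplasmid flag, primary
#'   MOB class and MPF type, transmissibility, partition counts by type,
#'   `ta_count`, `amr_count`, `vf_count`, `vf_labels`, `gc_diff` (percentage
#'   points, when host chromosome GC is available).
#' @export
profile_traits <- function(metadata, trait_hits,
                           mob_precedence = c("MOB_F", "MOB_Q", "MOB_P",
                                              "MOB_H", "MOB_C", "MOB_V")) {
  hit_of <- function(id, cat) trait_hits$label[
    trait_hits$replicon_id == id & trait_hits$category == cat]
  prof <- lapply(seq_len(nrow(metadata)), function(i) {
    id <- metadata$replicon_id[i]
    mobs <- unique(hit_of(id, "relaxase"))
    if (length(mobs) > 1L) {
      mobs <- mobs[order(match(mobs, mob_precedence))]
      message("replicon ", id, ": multiple MOB classes, primary = ", mobs[1L])
    }
    mpfs <- unique(hit_of(id, "mpf"))
    part <- hit_of(id, "partition")
    vf <- hit_of(id, "vf")
    data.frame(
      replicon_id = id,
      kind = metadata$kind[i],
      length = metadata$length[i],
      gc = metadata$gc[i],
      family = metadata$family[i],
      megaplasmid = if (metadata$kind[i] == "plasmid" &&
                        !is.na(metadata$family_median_genome[i]))
        is_megaplasmid(metadata$length[i], metadata$family_median_genome[i])
      else NA,
      mob_class = if (length(mobs)) mobs[1L] else "none",
      mob_all = paste(mobs, collapse = ","),
      mpf_type = if (length(mpfs)) mpfs[1L] else "none",
      transmissibility = classify_transmissibility(length(mobs) > 0L,
                                                   length(mpfs) > 0L),
      partition_I = sum(part == "I"),
      partition_II = sum(part == "II"),
      partition_III = sum(part == "III"),
      ta_count = length(hit_of(id, "ta")),
      amr_count = length(hit_of(id, "amr")),
      vf_count = length(vf),
      vf_labels = paste(vf, collapse = ","),
      ptu = if (!is.null(metadata$ptu)) metadata$ptu[i] else NA_character_,
      gc_diff = if (!is.null(metadata$host_chromosome_gc))
        gc_divergence(metadata$gc[i], metadata$host_chromosome_gc[i])
      else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, prof)
  rownames(out) <- NULL
  out
}

#' Assign each plasmid to a T6SS analysis group
#'
#' A plasmid with at least one complete system belongs to `complete_T6SS`
#' even when it also carries islands; plasmids carrying only islands or
#' isolated hcp/vgrG genes are `orphan_only`; the rest are `neither`.
#'
#' @param replicon_ids plasmid ids to assign.
#' @param clusters a [scan_clusters()] result.
#' @param islands result of [find_isolated_genes()] (optional; contributes
#'   isolated genes and homotypic islands to `orphan_only`).
#' @return character vector of group labels, parallel to `replicon_ids`.
#' @export
assign_t6ss_group <- function(replicon_ids, clusters, islands = NULL) {
  complete_ids <- unique(clusters$replicon_id[clusters$classification == "complete"])
  orphan_ids <- unique(clusters$replicon_id[clusters$classification == "orphan_island"])
  if (!is.null(islands))
    orphan_ids <- unique(c(orphan_ids, islands$isolated$replicon_id,
                           islands$homotypic_islands$replicon_id))
  ifelse(replicon_ids %in% complete_ids, "complete_T6SS",
         ifelse(replicon_ids %in% orphan_ids, "orphan_only", "neither"))
}

#' Cohort summary with 2x2 tables for the statistics layer
#'
#' Tabulates transmissibility classes, MOB classes, MPF types, megaplasmid
#' flags and trait medians per analysis group, and assembles the group-level
#' 2x2 contingency tables (transmissible vs not, virulence-factor carriage,
#' megaplasmid status) ready for [fisher_exact()].
#'
#' @param profiles result of [profile_traits()] restricted to plasmids.
#' @param groups group labels from [assign_t6ss_group()], parallel to
#'   `profiles` rows.
#' @return list with `counts` (per-group data frame: n, transmissibility
#'   counts and proportions, megaplasmid count and percentage, trait medians),
#'   `tables` (named list of 2x2 matrices), and `percent` helper values
#'   formatted to one decimal. Proportions of an empty group are `NA`, not 0.
#' @export
cohort_summary <- function(profiles, groups) {
  stopifnot(nrow(profiles) == length(groups))
  lev <- c("complete_T6SS", "orphan_only", "neither")
  rows <- lapply(lev, function(g) {
    p <- profiles[groups == g, , drop = FALSE]
    n <- nrow(p)
    tr <- table(factor(p$transmissibility,
                       levels = c("conjugative", "mobilizable", "non_transmissible")))
    mega_known <- sum(!is.na(p$megaplasmid))
    data.frame(
      group = g, n = n,
      conjugative = as.integer(tr["conjugative"]),
      mobilizable = as.integer(tr["mobilizable"]),
      non_transmissible = as.integer(tr["non_transmissible"]),
      prop_conjugative = if (n) unname(tr["conjugative"]) / n else NA_real_,
      prop_mobilizable = if (n) unname(tr["mobilizable"]) / n else NA_real_,
      prop_non_transmissible = if (n) unname(tr["non_transmissible"]) / n else NA_real_,
      n_megaplasmid = sum(p$megaplasmid, na.rm = TRUE),
      pct_megaplasmid = if (mega_known)
        100 * sum(p$megaplasmid, na.rm = TRUE) / mega_known else NA_real_,
      n_vf = sum(p$vf_count > 0),
      median_ta = if (n) stats::median(p$ta_count) else NA_real_,
      median_amr = if (n) stats::median(p$amr_count) else NA_real_,
      median_length = if (n) stats::median(p$length) else NA_real_,
      stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)

  two_by_two <- function(x1, n1, x2, n2)
    matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE,
           dimnames = list(c("complete_T6SS", "orphan_only"),
                           c("yes", "no")))
  cc <- counts[counts$group == "complete_T6SS", ]
  oo <- counts[counts$group == "orphan_only", ]
  tables <- list(
    virulence = two_by_two(cc$n_vf, cc$n, oo$n_vf, oo$n),
    transmissible = two_by_two(cc$conjugative + cc$mobilizable, cc$n,
                               oo$conjugative + oo$mobilizable, oo$n),
    megaplasmid = two_by_two(cc$n_megaplasmid, cc$n, oo$n_megaplasmid, oo$n))

  list(counts = counts, tables = tables,
       percent = stats::setNames(sprintf("%.1f", counts$pct_megaplasmid),
                                 counts$group))
}
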