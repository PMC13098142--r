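## Mobile-genetic-element neighborhood screening around T6SS loci.

mge_kinds <- c("IS", "integrase", "recombinase", "transposase")

#' Screen a gene window around a locus for MGE signatures
#'
#' Reports all mobile-genetic-element genes (insertion sequences, integrases,
#' recombinases, transposases) whose ordinal lies within `window` genes
#' upstream or downstream of the locus span, excluding the span itself.
#' Windows truncate at replicon ends; on circular replicons they wrap.
#' MGE genes inside the span are reported separately and do not set
#' `has_mge`.
#'
#' @param span two-element integer vector `c(start, end)`, half-open ordinal
#'   span of the locus.
#' @param genes gene table of the same replicon (`ordinal`, `label`,
#'   `category`; MGE rows carry `category` in
#'   `c("IS", "integrase", "recombinase", "transposase")` and the family in
#'   `label`, e.g. `"IS3"`).
#' @param window number of genes on each side (default 20).
#' @param circular wrap the window around the origin.
#' @param n_genes total gene count of the replicon (needed for wrapping;
#'   defaults to `max(ordinal) + 1`).
#' @return list of class `neighborhood_report`: `span`, `window`, `mge_hits`
#'   (data frame `ordinal`, `family`, `kind`), `internal_hits` (same layout,
#'   inside the span), `has_mge` flag.
#' @export
window_scan <- function(span, genes, window = 20L, circular = FALSE,
                        n_genes = NULL) {
  window <- check_count(window, "window", 1L)
  start <- span[[1L]]; end <- span[[2L]]
  mge <- genes[!is.na(genes$category) & genes$category %in% mge_kinds, ,
               drop = FALSE]
  ord <- mge$ordinal
  if (circular) {
    ng <- n_genes %||% (max(genes$ordinal) + 1L)
    in_window <- (ord < start | ord >= end) &
      ((start - ord) %% ng <= window | (ord - end) %% ng < window)
  } else {
    in_window <- (ord >= start - window & ord < start) |
      (ord >= end & ord < end + window)
  }
  inside <- ord >= start & ord < end
  hits <- data.frame(ordinal = ord[in_window & !inside],
                     family = mge$label[in_window & !inside],
                     kind = mge$category[in_window & !inside],
                     stringsAsFactors = FALSE)
  internal <- data.frame(ordinal = ord[inside], family = mge$label[inside],
                         kind = mge$category[inside], stringsAsFactors = FALSE)
  structure(list(span = c(start, end), window = window, mge_hits = hits,
                 internal_hits = internal, has_mge = nrow(hits) > 0L),
            class = "neighborhood_report")
}

#' Scan every detected locus on an annotation table
#'
#' @param clusters a [scan_clusters()] result (optionally subset).
#' @param genes full gene table covering the clusters' replicons.
#' @param window genes on each side (default 20).
#' @return data frame with one row per (locus, MGE hit), columns `locus_id`,
#'   `replicon_id`, `classification`, `family`, `kind`, `ordinal`, plus a
#'   `has_mge` per-locus summary attached as attribute `"locus_summary"`.
#' @export
scan_all_neighborhoods <- function(clusters, genes, window = 20L) {
  reports <- lapply(seq_len(nrow(clusters)), function(i) {
    g <- genes[genes$replicon_id == clusters$replicon_id[i], , drop = FALSE]
    window_scan(c(clusters$start[i], clusters$end[i]), g, window = window)
  })
  rows <- lapply(seq_along(reports), function(i) {
    h <- reports[[i]]$mge_hits
    if (!nrow(h)) return(NULL)
    data.frame(locus_id = i, replicon_id = clusters$replicon_id[i],
               classification = clusters$classification[i],
               h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus_id = integer(), replicon_id = character(),
                      classification = character(), ordinal = integer(),
                      family = character(), kind = character(),
                      stringsAsFactors = FALSE)
  attr(out, "locus_summary") <- data.frame(
    locus_id = seq_along(reports),
    replicon_id = clusters$replicon_id,
    classification = clusters$classification,
    has_mge = vapply(reports, `[[`, logical(1L), "has_mge"),
    stringsAsFactors = FALSE)
  out
}

#' Per-family association between MGE presence and locus class
#'
#' For each IS/MGE family, builds the 2x2 table (family present/absent in the
#' window) x (complete cluster / orphan island) over all loci and applies a
#' two-sided Fisher exact test, Benjamini-Hochberg adjusted across families.
#' Families absent from every window are skipped.
#'
#' @param neighborhoods result of [scan_all_neighborhoods()]; its
#'   `locus_summary` attribute supplies the locus universe.
#' @return data frame: `family`, counts per class, `odds_ratio`, `p`,
#'   `adjusted_p`, sorted by `p`.
#' @export
family_association <- function(neighborhoods) {
  loci <- attr(neighborhoods, "locus_summary")
  loci <- loci[loci$classification %in% c("complete", "orphan_island"), ,
               drop = FALSE]
  if (!nrow(loci)) stop("need at least one complete or orphan locus", call. = FALSE)
  fams <- sort(unique(neighborhoods$family))
  n_complete <- sum(loci$classification == "complete")
  n_orphan <- sum(loci$classification == "orphan_island")
  rows <- lapply(fams, function(f) {
    with_fam <- unique(neighborhoods$locus_id[neighborhoods$family == f])
    a <- sum(loci$locus_id %in% with_fam & loci$classification == "orphan_island")
    c_ <- sum(loci$locus_id %in% with_fam & loci$classification == "complete")
    ft <- fisher_exact(matrix(c(a, n_orphan - a, c_, n_complete - c_),
                              nrow = 2, byrow = TRUE), side = "two_sided")
    data.frame(family = f, orphan_with = a, orphan_without = n_orphan - a,
               complete_with = c_, complete_without = n_complete - c_,
               odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(family = character(), orphan_with = integer(),
                      orphan_without = integer(), complete_with = integer(),
                      complete_without = integer(), odds_ratio = numeric(),
                      p = numeric(), adjusted_p = numeric(),
                      stringsAsFactors = FALSE))
  out$adjusted_p <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
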