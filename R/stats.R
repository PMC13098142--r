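## Statistical layer: exact 2x2 tests, BH correction, rank tests, and
## presence/absence association and enrichment wrappers. The underlying
## machinery is base R (fisher.test, p.adjust, wilcox.test); the functions
## here enforce the conventions used throughout the pipeline (sample odds
## ratios, result layout, constant-gene handling).

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop("contingency table must be 2x2", call. = FALSE)
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m)))
    stop("contingency table must hold nonnegative integer counts", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test. The two-sided p-value sums the probabilities of
#' all tables with the same margins whose point probability does not exceed
#' that of the observed table. The reported odds ratio is the sample odds
#' ratio `a*d / (b*c)` (with `Inf` on a zero denominator), not the
#' conditional MLE.
#'
#' @param table 2x2 matrix of counts (rows = group, columns = outcome), or a
#'   length-4 vector `c(a, b, c, d)` read row-wise.
#' @param side one of `"two_sided"`, `"greater"`, `"less"`.
#' @return list of class `test_result` with `p`, `odds_ratio`, `side`.
#' @examples
#' fisher_exact(c(145, 230, 7, 265))$p   # ~1.28e-29
#' @export
fisher_exact <- function(table, side = c("two_sided", "greater", "less")) {
  side <- match.arg(side)
  if (is.vector(table) && length(table) == 4L)
    table <- matrix(table, nrow = 2, byrow = TRUE)
  m <- as_2x2(table)
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[side]]
  p <- stats::fisher.test(m, alternative = alt)$p.value
  or <- if (m[1, 2] * m[2, 1] == 0) {
    if (m[1, 1] * m[2, 2] == 0) NaN else Inf
  } else (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  structure(list(p = unname(p), odds_ratio = or, adjusted_p = NULL,
                 side = side), class = "test_result")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement;
#' the output preserves input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test
#'
#' Exact p-value by rank-permutation when `length(x) * length(y) <= 400` and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param side `"two_sided"`, `"greater"` (x tends larger), or `"less"`.
#' @return list of class `test_result` with `p`, `U` (statistic for `x`),
#'   `exact` flag, `side`.
#' @export
mann_whitney_u <- function(x, y, side = c("two_sided", "greater", "less")) {
  side <- match.arg(side)
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[side]]
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 400) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt,
                                            exact = exact, correct = TRUE))
  structure(list(p = unname(wt$p.value), U = unname(wt$statistic),
                 exact = exact, side = side), class = "test_result")
}

#' Per-gene presence/absence association with a binary grouping
#'
#' Naive gene-wise association ("naive GWAS"): for every gene a two-sided
#' Fisher exact test of the 2x2 table (gene present/absent) x (group +/-),
#' Benjamini-Hochberg adjusted across genes. No population-structure
#' correction is applied. Genes present or absent in every replicon are
#' assigned p = 1 and flagged `constant`.
#'
#' @param presence binary matrix, genes in rows, replicons in columns.
#' @param group logical (or 0/1) vector over columns: `TRUE` for the
#'   T6SS-positive set.
#' @param alpha FDR threshold defining the `significant` flag (default 0.05).
#' @return data frame: `gene`, `present_pos`, `present_neg`, `odds_ratio`,
#'   `p`, `adjusted_p`, `constant`, `significant`.
#' @export
gene_presence_association <- function(presence, group, alpha = 0.05) {
  presence <- as.matrix(presence)
  group <- as.logical(group)
  if (length(group) != ncol(presence))
    stop("group labels must match the number of replicon columns", call. = FALSE)
  if (!any(group) || all(group))
    stop("both groups must be non-empty", call. = FALSE)
  if (!all(presence %in% c(0, 1)))
    stop("presence matrix must be binary", call. = FALSE)
  n_pos <- sum(group); n_neg <- sum(!group)
  res <- lapply(seq_len(nrow(presence)), function(i) {
    a <- sum(presence[i, group]); b <- sum(presence[i, !group])
    constant <- (a + b == 0) || (a + b == n_pos + n_neg)
    ft <- if (constant) list(p = 1, odds_ratio = NaN)
    else fisher_exact(matrix(c(a, n_pos - a, b, n_neg - b), 2, byrow = TRUE))
    data.frame(gene = rownames(presence)[i] %||% as.character(i),
               present_pos = a, present_neg = b,
               odds_ratio = ft$odds_ratio, p = ft$p, constant = constant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- bh_adjust(out$p)
  out$significant <- out$adjusted_p < alpha & !out$constant
  out
}

#' COG-category enrichment between two plasmid sets
#'
#' Each category is tested against all other categories pooled
#' (2x2 Fisher exact, two-sided), BH-adjusted across categories; a category
#' is enriched in the positive set when adjusted p < `alpha` and the odds
#' ratio exceeds 1.
#'
#' @param counts_pos,counts_neg named integer vectors of annotation counts
#'   per COG category in the positive and negative sets.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data frame: `category`, counts, `odds_ratio`, `p`, `adjusted_p`,
#'   `enriched`.
#' @export
cog_enrichment <- function(counts_pos, counts_neg, alpha = 0.05) {
  cats <- union(names(counts_pos), names(counts_neg))
  pos <- stats::setNames(rep(0L, length(cats)), cats)
  neg <- pos
  pos[names(counts_pos)] <- counts_pos
  neg[names(counts_neg)] <- counts_neg
  tot_pos <- sum(pos); tot_neg <- sum(neg)
  rows <- lapply(cats, function(k) {
    ft <- fisher_exact(matrix(c(pos[[k]], tot_pos - pos[[k]],
                                neg[[k]], tot_neg - neg[[k]]), 2, byrow = TRUE))
    data.frame(category = k, count_pos = pos[[k]], count_neg = neg[[k]],
               odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p)
  out$enriched <- out$adjusted_p < alpha & out$odds_ratio > 1
  out[order(out$p), , drop = FALSE]
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("p = %.4g (%s)%s\n", x$p, x$side,
              if (!is.null(x$odds_ratio) && length(x$odds_ratio))
                sprintf(", OR = %.4g", x$odds_ratio) else ""))
  invisible(x)
}
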