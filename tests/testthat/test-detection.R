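test_that("hits separated by exactly the intervening-gene maximum are grouped", {
  g <- data.frame(replicon_id = "r1", ordinal = c(5L, 26L),
                  label = c("tssB", "tssC"), stringsAsFactors = FALSE)
  cl <- scan_clusters(g)
  expect_equal(nrow(cl), 1L)
  expect_equal(c(cl$start, cl$end), c(5L, 27L))

  g$ordinal <- c(5L, 27L)   # 21 intervening genes: split, both demoted
  cl2 <- scan_clusters(g)
  expect_equal(nrow(cl2), 0L)
  expect_equal(nrow(attr(cl2, "demoted")), 2L)
})

test_that("a single T6SS hit never forms a cluster", {
  g <- data.frame(replicon_id = "r1", ordinal = 10L, label = "tssB")
  cl <- scan_clusters(g)
  expect_equal(nrow(cl), 0L)
  expect_equal(attr(cl, "demoted")$ordinal, 10L)
})

test_that("classification follows the distinct-component rules", {
  mk <- function(comps) data.frame(replicon_id = "r", ordinal = seq_along(comps),
                                   label = comps, component = comps,
                                   stringsAsFactors = FALSE)
  eight <- c("tssB", "tssC", "tssD", "tssE", "tssF", "tssG", "tssK", "tssM")
  expect_equal(classify_cluster(mk(eight))$classification, "complete")
  # 8 hits, only 7 distinct (one duplicated) -> incomplete
  seven_dup <- c(eight[1:7], "tssB")
  res <- classify_cluster(mk(seven_dup))
  expect_equal(res$classification, "incomplete")
  expect_equal(res$n_distinct, length(unique(seven_dup)))
  # orphan island combinations, with synonyms normalized upstream
  expect_equal(classify_cluster(mk(c("tssD", "tssI")))$island_type, "hcp-vgrG")
  expect_equal(classify_cluster(mk(c("tssD", "evpJ")))$island_type, "hcp-PAAR")
  expect_equal(classify_cluster(mk(c("tssI", "evpJ")))$island_type, "vgrG-PAAR")
  expect_equal(classify_cluster(mk(c("tssD", "tssI", "evpJ")))$island_type,
               "hcp-vgrG-PAAR")
  # any extra component voids the island combination
  expect_equal(classify_cluster(mk(c("tssD", "tssI", "tssB")))$classification,
               "incomplete")
})

test_that("scan_clusters matches the brute-force gap-merge oracle", {
  set.seed(42)
  th <- detection_thresholds()
  for (i in 1:100) {
    n <- sample(50:500, 1)
    g <- random_gene_table(n, sample(2:10, 1))
    cl <- scan_clusters(g, th)
    hits <- g[!is.na(normalize_component(g$label)), ]
    oracle <- oracle_gap_merge(hits$ordinal, normalize_component(hits$label),
                               th$max_intervening_genes, th$min_distinct_genes)
    expect_equal(nrow(cl), length(oracle))
    if (length(oracle)) {
      expect_equal(cl$start, vapply(oracle, `[[`, numeric(1), "start"))
      expect_equal(cl$end, vapply(oracle, `[[`, numeric(1), "end"))
      expect_equal(cl$n_distinct, vapply(oracle, `[[`, integer(1), "n_distinct"),
                   ignore_attr = TRUE)
    }
  }
})

test_that("raising the gap threshold never shrinks clusters or drops hits", {
  set.seed(7)
  for (i in 1:25) {
    g <- random_gene_table(300, 12)
    a <- scan_clusters(g, detection_thresholds(max_intervening_genes = 10))
    b <- scan_clusters(g, detection_thresholds(max_intervening_genes = 25))
    n_a <- sum(a$n_hits); n_b <- sum(b$n_hits)
    expect_gte(n_b, n_a)
    # every cluster under the small gap is contained in one under the large gap
    for (j in seq_len(nrow(a)))
      expect_true(any(b$start <= a$start[j] & b$end >= a$end[j]))
  }
})

test_that("every T6SS hit is either a cluster member or an isolated candidate", {
  set.seed(11)
  for (i in 1:20) {
    g <- random_gene_table(200, 8)
    cl <- scan_clusters(g)
    n_hits_total <- sum(!is.na(normalize_component(g$label)))
    expect_equal(sum(cl$n_hits) + nrow(attr(cl, "demoted")), n_hits_total)
  }
})

test_that("duplicate ordinals are rejected and odd T6SS rows warned about", {
  g <- data.frame(replicon_id = "r1", ordinal = c(1L, 1L), label = c("a", "b"))
  expect_error(scan_clusters(g), "duplicate ordinal")
  g2 <- data.frame(replicon_id = "r1", ordinal = 1:2,
                   label = c("mystery", "tssB"), category = c("T6SS", "T6SS"))
  expect_warning(scan_clusters(g2), "unrecognized")
})

test_that("isolated hcp/vgrG genes are reported outside cluster spans only", {
  # one complete cluster containing a tssI, plus a lone distant tssI
  comps <- c("tssB", "tssC", "tssD", "tssE", "tssF", "tssG", "tssK", "tssI")
  g <- data.frame(replicon_id = "r1",
                  ordinal = c(seq(10, by = 1, length.out = 8), 90L),
                  label = c(comps, "vgrG"), stringsAsFactors = FALSE)
  cl <- scan_clusters(g)
  expect_equal(cl$classification, "complete")
  iso <- find_isolated_genes(g, cl)
  expect_equal(nrow(iso$isolated), 1L)
  expect_equal(iso$isolated$ordinal, 90L)
  expect_equal(iso$isolated$component, "tssI")
  expect_equal(iso$inventory$n_islands[iso$inventory$island_type == "vgrG"], 1L)
})

test_that("same-component isolated pairs become homotypic islands", {
  g <- data.frame(replicon_id = "r1", ordinal = c(10L, 20L, 80L),
                  label = c("hcp", "hcp", "hcp"), stringsAsFactors = FALSE)
  cl <- scan_clusters(g)   # all demoted: one distinct component per group
  expect_equal(nrow(cl), 0L)
  iso <- find_isolated_genes(g, cl)
  expect_equal(nrow(iso$homotypic_islands), 1L)
  expect_equal(iso$homotypic_islands$island_type, "hcp-hcp")
  inv <- iso$inventory
  expect_equal(inv$n_islands[inv$island_type == "hcp-hcp"], 1L)
  expect_equal(inv$n_islands[inv$island_type == "hcp"], 1L)  # the lone third copy
})

test_that("subtype assignment follows marker priority", {
  cl <- data.frame(labels = "tssB,tssii_marker,tssC", stringsAsFactors = FALSE)
  markers <- data.frame(marker = c("tssi_marker", "tssii_marker"),
                        subtype = c("i", "ii"), stringsAsFactors = FALSE)
  expect_equal(assign_subtype(cl, markers), "ii")
  expect_equal(assign_subtype(data.frame(labels = "tssB,tssC"), markers),
               "unassigned")
  both <- data.frame(labels = "tssi_marker,tssii_marker")
  expect_warning(res <- assign_subtype(both, markers), "multiple subtypes")
  expect_equal(res, "i")   # first by priority
  expect_message(assign_subtype(cl, markers[0, ]), "empty marker table")
})

test_that("component histograms count distinct components per cluster", {
  mk <- function(comps, off) data.frame(replicon_id = "r", label = comps,
                                        ordinal = off + seq_along(comps))
  g <- rbind(mk(c("tssB", "tssC"), 0), mk(c("tssD", "tssI"), 100),
             mk(c("tssA", "tssB", "tssC", "tssD", "tssE", "tssF", "tssG", "tssK"), 200))
  cl <- scan_clusters(g)
  s <- summarize_component_distribution(cl)
  expect_equal(unname(s$histogram[c("2", "8")]), c(2L, 1L))
  expect_equal(sum(s$histogram), 3L)
  big <- which(cl$n_distinct == 8L)
  expect_true(s$subcomplex_presence$baseplate[big])
  expect_true(s$subcomplex_presence$sheath[big])
  expect_false(s$subcomplex_presence$ATPase[big])
  empty <- summarize_component_distribution(scan_clusters(
    data.frame(replicon_id = "r", ordinal = 1L, label = "bg")))
  expect_equal(sum(empty$histogram), 0L)
})

test_that("circular replicons merge clusters across the origin", {
  # hits at ordinals 2 and 95 on a 100-gene circle: wrap gap = 4 + 2 = 6
  g <- data.frame(replicon_id = "r1", ordinal = c(2L, 95L),
                  label = c("tssB", "tssC"), stringsAsFactors = FALSE)
  lin <- scan_clusters(g)
  expect_equal(nrow(lin), 0L)   # 92 intervening genes on the line
  circ <- scan_clusters(g, circular = TRUE, n_genes = c(r1 = 100L))
  expect_equal(nrow(circ), 1L)
  expect_equal(circ$n_distinct, 2L)
})
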