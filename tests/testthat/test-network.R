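mk_meta <- function(ids, kind = "plasmid", ptu = NA_character_) {
  n <- length(ids)
  data.frame(replicon_id = ids, kind = rep_len(kind, n), ptu = rep_len(ptu, n),
             species = rep_len("s1", n), genus = rep_len("g1", n),
             family = rep_len("f1", n), order_ = rep_len("o1", n),
             class_ = rep_len("c1", n), stringsAsFactors = FALSE)
}

test_that("bipartite construction dedupes proteins and validates metadata", {
  hpc <- data.frame(protein_id = c("p1", "p2", "p3"),
                    replicon_id = c("r1", "r1", "r2"),
                    hpc_id = c("H1", "H1", "H1"), stringsAsFactors = FALSE)
  g <- build_bipartite(hpc, mk_meta(c("r1", "r2")))
  expect_true(igraph::is_bipartite(g))
  expect_equal(igraph::ecount(g), 2L)   # multiplicity collapsed
  # two replicons sharing one HPC: path of length 2
  expect_equal(igraph::distances(g, "r1", "r2")[1L], 2)
  expect_equal(igraph::degree(g, "H1"), c(H1 = 2))
  expect_error(build_bipartite(hpc, mk_meta("r1")), "r2")
  empty <- build_bipartite(hpc[0, ], mk_meta(character(0)))
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("HPC node degree equals the number of distinct carrying replicons", {
  set.seed(6)
  for (i in 1:10) {
    ids <- paste0("r", 1:8)
    tab <- data.frame(
      replicon_id = sample(ids, 60, replace = TRUE),
      hpc_id = sample(paste0("H", 1:12), 60, replace = TRUE),
      stringsAsFactors = FALSE)
    g <- build_bipartite(tab, mk_meta(ids))
    for (h in unique(tab$hpc_id)) {
      expect_equal(unname(igraph::degree(g, h)),
                   length(unique(tab$replicon_id[tab$hpc_id == h])))
    }
  }
})

test_that("two disconnected cliques give two communities plus singletons", {
  spec <- list(A = list(replicons = paste0("a", 1:5), shared = 8L),
               B = list(replicons = paste0("b", 1:5), shared = 8L))
  tab <- simulate_hpc_table(spec, noise = 0, seed = 1L)
  meta <- mk_meta(c(paste0("a", 1:5), paste0("b", 1:5), "lone"))
  g <- build_bipartite(tab, meta)
  comm <- detect_communities(g, seed = 7L)
  multi <- comm[comm$n_members > 1L, ]
  expect_equal(nrow(multi), 2L)
  memb <- attr(comm, "membership")
  expect_equal(length(unique(memb[paste0("a", 1:5)])), 1L)
  expect_equal(length(unique(memb[paste0("b", 1:5)])), 1L)
  # isolated replicon comes out as its own singleton community
  expect_equal(comm$n_members[grepl("lone", comm$members)], 1L)
  # every replicon is in exactly one community
  expect_setequal(names(memb), meta$replicon_id)
})

test_that("community detection is deterministic under a fixed seed", {
  spec <- list(A = list(replicons = paste0("a", 1:6), shared = 5L),
               B = list(replicons = paste0("b", 1:6), shared = 5L))
  tab <- simulate_hpc_table(spec, noise = 1, seed = 3L)
  meta <- mk_meta(c(paste0("a", 1:6), paste0("b", 1:6)))
  g <- build_bipartite(tab, meta)
  expect_identical(detect_communities(g, seed = 11L),
                   detect_communities(g, seed = 11L))
})

test_that("host range grades follow the taxonomic-rank ladder", {
  base <- data.frame(species = "s", genus = "g", family = "f",
                     order_ = "o", class_ = "c", stringsAsFactors = FALSE)
  two <- rbind(base, base)
  expect_equal(host_range_grade(two), "I")
  two2 <- two; two2$species[2] <- "s2"
  expect_equal(host_range_grade(two2), "II")
  two3 <- two2; two3$genus[2] <- "g2"
  expect_equal(host_range_grade(two3), "III")
  two4 <- two3; two4$family[2] <- "f2"
  expect_equal(host_range_grade(two4), "IV")
  two5 <- two4; two5$order_[2] <- "o2"
  expect_equal(host_range_grade(two5), "V")
  two6 <- two5; two6$class_[2] <- "c2"
  expect_warning(expect_equal(host_range_grade(two6), "beyond_V"), "class rank")
  expect_error(host_range_grade(base), "at least two")
})

test_that("host range grade matches the rank-walk oracle and is monotone", {
  set.seed(12)
  for (i in 1:50) {
    tax <- random_taxonomy(sample(2:6, 1))
    suppressWarnings({
      expect_equal(host_range_grade(tax), oracle_host_range(tax))
      # order-invariant
      expect_equal(host_range_grade(tax[sample(nrow(tax)), , drop = FALSE]),
                   host_range_grade(tax))
      # adding a member never lowers the grade
      grades <- c("I", "II", "III", "IV", "V", "beyond_V")
      g1 <- match(host_range_grade(tax), grades)
      g2 <- match(host_range_grade(rbind(tax, random_taxonomy(1))), grades)
      expect_gte(g2, g1)
    })
  }
})

test_that("core proteome applies the 80% threshold inclusively", {
  members <- paste0("r", 1:10)
  tab <- rbind(
    data.frame(replicon_id = members[1:8], hpc_id = "H_core8"),
    data.frame(replicon_id = members[1:7], hpc_id = "H_seven"),
    data.frame(replicon_id = members, hpc_id = "H_all"))
  core <- core_proteome(tab, members)
  expect_setequal(core, c("H_core8", "H_all"))   # 8/10 in, 7/10 out
  expect_error(core_proteome(tab, "r1"), "at least 2")
})

test_that("ANI edges require half coverage of the shorter replicon", {
  tab <- data.frame(replicon_a = c("x", "x", "y"),
                    replicon_b = c("y", "z", "y"),
                    ani = c(0.98, 0.99, 1), coverage = c(0.5, 0.49, 1),
                    stringsAsFactors = FALSE)
  g <- ani_network(tab)
  expect_equal(igraph::ecount(g), 1L)            # 0.49 excluded, self-pair ignored
  e <- igraph::E(g)[1]
  expect_equal(igraph::E(g)$weight, 0.98)
  expect_error(ani_network(transform(tab, ani = c(1.2, 0.9, 1))), "0, 1")
})

test_that("cross-tab links entities sharing a community and flags shared IS", {
  comm <- data.frame(community = 1:2,
                     n_members = c(2L, 1L),
                     members = c("p1,c1", "p2"),
                     compartment_mix = c("mixed", "plasmid_only"),
                     ptus = c("PTU-A", ""),
                     host_range_grade = c("I", NA), stringsAsFactors = FALSE)
  meta <- data.frame(replicon_id = c("p1", "p2", "c1"),
                     kind = c("plasmid", "plasmid", "chromosome"),
                     ptu = c("PTU-A", NA, NA), stringsAsFactors = FALSE)
  nb <- data.frame(locus_id = 1:2, replicon_id = c("p1", "c1"),
                   classification = "complete", ordinal = 1L,
                   family = "IS200/IS605", kind = "IS", stringsAsFactors = FALSE)
  ct <- community_cross_tab(comm, meta, nb)
  expect_equal(ct$pairs$entity_a, "Chr")
  expect_equal(ct$pairs$entity_b, "PTU-A")
  expect_equal(ct$pairs$n_communities, 1L)
  expect_true(ct$community_flags$shared_is_family[1L])
  expect_false(ct$community_flags$shared_is_family[2L])
})
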