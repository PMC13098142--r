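mk_tip_meta <- function(tips, compartment, host = NULL, ic = NULL) {
  data.frame(tip = tips, compartment = compartment,
             host_id = host %||% paste0("h", seq_along(tips)),
             identity_cluster = if (is.null(ic)) NA_character_ else ic,
             stringsAsFactors = FALSE)
}

test_that("patristic distances sum branch lengths along tip paths", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2);")
  D <- patristic_matrix(tr)
  expect_equal(D["A", "B"], 0.3)
  expect_equal(diag(D), c(A = 0, B = 0))
  expect_error(patristic_matrix(ape::rtree(4, br = NULL)), "branch lengths")
})

test_that("patristic matrix equals the cophenetic oracle on random trees", {
  set.seed(31)
  for (i in 1:25) {
    tr <- ape::rtree(sample(3:40, 1))
    D <- patristic_matrix(tr)
    ref <- ape::cophenetic.phylo(tr)
    expect_equal(D[rownames(ref), colnames(ref)], ref, tolerance = 1e-12)
    expect_equal(D, t(D))
  }
})

test_that("closest homolog minima equal exhaustive search", {
  set.seed(17)
  tr <- ape::rtree(20)
  D <- patristic_matrix(tr)
  meta <- mk_tip_meta(tr$tip.label,
                      sample(c("plasmid", "chromosome"), 20, replace = TRUE,
                             prob = c(0.6, 0.4)))
  ch <- closest_homolog(D, meta)
  for (i in seq_len(nrow(ch$distances))) {
    tip <- ch$distances$tip[i]
    for (cmp in c("plasmid", "chromosome")) {
      others <- setdiff(meta$tip[meta$compartment == cmp], tip)
      want <- if (length(others)) min(D[tip, others]) else NA_real_
      got <- ch$distances[[paste0("to_", cmp)]][i]
      expect_equal(got, want)
    }
  }
})

test_that("identity-cluster companions force a distance of zero", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  D <- patristic_matrix(tr)
  meta <- mk_tip_meta(c("A", "B", "C", "D"),
                      c("plasmid", "chromosome", "chromosome", "plasmid"),
                      ic = c("IC1", NA, "IC1", NA))
  ch <- closest_homolog(D, meta)
  a <- ch$distances[ch$distances$tip == "A", ]
  expect_equal(a$to_chromosome, 0)        # shares IC1 with chromosome tip C
  expect_true(a$zero_chromosome)
  d <- ch$distances[ch$distances$tip == "D", ]
  expect_gt(d$to_chromosome, 0)
})

test_that("homolog ECDFs are right-continuous and reach one at the maximum", {
  set.seed(23)
  tr <- ape::rtree(15)
  D <- patristic_matrix(tr)
  meta <- mk_tip_meta(tr$tip.label,
                      rep(c("plasmid", "chromosome"), length.out = 15))
  ch <- closest_homolog(D, meta)
  f <- ch$ecdf$plasmid
  xs <- ch$distances$to_plasmid
  expect_equal(f(max(xs)), 1)
  grid <- sort(unique(xs))
  expect_true(all(diff(f(grid)) >= 0))
  expect_true(all(f(grid) >= 0 & f(grid) <= 1))
  # single tip of a compartment: curve undefined and flagged
  meta1 <- mk_tip_meta(tr$tip.label, c("plasmid", rep("chromosome", 14)))
  expect_warning(ch1 <- closest_homolog(D, meta1), "plasmid")
  expect_null(ch1$ecdf$plasmid)
})

test_that("co-resident distances are bounded below by the global minimum", {
  set.seed(29)
  tr <- ape::rtree(16)
  D <- patristic_matrix(tr)
  hosts <- rep(paste0("h", 1:8), each = 2)
  meta <- mk_tip_meta(tr$tip.label,
                      rep(c("chromosome", "plasmid"), 8), host = hosts)
  cc <- coresident_comparison(D, meta)
  expect_true(all(cc$pairs$global <= cc$pairs$coresident + 1e-12))
  expect_s3_class(cc$test, "test_result")
  # a host whose co-resident homolog is the global closest: equality
  onehost <- mk_tip_meta(tr$tip.label, rep(c("chromosome", "plasmid"), 8),
                         host = rep("h1", 16))
  cc1 <- coresident_comparison(D, onehost)
  expect_equal(cc1$pairs$coresident, cc1$pairs$global)
  none <- mk_tip_meta(tr$tip.label, rep("plasmid", 16))
  expect_equal(nrow(coresident_comparison(D, none)$pairs), 0L)
})

test_that("single-state tips give a single-state reconstruction", {
  tr <- ape::rtree(6)
  states <- stats::setNames(rep("plasmid", 6), tr$tip.label)
  rec <- ancestral_states(tr, states)
  expect_true(all(vapply(rec$mppa, identical, logical(1), "plasmid")))
  expect_equal(count_transitions(rec)$counts,
               c(plasmid_to_chromosome = 0L, chromosome_to_plasmid = 0L))
})

test_that("pruning posteriors equal exhaustive enumeration on small trees", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    tr <- ape::rtree(n)
    states <- stats::setNames(sample(c("plasmid", "chromosome"), n,
                                     replace = TRUE), tr$tip.label)
    if (length(unique(states)) == 1L) states[1] <- "chromosome"
    pi <- c(0.5, 0.5)
    rec <- ancestral_states(tr, states, pi = pi)
    oracle <- oracle_marginals(tr, states, pi)
    expect_equal(rec$posterior, oracle, tolerance = 1e-10)
    expect_equal(rowSums(rec$posterior), rep(1, nrow(rec$posterior)),
                 ignore_attr = TRUE)
  }
})

test_that("tip-frequency equilibrium matches the observed proportions", {
  tr <- ape::rtree(10)
  states <- stats::setNames(rep(c("plasmid", "chromosome"), c(7, 3)),
                            tr$tip.label)
  rec <- ancestral_states(tr, states)
  expect_equal(rec$pi, c(0.7, 0.3))
})

test_that("shorter terminal branches pull the parent toward the tip state", {
  base <- ape::read.tree(text = "((A:0.5,B:1):1,C:1);")
  states <- c(A = "plasmid", B = "chromosome", C = "chromosome")
  post_at <- function(len) {
    tr <- base
    tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")] <- len
    n <- length(tr$tip.label)
    rec <- ancestral_states(tr, states, pi = c(0.5, 0.5))
    rec$posterior[n + 2L, "plasmid"]   # parent of A and B
  }
  expect_gt(post_at(1e-9), post_at(0.5))
  expect_gt(post_at(0.5), post_at(5))
})

test_that("conflicting tips on an all-zero tree are rejected", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  expect_error(ancestral_states(tr, c(A = "plasmid", B = "chromosome")),
               "unidentifiable")
})

test_that("transition counting uses disjoint MPPA sets with direction", {
  # chain: root and inner node chromosome, one tip plasmid on a long branch
  tr <- ape::read.tree(text = "((A:0.05,B:0.05):0.05,(C:2,D:0.05):0.05);")
  states <- c(A = "chromosome", B = "chromosome", C = "plasmid",
              D = "chromosome")
  rec <- ancestral_states(tr, states, pi = c(0.5, 0.5))
  tc <- count_transitions(rec)
  expect_equal(unname(tc$counts["chromosome_to_plasmid"]), 1L)
  expect_equal(unname(tc$counts["plasmid_to_chromosome"]), 0L)
  expect_equal(tc$events$child, which(tr$tip.label == "C"))
})

test_that("zero-switch simulations reconstruct zero transitions", {
  for (s in 1:5) {
    ct <- simulate_compartment_tree(20, switch_rate = 0, seed = s,
                                    root_state = "chromosome")
    rec <- ancestral_states(ct$tree, ct$tip_states)
    expect_equal(sum(count_transitions(rec)$counts), 0L)
  }
})

test_that("patristic distances satisfy the four-point condition", {
  set.seed(53)
  tr <- ape::rtree(12)
  D <- patristic_matrix(tr)
  tips <- rownames(D)
  for (i in 1:30) {
    q <- sample(tips, 4)
    s1 <- D[q[1], q[2]] + D[q[3], q[4]]
    s2 <- D[q[1], q[3]] + D[q[2], q[4]]
    s3 <- D[q[1], q[4]] + D[q[2], q[3]]
    sums <- sort(c(s1, s2, s3))
    expect_lt(sums[3] - sums[2], 1e-9)   # two largest sums coincide
  }
})
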