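## Independent brute-force oracles used to validate the implementation.
## These deliberately take different routes than the package code.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Gap-merge oracle: start from singleton groups of sorted T6SS hits and
## repeatedly merge neighbouring groups while the count of genes strictly
## between the boundary hits is within the threshold; then filter by the
## distinct-component count. Returns spans (half-open) of surviving groups.
oracle_gap_merge <- function(ordinals, components, max_gap, min_distinct) {
  o <- order(ordinals)
  ordinals <- ordinals[o]; components <- components[o]
  groups <- lapply(seq_along(ordinals), function(i) i)
  repeat {
    merged <- FALSE
    if (length(groups) > 1L) {
      for (i in seq_len(length(groups) - 1L)) {
        left <- groups[[i]]; right <- groups[[i + 1L]]
        gap <- ordinals[right[1L]] - ordinals[left[length(left)]] - 1L
        if (gap <= max_gap) {
          groups[[i]] <- c(left, right)
          groups[[i + 1L]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  keep <- Filter(function(g) length(unique(components[g])) >= min_distinct, groups)
  lapply(keep, function(g)
    list(start = ordinals[g[1L]], end = ordinals[g[length(g)]] + 1L,
         n_distinct = length(unique(components[g]))))
}

## Random gene table with T6SS hits scattered over a linear replicon.
random_gene_table <- function(n_genes, n_hits, id = "r1") {
  vocab <- t6sscope::t6ss_vocabulary()
  ords <- sort(sample.int(n_genes, n_hits) - 1L)
  labels <- rep("bg", n_genes)
  labels[ords + 1L] <- sample(vocab$components, n_hits, replace = TRUE)
  data.frame(replicon_id = id, ordinal = seq_len(n_genes) - 1L,
             label = labels, stringsAsFactors = FALSE)
}

## Exact two-sided Fisher p by full enumeration of the margin-constrained
## table family, point masses via log-factorials.
oracle_fisher_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lchoose_mass <- function(k)
    lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  ks <- max(0L, c1 - r2):min(r1, c1)
  masses <- exp(lchoose_mass(ks))
  obs <- exp(lchoose_mass(a))
  sum(masses[masses <= obs * (1 + rel_tol)])
}

## Step-up BH by the direct min-over-j formula.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1L))
  out <- numeric(m); out[o] <- adj
  out
}

## Exact Mann-Whitney null distribution by enumeration of all assignments of
## pooled ranks to the x-sample; returns one- and two-sided p for observed U.
oracle_mw <- function(x, y, side) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  u_all <- apply(idx, 2L, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  switch(side,
         greater = mean(u_all >= u_obs),
         less = mean(u_all <= u_obs),
         two_sided = min(1, 2 * min(mean(u_all >= u_obs), mean(u_all <= u_obs))))
}

## Marginal ancestral posteriors by exhaustive summation over every
## assignment of states to internal nodes.
oracle_marginals <- function(tree, tip_states, pi) {
  states <- c("plasmid", "chromosome")
  n <- length(tree$tip.label)
  m <- n + tree$Nnode
  nu <- 1 - sum(pi^2)
  pmat <- function(t) {
    e <- exp(-t / nu)
    rbind(pi + c(1 - pi[1], -pi[2]) * e,
          pi + c(-pi[1], 1 - pi[2]) * e)
  }
  tipidx <- match(tip_states[tree$tip.label], states)
  internal <- (n + 1L):m
  grid <- as.matrix(expand.grid(rep(list(1:2), length(internal))))
  pmats <- lapply(tree$edge.length, pmat)
  lik_tot <- 0
  marg <- matrix(0, m, 2L)
  for (g in seq_len(nrow(grid))) {
    assign_all <- integer(m)
    assign_all[seq_len(n)] <- tipidx
    assign_all[internal] <- grid[g, ]
    lik <- pi[assign_all[n + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      lik <- lik * pmats[[e]][assign_all[tree$edge[e, 1L]],
                              assign_all[tree$edge[e, 2L]]]
    }
    lik_tot <- lik_tot + lik
    marg[cbind(seq_len(m), assign_all)] <- marg[cbind(seq_len(m), assign_all)] + lik
  }
  marg <- marg / lik_tot
  colnames(marg) <- states
  marg
}

## Host-range grade by walking ranks from the deepest upward and reporting
## the first full agreement.
oracle_host_range <- function(tax) {
  ranks <- c("species", "genus", "family", "order_", "class_")
  grades <- c("I", "II", "III", "IV", "V")
  for (i in seq_along(ranks))
    if (all(tax[[ranks[i]]] == tax[[ranks[i]]][1L])) return(grades[i])
  "beyond_V"
}

## Adjusted Rand index between two labelings.
ari <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  igraph::compare(a, b, method = "adjusted.rand")
}

random_taxonomy <- function(n, n_levels = 2L) {
  pick <- function(prefix) sample(paste0(prefix, seq_len(n_levels)), n, replace = TRUE)
  data.frame(class_ = pick("c"), order_ = pick("o"), family = pick("f"),
             genus = pick("g"), species = pick("s"), stringsAsFactors = FALSE)
}
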