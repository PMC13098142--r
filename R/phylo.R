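## Patristic distances, closest-homolog ECDFs, co-resident comparisons, and
## two-state ancestral reconstruction of genomic compartment (plasmid vs
## chromosome) under the F81 model with marginal posteriors and MPPA state
## selection.

compartment_states <- c("plasmid", "chromosome")

#' Patristic distance matrix of a tree
#'
#' Sums branch lengths along the tip-to-tip path for every pair of tips.
#' Computed by a post-order sweep that merges child-subtree tip depth lists
#' at each internal node, so each pair is combined exactly once at its most
#' recent common ancestor.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @return symmetric numeric matrix with tip labels as dimnames and zero
#'   diagonal.
#' @export
patristic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  n <- length(tree$tip.label)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  ## depth list per node: tip index -> distance from this node
  sweep_node <- function(node) {
    if (node <= n)
      return(list(tips = node, depth = 0))
    parts <- lapply(kids[[as.character(node)]], function(e) {
      sub <- sweep_node(tree$edge[e, 2L])
      sub$depth <- sub$depth + tree$edge.length[e]
      sub
    })
    for (i in seq_along(parts))
      for (j in seq_len(i - 1L)) {
        a <- parts[[i]]; b <- parts[[j]]
        pair <- outer(a$depth, b$depth, `+`)
        D[a$tips, b$tips] <<- pair
        D[b$tips, a$tips] <<- t(pair)
      }
    list(tips = unlist(lapply(parts, `[[`, "tips")),
         depth = unlist(lapply(parts, `[[`, "depth")))
  }
  root <- n + 1L
  sweep_node(root)
  D
}

#' Closest plasmid and chromosomal homolog per plasmid tip
#'
#' For each plasmid tip, the minimum patristic distance to any other tip of
#' each compartment. Tips sharing an identity cluster (near-identical
#' proteins in different genomic contexts) force a distance of zero to that
#' compartment. The empirical CDFs of the two distance sets are returned.
#'
#' @param D patristic matrix from [patristic_matrix()].
#' @param tip_metadata data frame `tip`, `compartment`
#'   (`"plasmid"`/`"chromosome"`), `host_id`, optionally `identity_cluster`
#'   (`NA` when unclustered); must cover all tips.
#' @return list with `distances` (data frame `tip`, `to_plasmid`,
#'   `to_chromosome`, `zero_plasmid`, `zero_chromosome`) and `ecdf`
#'   (list of `stats::ecdf` functions per compartment, `NULL` with a warning
#'   when a compartment has no admissible homolog distances).
#' @export
closest_homolog <- function(D, tip_metadata) {
  tips <- rownames(D)
  miss <- setdiff(tips, tip_metadata$tip)
  if (length(miss))
    stop("tip metadata missing for: ", paste(miss, collapse = ", "), call. = FALSE)
  meta <- tip_metadata[match(tips, tip_metadata$tip), , drop = FALSE]
  has_ic <- !is.null(meta$identity_cluster)
  plas <- which(meta$compartment == "plasmid")
  rows <- lapply(plas, function(i) {
    d <- D[i, ]; d[i] <- NA
    res <- lapply(compartment_states, function(cmp) {
      j <- setdiff(which(meta$compartment == cmp), i)
      zero <- has_ic && !is.na(meta$identity_cluster[i]) &&
        any(!is.na(meta$identity_cluster[j]) &
              meta$identity_cluster[j] == meta$identity_cluster[i])
      dist <- if (zero) 0 else if (length(j)) min(d[j]) else NA_real_
      list(dist = dist, zero = zero)
    })
    data.frame(tip = tips[i],
               to_plasmid = res[[1L]]$dist, to_chromosome = res[[2L]]$dist,
               zero_plasmid = res[[1L]]$zero, zero_chromosome = res[[2L]]$zero,
               stringsAsFactors = FALSE)
  })
  distances <- do.call(rbind, rows)
  mk_ecdf <- function(x, label) {
    x <- x[!is.na(x)]
    if (!length(x)) {
      warning("no homolog distances for compartment ", label, call. = FALSE)
      return(NULL)
    }
    stats::ecdf(x)
  }
  list(distances = distances,
       ecdf = list(plasmid = mk_ecdf(distances$to_plasmid, "plasmid"),
                   chromosome = mk_ecdf(distances$to_chromosome, "chromosome")))
}

#' Co-resident versus globally closest plasmid homolog
#'
#' For each host carrying tips in both compartments, compares the minimal
#' patristic distance from its chromosomal tip(s) to a plasmid tip of the
#' same host (co-resident) with the distance to the closest plasmid tip
#' anywhere. The one-sided Mann-Whitney test asks whether co-resident
#' distances stochastically exceed the global minima.
#'
#' @param D patristic matrix.
#' @param tip_metadata as in [closest_homolog()].
#' @return list with `pairs` (data frame `host_id`, `coresident`, `global`)
#'   and `test` (a [mann_whitney_u()] result, `NULL` when fewer than two
#'   hosts qualify).
#' @export
coresident_comparison <- function(D, tip_metadata) {
  tips <- rownames(D)
  meta <- tip_metadata[match(tips, tip_metadata$tip), , drop = FALSE]
  hosts <- unique(meta$host_id)
  rows <- lapply(hosts, function(h) {
    chr <- which(meta$host_id == h & meta$compartment == "chromosome")
    pl_local <- which(meta$host_id == h & meta$compartment == "plasmid")
    pl_all <- which(meta$compartment == "plasmid")
    if (!length(chr) || !length(pl_local)) return(NULL)
    data.frame(host_id = h,
               coresident = min(D[chr, pl_local]),
               global = min(D[chr, setdiff(pl_all, chr)]),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    return(list(pairs = data.frame(host_id = character(),
                                   coresident = numeric(), global = numeric(),
                                   stringsAsFactors = FALSE), test = NULL))
  test <- if (nrow(pairs) >= 2L)
    mann_whitney_u(pairs$coresident, pairs$global, side = "greater") else NULL
  list(pairs = pairs, test = test)
}

## F81 transition probability matrix for the two-state compartment character.
## P(i -> j, t) = pi_j + (delta_ij - pi_j) * exp(-t / nu), nu = 1 - sum(pi^2),
## so that the expected substitution rate at stationarity equals 1.
f81_pmatrix <- function(t, pi) {
  nu <- 1 - sum(pi^2)
  e <- exp(-t / nu)
  rbind(pi + c(1 - pi[1L], -pi[2L]) * e,
        pi + c(-pi[1L], 1 - pi[2L]) * e)
}

#' Ancestral compartment reconstruction under the two-state F81 model
#'
#' Estimates marginal posterior probabilities of the plasmid/chromosome state
#' at every node by Felsenstein's pruning algorithm (one post-order pass for
#' partial likelihoods, one pre-order pass for the complementary
#' likelihoods), then selects states per node with the MPPA rule: states are
#' added in decreasing posterior order while the expected Brier-style
#' prediction error keeps decreasing. For two states this keeps the
#' second-best state whenever the best posterior falls below 0.75; exact
#' ties keep both.
#'
#' @param tree rooted `ape::phylo` with branch lengths; tips are treated as
#'   observed with certainty.
#' @param tip_states named character vector over tips, values `"plasmid"` or
#'   `"chromosome"`.
#' @param pi equilibrium frequencies `c(plasmid, chromosome)`; default
#'   `"tips"` estimates them from the observed tip-state proportions.
#' @return list of class `ancestral_reconstruction` with `posterior` (matrix,
#'   rows = nodes in `1..(Ntip+Nnode)` order, columns `plasmid`,
#'   `chromosome`), `mppa` (list of per-node selected state sets), `pi`,
#'   `log_likelihood`, and `tree`.
#' @export
ancestral_states <- function(tree, tip_states, pi = "tips") {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object", call. = FALSE)
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least 2 tips", call. = FALSE)
  states <- tip_states[tree$tip.label]
  if (any(is.na(states)) || !all(states %in% compartment_states))
    stop("tip_states must cover all tips with plasmid/chromosome", call. = FALSE)
  if (identical(pi, "tips")) {
    pi <- c(mean(states == "plasmid"), mean(states == "chromosome"))
    ## degenerate single-state data: keep the model proper
    if (any(pi == 0)) pi <- pmax(pi, 1e-6) / sum(pmax(pi, 1e-6))
  }
  stopifnot(length(pi) == 2L, abs(sum(pi) - 1) < 1e-8)
  if (all(tree$edge.length == 0) && length(unique(states)) > 1L)
    stop("all branch lengths zero with conflicting tip states: unidentifiable",
         call. = FALSE)

  m <- n + tree$Nnode
  root <- n + 1L
  edge <- tree$edge; elen <- tree$edge.length
  kids <- split(seq_len(nrow(edge)), edge[, 1L])

  ## post-order: down[v, s] = P(tip data below v | state of v = s)
  down <- matrix(1, m, 2L)
  down[seq_len(n), ] <- 0
  down[cbind(seq_len(n), match(states, compartment_states))] <- 1
  ## breadth-first node order from the root; reversed it is a valid post-order
  stack <- root
  ordered <- integer(0)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    ordered <- c(ordered, v)
    ch <- edge[kids[[as.character(v)]], 2L]
    ch <- ch[ch > n]
    stack <- c(stack, ch)
  }
  for (v in rev(ordered)) {
    for (e in kids[[as.character(v)]]) {
      w <- edge[e, 2L]
      P <- f81_pmatrix(elen[e], pi)
      down[v, ] <- down[v, ] * as.vector(P %*% down[w, ])
    }
  }
  lik <- sum(pi * down[root, ])
  if (lik <= 0) stop("zero likelihood: check branch lengths", call. = FALSE)

  ## pre-order: up[v, s] = P(data outside the subtree of v, state of v = s)
  up <- matrix(1, m, 2L)
  up[root, ] <- pi
  for (v in ordered) {
    for (e in kids[[as.character(v)]]) {
      w <- edge[e, 2L]
      P <- f81_pmatrix(elen[e], pi)
      sib <- rep(1, 2L)
      for (e2 in setdiff(kids[[as.character(v)]], e)) {
        P2 <- f81_pmatrix(elen[e2], pi)
        sib <- sib * as.vector(P2 %*% down[edge[e2, 2L], ])
      }
      up[w, ] <- as.vector(t(P) %*% (up[v, ] * sib))
    }
  }
  post <- up * down
  post <- post / rowSums(post)
  colnames(post) <- compartment_states

  mppa <- lapply(seq_len(m), function(v) mppa_select(post[v, ]))
  structure(list(posterior = post, mppa = mppa, pi = pi,
                 log_likelihood = log(lik), tree = tree),
            class = "ancestral_reconstruction")
}

## MPPA subset selection: minimize over k the expected Brier-style error
## f(k) = 1 + (1 - 2 * sum of top-k posteriors) / k; ties keep both states.
mppa_select <- function(p, tol = 1e-9) {
  ord <- order(p, decreasing = TRUE)
  f <- 1 + (1 - 2 * cumsum(p[ord])) / seq_along(p)
  k_best <- max(which(f <= min(f) + tol))   # ties keep the larger set
  sort(names(p)[ord[seq_len(k_best)]])
}

#' Count compartment-switch events from an MPPA reconstruction
#'
#' A branch contributes one event exactly when the MPPA state sets of its
#' parent and child are disjoint; the direction runs from the parent's state
#' to the child's. Branches with overlapping (ambiguous) sets contribute
#' nothing.
#'
#' @param reconstruction an [ancestral_states()] result.
#' @return list with `counts` (named integer vector
#'   `c(plasmid_to_chromosome, chromosome_to_plasmid)`) and `events`
#'   (data frame `parent`, `child`, `direction`).
#' @export
count_transitions <- function(reconstruction) {
  tree <- reconstruction$tree
  mppa <- reconstruction$mppa
  rows <- lapply(seq_len(nrow(tree$edge)), function(e) {
    a <- mppa[[tree$edge[e, 1L]]]
    b <- mppa[[tree$edge[e, 2L]]]
    if (length(intersect(a, b))) return(NULL)
    data.frame(parent = tree$edge[e, 1L], child = tree$edge[e, 2L],
               direction = if (a[1L] == "plasmid") "P->C" else "C->P",
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, rows)
  if (is.null(events))
    events <- data.frame(parent = integer(), child = integer(),
                         direction = character(), stringsAsFactors = FALSE)
  list(counts = c(plasmid_to_chromosome = sum(events$direction == "P->C"),
                  chromosome_to_plasmid = sum(events$direction == "C->P")),
       events = events)
}
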