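# Hierarchical density-based clustering with noise (HDBSCAN).
#
# Implemented from the algorithm definition: Euclidean distances are
# inflated to mutual-reachability distances using each point's core
# distance, a minimum spanning tree over the mutual-reachability graph
# gives the single-linkage hierarchy, the hierarchy is condensed by the
# minimum cluster size, and clusters are extracted by excess-of-mass
# stability. Points that never join a selected cluster are labelled -1
# (noise). Written for the moderate cohort sizes this package works at
# (hundreds of points); all-pairs distances are held in memory.

#' HDBSCAN density clustering
#'
#' @param x Numeric matrix (rows = observations) or data frame of numeric
#'   columns.
#' @param min_cluster_size Smallest group of points accepted as a cluster.
#' @param min_samples Neighbourhood size for the core distance (the
#'   density scale); defaults to `min_cluster_size`.
#' @return List with `labels` (integer per point: 0-based cluster ids,
#'   -1 = noise), `n_clusters`, and `cluster_sizes`.
#' @export
hdbscan <- function(x, min_cluster_size = 10, min_samples = min_cluster_size) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (!is_count(min_cluster_size, 2L)) {
    stop_eyec("`min_cluster_size` must be an integer >= 2")
  }
  if (n < 2L) stop_eyec("need at least 2 points")
  min_samples <- min(as.integer(min_samples), n)

  d <- as.matrix(stats::dist(x))
  # core distance: distance to the (min_samples-1)-th nearest other point
  # (the point itself counts as its own first neighbour)
  core <- apply(d, 1L, function(r) sort(r, partial = min_samples)[min_samples])
  mr <- pmax(d, outer(core, core, pmax))

  # Prim's MST on the mutual-reachability graph
  in_tree <- rep(FALSE, n)
  in_tree[1] <- TRUE
  best <- mr[1, ]; best[1] <- Inf
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)  # from, to, weight
  for (k in seq_len(n - 1L)) {
    nxt <- which.min(best)
    edges[k, ] <- c(best_from[nxt], nxt, best[nxt])
    in_tree[nxt] <- TRUE
    upd <- !in_tree & mr[nxt, ] < best
    best[upd] <- mr[nxt, upd]
    best_from[upd] <- nxt
    best[nxt] <- Inf
  }

  hier <- single_linkage(edges, n)
  cond <- condense_tree(hier, n, min_cluster_size)
  sel <- extract_eom(cond)
  labels <- label_points(cond, sel, n)

  sizes <- table(labels[labels >= 0])
  list(labels = labels, n_clusters = length(unique(labels[labels >= 0])),
       cluster_sizes = as.integer(sizes))
}

# Merge MST edges (ascending) into a dendrogram. Leaves are 1..n; internal
# nodes n+1 .. 2n-1 with children, merge distance and subtree size.
single_linkage <- function(edges, n) {
  o <- order(edges[, 3])
  edges <- edges[o, , drop = FALSE]
  parent <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  left <- integer(n - 1L); right <- integer(n - 1L)
  dist_ <- numeric(n - 1L); size <- integer(n - 1L)
  leaf_size <- c(rep(1L, n), integer(n - 1L))
  for (k in seq_len(n - 1L)) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    node <- n + k
    left[k] <- a; right[k] <- b; dist_[k] <- edges[k, 3]
    leaf_size[node] <- leaf_size[a] + leaf_size[b]
    size[k] <- leaf_size[node]
    parent[a] <- node; parent[b] <- node
  }
  list(left = left, right = right, dist = dist_, size = size, n = n)
}

subtree_leaves <- function(hier, node) {
  n <- hier$n
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) {
      out[length(out) + 1L] <- v
    } else {
      k <- v - n
      stack <- c(stack, hier$left[k], hier$right[k])
    }
  }
  out
}

node_size <- function(hier, node) {
  if (node <= hier$n) 1L else hier$size[node - hier$n]
}

# Condense the dendrogram: keep only splits where both sides reach
# min_cluster_size; smaller sides fall out of the running cluster as
# individual points at the split's lambda (= 1/distance).
# Returns an edge table: parent cluster, child (cluster id or -point),
# lambda, size; cluster ids start at 1 (the root cluster).
condense_tree <- function(hier, n, mcs) {
  root <- 2L * n - 1L
  relabel <- integer(2L * n - 1L)
  relabel[root] <- 1L
  next_label <- 1L
  parent <- integer(0); child <- integer(0)
  lambda <- numeric(0); csize <- integer(0)
  add <- function(p, c_, l, s) {
    parent[length(parent) + 1L] <<- p
    child[length(child) + 1L] <<- c_
    lambda[length(lambda) + 1L] <<- l
    csize[length(csize) + 1L] <<- s
  }
  drop_leaves <- function(cluster, node, lam) {
    for (leaf in subtree_leaves(hier, node)) add(cluster, -leaf, lam, 1L)
  }
  queue <- root
  while (length(queue) > 0L) {
    node <- queue[1]; queue <- queue[-1]
    if (node <= n) next
    k <- node - n
    a <- hier$left[k]; b <- hier$right[k]
    lam <- if (hier$dist[k] > 0) 1 / hier$dist[k] else 1e12
    na <- node_size(hier, a); nb <- node_size(hier, b)
    cl <- relabel[node]
    if (na >= mcs && nb >= mcs) {
      for (ch in c(a, b)) {
        next_label <- next_label + 1L
        relabel[ch] <- next_label
        add(cl, next_label, lam, node_size(hier, ch))
        if (ch > n) queue <- c(queue, ch)
      }
    } else if (na < mcs && nb < mcs) {
      drop_leaves(cl, a, lam)
      drop_leaves(cl, b, lam)
    } else {
      big <- if (na >= mcs) a else b
      small <- if (na >= mcs) b else a
      relabel[big] <- cl
      drop_leaves(cl, small, lam)
      if (big > n) queue <- c(queue, big)
    }
  }
  list(parent = parent, child = child, lambda = lambda, size = csize,
       n_clusters = next_label)
}

# Excess-of-mass cluster selection. The root cluster (id 1) is never
# selected, so a dataset with no internal density split comes back all
# noise.
extract_eom <- function(cond) {
  m <- cond$n_clusters
  birth <- numeric(m)
  for (i in seq_along(cond$child)) {
    if (cond$child[i] > 0) birth[cond$child[i]] <- cond$lambda[i]
  }
  stability <- numeric(m)
  for (i in seq_along(cond$parent)) {
    p <- cond$parent[i]
    stability[p] <- stability[p] + (cond$lambda[i] - birth[p]) * cond$size[i]
  }
  children_of <- split(cond$child[cond$child > 0], cond$parent[cond$child > 0])
  selected <- rep(FALSE, m)
  subtree_stab <- numeric(m)
  for (cl in m:1) {
    kids <- children_of[[as.character(cl)]]
    if (is.null(kids) || length(kids) == 0L) {
      selected[cl] <- TRUE
      subtree_stab[cl] <- stability[cl]
    } else {
      kid_sum <- sum(subtree_stab[kids])
      if (stability[cl] >= kid_sum && cl != 1L) {
        selected[cl] <- TRUE
        # deselect all descendants
        stack <- kids
        while (length(stack) > 0L) {
          v <- stack[length(stack)]; stack <- stack[-length(stack)]
          selected[v] <- FALSE
          more <- children_of[[as.character(v)]]
          if (!is.null(more)) stack <- c(stack, more)
        }
        subtree_stab[cl] <- stability[cl]
      } else {
        subtree_stab[cl] <- kid_sum
      }
    }
  }
  selected[1L] <- FALSE
  which(selected)
}

label_points <- function(cond, selected, n) {
  parent_of_cluster <- integer(cond$n_clusters)
  for (i in seq_along(cond$child)) {
    if (cond$child[i] > 0) parent_of_cluster[cond$child[i]] <- cond$parent[i]
  }
  point_cluster <- integer(n)
  for (i in seq_along(cond$child)) {
    if (cond$child[i] < 0) point_cluster[-cond$child[i]] <- cond$parent[i]
  }
  labels <- rep(-1L, n)
  if (length(selected) > 0L) {
    new_id <- setNames(seq_along(selected) - 1L, selected)
    for (p in seq_len(n)) {
      cl <- point_cluster[p]
      while (cl > 0L) {
        if (cl %in% selected) {
          labels[p] <- new_id[[as.character(cl)]]
          break
        }
        cl <- parent_of_cluster[cl]
      }
    }
  }
  labels
}
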