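# Hierarchical density-based clustering (HDBSCAN): mutual-reachability
# distances -> minimum spanning tree -> single-linkage hierarchy ->
# condensed tree at min_cluster_size -> excess-of-mass cluster selection.
# Exact O(n^2) implementation, deterministic for identical input.

hdbscan_points <- function(coords, min_cluster_size, min_samples = min_cluster_size) {
  n <- nrow(coords)
  if (min_cluster_size < 2L) abort("`min_cluster_size` must be >= 2.")
  if (n < min_cluster_size) return(rep(-1L, n))
  d <- as.matrix(dist(coords))
  # core distance: k-th nearest neighbour with the point itself counted
  k <- min(min_samples, n)
  core <- apply(d, 1L, function(r) sort(r, partial = k)[k])
  mr <- pmax(d, outer(core, rep(1, n)), outer(rep(1, n), core))

  # Prim MST on the mutual-reachability graph
  in_tree <- rep(FALSE, n)
  best <- rep(Inf, n); from <- rep(NA_integer_, n)
  in_tree[1] <- TRUE
  best <- mr[1, ]; from[] <- 1L; best[1] <- Inf
  edges <- matrix(0, n - 1L, 3L) # from, to, weight
  for (e in seq_len(n - 1L)) {
    v <- which.min(replace(best, in_tree, Inf))
    edges[e, ] <- c(from[v], v, best[v])
    in_tree[v] <- TRUE
    upd <- !in_tree & mr[v, ] < best
    best[upd] <- mr[v, upd]; from[upd] <- v
  }
  edges <- edges[order(edges[, 3L]), , drop = FALSE]

  # single-linkage hierarchy via union-find; internal nodes n+1 .. 2n-1
  parent_uf <- seq_len(2L * n - 1L)
  find <- function(i) {
    while (parent_uf[i] != i) {
      parent_uf[i] <<- parent_uf[parent_uf[i]]
      i <- parent_uf[i]
    }
    i
  }
  comp_node <- seq_len(n) # component representative -> current hierarchy node
  child_l <- child_r <- integer(n - 1L)
  height <- numeric(n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  for (e in seq_len(n - 1L)) {
    a <- find(edges[e, 1L]); b <- find(edges[e, 2L])
    node <- n + e
    child_l[e] <- comp_node[a]; child_r[e] <- comp_node[b]
    height[e] <- edges[e, 3L]
    size[node] <- size[comp_node[a]] + size[comp_node[b]]
    parent_uf[a] <- b
    comp_node[b] <- node
  }

  # condensed tree: walk down from the root, splitting only when both sides
  # reach min_cluster_size; smaller sides shed their points at the split level
  root_node <- 2L * n - 1L
  n_cl <- 0L
  cl_parent <- integer(0); cl_birth <- numeric(0)
  cl_death <- numeric(0); cl_children <- list()
  pt_cluster <- integer(n); pt_lambda <- numeric(n)
  leaves_of <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v)
      else stack <- c(stack, child_l[v - n], child_r[v - n])
    }
    out
  }
  lam <- function(h) 1 / max(h, 1e-12)

  new_cluster <- function(parent, birth) {
    n_cl <<- n_cl + 1L
    cl_parent[n_cl] <<- parent; cl_birth[n_cl] <<- birth
    cl_death[n_cl] <<- NA_real_; cl_children[[n_cl]] <<- integer(0)
    if (parent > 0L) cl_children[[parent]] <<- c(cl_children[[parent]], n_cl)
    n_cl
  }
  root_cl <- new_cluster(0L, 0)
  stack <- list(list(node = root_node, cl = root_cl))
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- fr$node; cl <- fr$cl
    while (TRUE) {
      if (node <= n) { # single point remains: it leaves as density vanishes
        pt_cluster[node] <- cl; pt_lambda[node] <- lam(core[node])
        cl_death[cl] <- max(cl_death[cl], lam(core[node]), na.rm = TRUE)
        break
      }
      e <- node - n
      l <- child_l[e]; r <- child_r[e]
      lv <- lam(height[e])
      sl <- size[l]; sr <- size[r]
      if (sl >= min_cluster_size && sr >= min_cluster_size) {
        cl_death[cl] <- lv
        stack[[length(stack) + 1L]] <- list(node = l, cl = new_cluster(cl, lv))
        stack[[length(stack) + 1L]] <- list(node = r, cl = new_cluster(cl, lv))
        break
      } else if (sl < min_cluster_size && sr < min_cluster_size) {
        for (p in leaves_of(node)) { pt_cluster[p] <- cl; pt_lambda[p] <- lv }
        cl_death[cl] <- lv
        break
      } else {
        small <- if (sl < min_cluster_size) l else r
        big <- if (sl < min_cluster_size) r else l
        for (p in leaves_of(small)) { pt_cluster[p] <- cl; pt_lambda[p] <- lv }
        node <- big
      }
    }
  }

  # stability (excess of mass) per condensed cluster
  stability <- numeric(n_cl)
  for (p in seq_len(n)) {
    cl <- pt_cluster[p]
    stability[cl] <- stability[cl] +
      min(pt_lambda[p], cl_death[cl]) - cl_birth[cl]
  }
  # points passed to child clusters persist until the parent's death;
  # cluster sizes (points at birth) accumulate bottom-up
  cl_size <- tabulate(pt_cluster, n_cl)
  # children always carry a higher index than their parent, so descending
  # index order within equal birth levels keeps the pass bottom-up
  ord <- order(cl_birth, seq_len(n_cl), decreasing = TRUE)
  for (cl in ord) {
    for (ch in cl_children[[cl]]) {
      cl_size[cl] <- cl_size[cl] + cl_size[ch]
      stability[cl] <- stability[cl] + cl_size[ch] * (cl_death[cl] - cl_birth[cl])
    }
  }

  # excess-of-mass selection, root excluded
  selected <- rep(FALSE, n_cl)
  value <- numeric(n_cl)
  for (cl in ord) {
    ch <- cl_children[[cl]]
    if (!length(ch)) {
      value[cl] <- stability[cl]; selected[cl] <- TRUE
    } else {
      child_sum <- sum(value[ch])
      if (is.finite(stability[cl]) && stability[cl] > child_sum && cl != root_cl) {
        value[cl] <- stability[cl]
        selected[cl] <- TRUE
        deselect_subtree(ch, cl_children, environment())
      } else {
        value[cl] <- child_sum
      }
    }
  }
  selected[root_cl] <- FALSE

  # label: deepest selected ancestor (or self) of each point's cluster
  labels <- rep(-1L, n)
  for (p in seq_len(n)) {
    cl <- pt_cluster[p]
    while (cl > 0L && !selected[cl]) cl <- cl_parent[cl]
    if (cl > 0L) labels[p] <- cl
  }
  # contiguous labels from 0, ordered by decreasing cluster size then first point
  used <- sort(unique(labels[labels > 0L]))
  if (length(used)) {
    sz <- vapply(used, function(u) sum(labels == u), 1L)
    first <- vapply(used, function(u) which(labels == u)[1L], 1L)
    used <- used[order(-sz, first)]
    labels <- match(labels, used) - 1L
    labels[is.na(labels)] <- -1L
  }
  labels
}

deselect_subtree <- function(cls, children, env) {
  stack <- cls
  while (length(stack)) {
    cl <- stack[length(stack)]; stack <- stack[-length(stack)]
    env$selected[cl] <- FALSE
    stack <- c(stack, children[[cl]])
  }
}
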