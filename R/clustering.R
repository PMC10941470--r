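# Ward-linkage agglomeration and dendrogram pruning into isogloss partitions.

#' Ward-linkage hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerates units with the Lance–Williams Ward recurrence. The default
#' `"ward.D2"` dialect treats the input as distances and minimizes the Ward
#' objective on squared distances (merge heights are reported on the original
#' distance scale); `"ward.D"` applies the same recurrence to the distances
#' as given. Ties between equally cheap merges are broken deterministically
#' in favour of the pair whose clusters contain the lowest original leaf
#' indices, so runs are bit-reproducible regardless of platform.
#'
#' @param m a `dissimilarity_matrix` (all pairs defined) or a symmetric
#'   numeric matrix / `dist` object.
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return an object of class `c("isogloss_dendrogram", "hclust")` with the
#'   usual `merge`, `height`, `order`, `labels` fields.
#' @export
ward_cluster <- function(m, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  if (inherits(m, "dissimilarity_matrix")) {
    if (!all(m$defined)) {
      stop("ward_cluster(): undefined pairs present; merge or drop units first",
           call. = FALSE)
    }
    labels <- m$units
    S <- m$values
  } else if (inherits(m, "dist")) {
    labels <- attr(m, "Labels")
    S <- as.matrix(m)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(S)))
  } else if (is.matrix(m)) {
    if (!isSymmetric(unname(m), tol = 1e-12)) {
      stop("ward_cluster(): input matrix is not symmetric", call. = FALSE)
    }
    labels <- rownames(m)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
    S <- m
  } else {
    stop("ward_cluster(): unsupported input type", call. = FALSE)
  }
  if (anyNA(S)) stop("ward_cluster(): missing entries in dissimilarities", call. = FALSE)
  n <- nrow(S)
  if (n < 2L) stop("ward_cluster(): need at least 2 units", call. = FALSE)
  S <- unname(S)
  if (method == "ward.D2") S <- S^2
  diag(S) <- Inf

  size <- rep(1L, n)
  code <- -seq_len(n)            # hclust convention: negative = leaf
  minleaf <- seq_len(n)          # lowest original leaf index per active cluster
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  children <- vector("list", n - 1L)

  for (k in seq_len(n - 1L)) {
    idx <- which(active)
    Sm <- S[idx, idx, drop = FALSE]
    hmin <- min(Sm)
    cand <- which(Sm == hmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pi <- idx[cand[, 1]]; pj <- idx[cand[, 2]]
    lo <- pmin(minleaf[pi], minleaf[pj]); hi <- pmax(minleaf[pi], minleaf[pj])
    pick <- order(lo, hi)[1]
    i <- pi[pick]; j <- pj[pick]

    height[k] <- if (method == "ward.D2") sqrt(hmin) else hmin
    # order children so the lower-minleaf cluster comes first
    ch <- if (minleaf[i] <= minleaf[j]) c(code[i], code[j]) else c(code[j], code[i])
    merge[k, ] <- ch
    children[[k]] <- ch

    m_others <- which(active); m_others <- m_others[m_others != i & m_others != j]
    ni <- size[i]; nj <- size[j]
    if (length(m_others) > 0L) {
      nm <- size[m_others]
      upd <- ((ni + nm) * S[i, m_others] + (nj + nm) * S[j, m_others] - nm * hmin) /
        (ni + nj + nm)
      S[i, m_others] <- upd
      S[m_others, i] <- upd
    }
    active[j] <- FALSE
    S[j, ] <- Inf; S[, j] <- Inf
    size[i] <- ni + nj
    code[i] <- k
    minleaf[i] <- min(minleaf[i], minleaf[j])
  }

  # leaf order by depth-first traversal from the root
  dfs <- function(node) {
    if (node < 0L) return(-node)
    c(dfs(children[[node]][1]), dfs(children[[node]][2]))
  }
  out <- structure(
    list(merge = merge, height = height, order = dfs(n - 1L),
         labels = labels, method = method,
         call = match.call(), dist.method = "user-supplied"),
    class = c("isogloss_dendrogram", "hclust")
  )
  out
}

# cluster membership after applying the first n-K merges (internal)
membership_at <- function(dend, K) {
  n <- length(dend$labels)
  grp <- -seq_len(n)                       # each leaf its own (coded) cluster
  names(grp) <- NULL
  if (K < n) {
    for (k in seq_len(n - K)) {
      ch <- dend$merge[k, ]
      grp[grp == ch[1] | grp == ch[2]] <- k
    }
  }
  grp
}

#' Prune a dendrogram into an isogloss partition with K groups
#'
#' Removes the K−1 highest merges, leaving exactly K groups. Group labels are
#' assigned deterministically in order of first appearance along the
#' dendrogram's depth-first leaf order, so label 1 is the group containing
#' the leftmost leaf.
#'
#' @param dend an `isogloss_dendrogram` (from [ward_cluster()]).
#' @param K number of groups, `1 <= K <= n`.
#' @return an `isogloss_partition`: named integer vector (unit -> group in
#'   `1..K`) with attribute `K`.
#' @export
cut_dendrogram <- function(dend, K) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$labels)
  if (!(K >= 1L && K <= n)) {
    stop("cut_dendrogram(): K must be between 1 and ", n, call. = FALSE)
  }
  grp <- membership_at(dend, K)
  first_seen <- unique(grp[dend$order])
  assignment <- match(grp, first_seen)
  names(assignment) <- dend$labels
  structure(assignment, K = as.integer(K), class = "isogloss_partition")
}

#' @export
print.isogloss_partition <- function(x, ...) {
  cat("Isogloss partition: ", length(x), " units in ", attr(x, "K"),
      " groups (sizes: ", paste(tabulate(x, attr(x, "K")), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Prune a dendrogram at several depths
#'
#' @param dend an `isogloss_dendrogram`.
#' @param Ks integer vector of group counts (e.g. `2:5`).
#' @return named list of `isogloss_partition`, one per K, nested: the
#'   partition at K is the merge of two groups of the partition at K+1.
#' @export
cut_range <- function(dend, Ks = 2:5) {
  out <- lapply(Ks, function(K) cut_dendrogram(dend, K))
  names(out) <- paste0("K", Ks)
  out
}

#' Are two partitions identical up to group relabeling?
#'
#' @param p,q partitions over the same units (named vectors or factors).
#' @return TRUE iff the induced equivalence relations coincide.
#' @export
same_partition <- function(p, q) {
  if (!is.null(names(p)) && !is.null(names(q))) q <- q[names(p)]
  tab <- table(p, q)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

#' Export partitions as long CSV (unit_id, K, group)
#' @param partitions list of `isogloss_partition` (e.g. from [cut_range()]).
#' @param path output path.
#' @export
write_partitions <- function(partitions, path) {
  if (inherits(partitions, "isogloss_partition")) partitions <- list(partitions)
  df <- do.call(rbind, lapply(partitions, function(p) {
    data.frame(unit_id = names(p), K = attr(p, "K"), group = as.integer(p))
  }))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are differences of merge heights (leaf branches run from
#' height zero to the leaf's first merge); leaf names are unit ids.
#' @param dend an `isogloss_dendrogram`.
#' @param path output path.
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "hclust"))
  phy <- ape::as.phylo(dend)
  ape::write.tree(phy, file = path)
  invisible(path)
}
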