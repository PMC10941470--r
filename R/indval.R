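# Indicator-name analysis: group-size-corrected presence/absence IndVal with
# a permutation null.

# relative occurrence frequency per group: L x names matrix (internal)
group_freq <- function(m, grp) {
  counts <- rowsum(m, grp)                       # occurrences per group
  sizes <- as.vector(rowsum(rep(1L, length(grp)), grp))
  counts / sizes
}

#' Indicator-value statistics for every name and group
#'
#' Presence/absence indicator values with group-size correction: with
#' \eqn{r_g} the fraction of units in group \eqn{g} recording the name,
#' specificity \eqn{A_g = r_g / \sum_h r_h}, fidelity \eqn{B_g = r_g}, and
#' the indicator statistic \eqn{\sqrt{A_g B_g}}. The best group is the
#' argmax of the statistic, ties going to the lowest group label. Names
#' absent from every unit are excluded with a message. Only single target
#' groups are considered (no group combinations).
#'
#' @param occurrence an `occurrence_table` (binary unit-by-name matrix).
#' @param partition an `isogloss_partition` or named group vector over the
#'   same units.
#' @return list with matrices `A`, `B`, `stat` (groups x names) and vectors
#'   `best_group`, `best_stat` per name.
#' @export
indval_stats <- function(occurrence, partition) {
  m <- unclass(occurrence)
  if (!is.null(names(partition))) {
    if (!setequal(names(partition), rownames(m))) {
      stop("indval_stats(): unit rosters of occurrence table and partition differ",
           call. = FALSE)
    }
    partition <- partition[rownames(m)]
  } else if (length(partition) != nrow(m)) {
    stop("indval_stats(): partition length does not match unit count", call. = FALSE)
  }
  grp <- as.integer(factor(partition))
  if (any(tabulate(grp) == 0L)) stop("indval_stats(): empty group", call. = FALSE)
  absent <- colSums(m) == 0L
  if (any(absent)) {
    message("indval_stats: excluded ", sum(absent), " name(s) absent everywhere")
    m <- m[, !absent, drop = FALSE]
  }
  r <- group_freq(m, grp)                         # B_g = r_g
  A <- sweep(r, 2, colSums(r), "/")
  stat <- sqrt(A * r)
  best <- apply(stat, 2, which.max)               # which.max: first max = lowest label
  list(A = A, B = r, stat = stat,
       best_group = best,
       best_stat = stat[cbind(best, seq_len(ncol(stat)))],
       names = colnames(m), groups = sort(unique(grp)))
}

# max-over-groups statistic per name for one label vector (internal)
max_stat <- function(m, grp) {
  r <- group_freq(m, grp)
  A <- sweep(r, 2, colSums(r), "/")
  apply(sqrt(A * r), 2, max)
}

#' Permutation test of indicator values
#'
#' Group labels are permuted uniformly over units; the null statistic is the
#' maximum over groups of the indicator statistic, compared with the observed
#' best-group statistic. Monte Carlo p-values carry the plus-one correction
#' \eqn{p = (1 + \#\{stat^{perm} \ge stat^{obs}\}) / (1 + n_{perm})}.
#' With `exact = TRUE` (two groups only) all distinct label arrangements are
#' enumerated and the p-value is the exact fraction.
#'
#' @param occurrence an `occurrence_table`.
#' @param partition group labels over the units.
#' @param n_perm number of Monte Carlo permutations (default 999; at least 99).
#' @param seed integer seed; required, so runs are reproducible.
#' @param exact enumerate all distinct two-group label arrangements instead
#'   of sampling.
#' @param alpha reference level used only to warn when `n_perm` is too small
#'   to ever reach it.
#' @return data.frame with columns `name`, `best_group`, `A`, `B`, `stat`,
#'   `p_perm`, `n_perm`, sorted by the table's name order.
#' @export
indval_test <- function(occurrence, partition, n_perm = 999L, seed,
                        exact = FALSE, alpha = 0.05) {
  if (missing(seed)) stop("indval_test(): seed is required", call. = FALSE)
  m <- unclass(occurrence)
  obs <- indval_stats(occurrence, partition)
  m <- m[, obs$names, drop = FALSE]
  grp <- as.integer(factor(if (!is.null(names(partition))) partition[rownames(m)] else partition))

  if (exact) {
    L <- length(unique(grp))
    if (L != 2L) {
      stop("indval_test(): exact enumeration implemented for 2 groups only",
           call. = FALSE)
    }
    n <- length(grp)
    n1 <- sum(grp == 1L)
    combos <- utils::combn(n, n1)
    ge <- rep(0L, ncol(m))
    for (c_i in seq_len(ncol(combos))) {
      g <- rep(2L, n); g[combos[, c_i]] <- 1L
      ge <- ge + (max_stat(m, g) >= obs$best_stat - 1e-12)
    }
    p <- ge / ncol(combos)
    n_used <- ncol(combos)
  } else {
    if (n_perm < 99L) stop("indval_test(): n_perm must be at least 99", call. = FALSE)
    if (alpha < 1 / (n_perm + 1)) {
      warning("indval_test(): n_perm = ", n_perm,
              " cannot reach alpha = ", alpha, " (minimum attainable p = ",
              signif(1 / (n_perm + 1), 3), ")")
    }
    set.seed(as.integer(seed))
    ge <- rep(0L, ncol(m))
    for (b in seq_len(n_perm)) {
      g <- sample(grp)
      ge <- ge + (max_stat(m, g) >= obs$best_stat - 1e-12)
    }
    p <- (1 + ge) / (1 + n_perm)
    n_used <- n_perm
  }
  out <- data.frame(
    name = obs$names,
    best_group = obs$best_group,
    A = obs$A[cbind(obs$best_group, seq_along(obs$names))],
    B = obs$B[cbind(obs$best_group, seq_along(obs$names))],
    stat = obs$best_stat,
    p_perm = p,
    n_perm = n_used,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("indval_result", "data.frame")
  out
}

#' Filter significant indicator names per group
#'
#' @param results an `indval_result` from [indval_test()].
#' @param alpha significance threshold on the permutation p-value.
#' @return data.frame of names with `p_perm <= alpha`, ordered by group then
#'   by decreasing indicator statistic.
#' @export
indicators <- function(results, alpha = 0.05) {
  stopifnot(inherits(results, "data.frame"))
  sig <- results[results$p_perm <= alpha, , drop = FALSE]
  sig <- sig[order(sig$best_group, -sig$stat, sig$name), , drop = FALSE]
  rownames(sig) <- NULL
  sig
}
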