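# Seeded generators for nomenclature tables, landrace occurrence tables and
# covariate grids with known ground truth.

#' Configuration for the synthetic-data generators
#'
#' Bundles every parameter of the generative model, with defaults mirroring
#' the scale of the motivating surveys: 69 municipalities by 310 tree species
#' for the multi-species table, 14 regions by 722 landrace varieties for the
#' single-crop table, and about 5,800 grid centroids for the covariate
#' layers.
#'
#' The tree model places units on a one-dimensional latent environmental
#' gradient; species occupancy (whether a species enters a unit's survey) is
#' a logistic function of the unit coordinate with a per-species random
#' slope, creating innate between-unit flora differences. Each latent group
#' carries one canonical name per species; a unit replaces the group name
#' with a private form with probability `epsilon` (lexicon noise) and records
#' an additional group-level synonym with probability `synonym_rate`. The
#' landrace model gives each group an exclusive variety pool carried by all
#' its units; with probability `mu` a unit additionally carries each variety
#' of an adjacent group's pool (seed-transfer migration, ring adjacency by
#' default).
#'
#' @param n_units,n_groups,n_species tree-table dimensions and planted group
#'   count.
#' @param occupancy baseline probability a species enters a unit's survey.
#' @param gradient strength of the environmental gradient (logit slope scale).
#' @param epsilon probability a unit replaces a group name with a private name.
#' @param synonym_rate probability a unit records an extra synonym for a
#'   present species.
#' @param shared_species_frac fraction of species whose canonical name is
#'   common to all groups.
#' @param n_units_rice,n_groups_rice,n_varieties_per_group landrace-table
#'   dimensions.
#' @param mu migration rate: probability a unit carries a given variety from
#'   an adjacent group's pool.
#' @param adjacency optional symmetric logical matrix (`n_groups_rice` square)
#'   marking adjacent groups; default is a ring over group order.
#' @param n_centroids total grid centroids.
#' @param relabel_frac fraction of centroids whose degraded categorical layer
#'   label is resampled uniformly over groups.
#' @param q_target target factor-detector q of the numeric layer against the
#'   planted partition, in (0, 1]; noise variance is set to
#'   `Var(group means) * (1 - q) / q`, so `q_target = 1` means zero noise.
#' @param seed integer seed (mandatory).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_units = 69L, n_groups = 3L, n_species = 310L,
                             occupancy = 0.30, gradient = 1, epsilon = 0.05,
                             synonym_rate = 0.10, shared_species_frac = 0,
                             n_units_rice = 14L, n_groups_rice = 2L,
                             n_varieties_per_group = 361L, mu = 0.10,
                             adjacency = NULL,
                             n_centroids = 5800L, relabel_frac = 0.20,
                             q_target = 0.80, seed) {
  if (missing(seed)) stop("synthetic_config(): seed is mandatory", call. = FALSE)
  probs <- c(occupancy = occupancy, epsilon = epsilon,
             synonym_rate = synonym_rate, shared_species_frac = shared_species_frac,
             mu = mu, relabel_frac = relabel_frac)
  if (any(probs < 0 | probs > 1)) {
    stop("synthetic_config(): probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "), call. = FALSE)
  }
  if (!(q_target > 0 && q_target <= 1)) {
    stop("synthetic_config(): q_target must lie in (0, 1]; a target of 1 with ",
         "positive noise is unattainable", call. = FALSE)
  }
  if (n_groups > n_units || n_groups_rice > n_units_rice) {
    stop("synthetic_config(): more groups than units", call. = FALSE)
  }
  if (!is.null(adjacency)) {
    stopifnot(is.matrix(adjacency), nrow(adjacency) == n_groups_rice,
              isSymmetric(adjacency))
  }
  structure(list(n_units = as.integer(n_units), n_groups = as.integer(n_groups),
                 n_species = as.integer(n_species), occupancy = occupancy,
                 gradient = gradient, epsilon = epsilon,
                 synonym_rate = synonym_rate,
                 shared_species_frac = shared_species_frac,
                 n_units_rice = as.integer(n_units_rice),
                 n_groups_rice = as.integer(n_groups_rice),
                 n_varieties_per_group = as.integer(n_varieties_per_group),
                 mu = mu, adjacency = adjacency,
                 n_centroids = as.integer(n_centroids),
                 relabel_frac = relabel_frac, q_target = q_target,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# contiguous near-equal group blocks over the unit roster (internal)
planted_partition <- function(units, K) {
  g <- as.integer(cut(seq_along(units), K, labels = FALSE))
  structure(stats::setNames(g, units), K = as.integer(K),
            class = "isogloss_partition")
}

#' Simulate a multi-species folk-nomenclature table with known groups
#'
#' See [synthetic_config()] for the generative model. Units are split into
#' `n_groups` contiguous blocks along the environmental gradient. If a unit
#' draws an empty survey its species row is redrawn (up to 100 attempts).
#'
#' @param config a `synthetic_config`.
#' @return list with `table` (a `folk_table`), `truth` (the planted
#'   `isogloss_partition`) and `expected_records` (the model's conditional
#'   expectation of the record count given the drawn occupancy
#'   probabilities).
#' @export
simulate_tree_nomenclature <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_units; S <- config$n_species
  units <- sprintf("u%03d", seq_len(n))
  species <- sprintf("sp%03d", seq_len(S))
  truth <- planted_partition(units, config$n_groups)

  e <- if (n > 1) seq(-1, 1, length.out = n) else 0
  slope <- config$gradient * stats::rnorm(S)
  b0 <- stats::qlogis(config$occupancy)
  p <- stats::plogis(outer(e, slope) + b0)        # n x S occupancy probs

  present <- matrix(stats::rbinom(n * S, 1L, p), n, S)
  for (u in which(rowSums(present) == 0L)) {
    for (try in seq_len(100L)) {
      present[u, ] <- stats::rbinom(S, 1L, p[u, ])
      if (sum(present[u, ]) > 0L) break
    }
    if (sum(present[u, ]) == 0L) {
      stop("simulate_tree_nomenclature(): unit ", units[u],
           " drew an empty survey 100 times; raise occupancy", call. = FALSE)
    }
  }

  shared <- stats::runif(S) < config$shared_species_frac
  idx <- which(present == 1L, arr.ind = TRUE)
  u_i <- idx[, 1]; s_i <- idx[, 2]
  g_i <- as.integer(truth)[u_i]
  canonical <- ifelse(shared[s_i], sprintf("name%03d", s_i),
                      sprintf("name%03d.g%d", s_i, g_i))
  private <- stats::runif(nrow(idx)) < config$epsilon
  name1 <- ifelse(private, sprintf("name%03d.%s.priv", s_i, units[u_i]), canonical)
  extra <- stats::runif(nrow(idx)) < config$synonym_rate
  syn <- ifelse(shared[s_i[extra]], sprintf("name%03d.syn", s_i[extra]),
                sprintf("name%03d.g%d.syn", s_i[extra], g_i[extra]))

  tab <- folk_table(
    unit_id = c(units[u_i], units[u_i[extra]]),
    species_id = c(species[s_i], species[s_i[extra]]),
    name = c(name1, syn),
    normalize = FALSE
  )
  list(table = tab, truth = truth,
       expected_records = sum(p) * (1 + config$synonym_rate))
}

ring_adjacency <- function(K) {
  adj <- matrix(FALSE, K, K)
  if (K > 1) {
    for (g in seq_len(K)) {
      adj[g, if (g == K) 1 else g + 1] <- TRUE
      adj[g, if (g == 1) K else g - 1] <- TRUE
    }
  }
  diag(adj) <- FALSE
  adj
}

#' Simulate a landrace occurrence table with known groups and indicators
#'
#' Each planted group holds an exclusive pool of `n_varieties_per_group`
#' variety names carried by all its units; with probability `mu` a unit
#' additionally carries each variety from the pools of adjacent groups
#' (seed-transfer migration). The planted indicator list contains the
#' varieties that remain exclusive to their home group after migration (they
#' are present in every home unit by construction).
#'
#' @param config a `synthetic_config`.
#' @return list with `occurrence` (an `occurrence_table`), `truth` (planted
#'   `isogloss_partition`) and `planted_indicators` (character vector).
#' @export
simulate_rice_varieties <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  n <- config$n_units_rice; K <- config$n_groups_rice
  units <- sprintf("r%02d", seq_len(n))
  truth <- planted_partition(units, K)
  per <- config$n_varieties_per_group
  pool_of <- rep(seq_len(K), each = per)
  varieties <- sprintf("v%d.%03d", pool_of, sequence(rep(per, K)))
  adj <- if (is.null(config$adjacency)) ring_adjacency(K) else config$adjacency

  m <- matrix(0L, n, length(varieties), dimnames = list(units, varieties))
  g_u <- as.integer(truth)
  for (u in seq_len(n)) {
    m[u, pool_of == g_u[u]] <- 1L
    if (config$mu > 0) {
      from <- which(adj[g_u[u], ])
      mig <- pool_of %in% from & stats::runif(length(varieties)) < config$mu
      m[u, mig] <- 1L
    }
  }
  home_units <- lapply(seq_len(K), function(g) which(g_u == g))
  exclusive <- vapply(seq_along(varieties), function(j) {
    g <- pool_of[j]
    all(m[home_units[[g]], j] == 1L) && sum(m[, j]) == length(home_units[[g]])
  }, logical(1))
  list(occurrence = occurrence_table(m), truth = truth,
       planted_indicators = varieties[exclusive])
}

#' Simulate a centroid covariate grid tied to a planted partition
#'
#' Units are tiled as unit squares on a near-square lattice; `n_centroids`
#' points are spread round-robin over unit territories at uniform positions.
#' Three layers are produced: `truth`, the planted group at each centroid
#' (V-measure 1 against the partition by construction); `degraded`, the truth
#' layer with a `relabel_frac` fraction of centroids resampled uniformly over
#' groups (tunable V-measure); and `gradient`, a numeric layer equal to the
#' group mean plus Gaussian noise whose variance is chosen so the expected
#' factor-detector q against the truth strata equals `q_target`
#' (`sigma^2 = Var(means) (1 - q)/q`; `q_target = 1` yields zero noise).
#'
#' @param config a `synthetic_config`.
#' @param truth an `isogloss_partition` giving each unit's planted group.
#' @return a `centroid_layers` object with layers `unit`, `truth`,
#'   `degraded`, `gradient`.
#' @export
simulate_covariate_grid <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(truth, "isogloss_partition"))
  set.seed(config$seed + 2L)
  units <- names(truth)
  n_u <- length(units)
  K <- attr(truth, "K")
  ncent <- config$n_centroids
  ncol_grid <- ceiling(sqrt(n_u))
  cell_x <- (seq_len(n_u) - 1) %% ncol_grid
  cell_y <- (seq_len(n_u) - 1) %/% ncol_grid

  owner <- rep_len(seq_len(n_u), ncent)
  x <- cell_x[owner] + stats::runif(ncent)
  y <- cell_y[owner] + stats::runif(ncent)
  grp <- as.integer(truth)[owner]

  truth_layer <- paste0("g", grp)
  degraded <- truth_layer
  flip <- stats::runif(ncent) < config$relabel_frac
  degraded[flip] <- paste0("g", sample.int(K, sum(flip), replace = TRUE))

  mu_g <- seq_len(K)                         # unit-spaced group means
  counts <- tabulate(grp, K)
  mbar <- sum(mu_g * counts) / ncent
  var_means <- sum(counts * (mu_g - mbar)^2) / ncent
  sigma2 <- var_means * (1 - config$q_target) / config$q_target
  gradient <- mu_g[grp] + stats::rnorm(ncent, sd = sqrt(sigma2))

  centroid_layers(sprintf("c%05d", seq_len(ncent)), x, y,
                  layers = list(unit = units[owner], truth = truth_layer,
                                degraded = degraded, gradient = gradient))
}
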