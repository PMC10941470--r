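# Orchestration: staged commands driven by a single config, plus an
# end-to-end pipeline runner. These functions back the thin command-line
# front end shipped in inst/cli/isogloss.R.

pipeline_defaults <- function() {
  list(
    seed = NULL,
    out_dir = "isogloss-out",
    simulate = list(),
    cluster = list(distance = "shared-name", ward = "ward.D2", K = 2:5,
                   min_species = 5L, strict = FALSE),
    indval = list(K = NULL, n_perm = 999L, alpha = 0.05, force_multi_species = FALSE),
    associate = list(n_perm = 999L)
  )
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read a pipeline run configuration
#'
#' Reads a YAML (or JSON) document and merges it over the documented
#' defaults. The seed is mandatory: every stochastic stage (synthesis,
#' permutation tests) derives its stream from it, so a config determines its
#' outputs byte-for-byte.
#'
#' @param path YAML/JSON config file; `NULL` returns the defaults (with no
#'   seed, which [run_pipeline()] will reject).
#' @param overrides named list applied over the file (e.g.
#'   `list(seed = 7)`).
#' @return a `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("read_run_config(): no such file: ", path, call. = FALSE)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  structure(cfg, class = "run_config")
}

#' Print a full configuration (all defaults made explicit)
#' @param x a `run_config`.
#' @param ... unused.
#' @export
print.run_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

require_seed <- function(config) {
  if (is.null(config$seed)) stop("config error: seed is mandatory", call. = FALSE)
  as.integer(config$seed)
}

#' Generate a full synthetic dataset with ground truth
#'
#' Writes the tree name table, the landrace occurrence table, the centroid
#' covariate grid, both truth partitions and a JSON manifest recording the
#' seed and every generator parameter.
#'
#' @param config a `run_config`; `config$simulate` holds
#'   [synthetic_config()] arguments.
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return invisibly, a named list of the files written.
#' @export
cmd_simulate <- function(config, out_dir = config$out_dir) {
  seed <- require_seed(config)
  scfg <- do.call(synthetic_config, c(config$simulate, list(seed = seed)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trees <- simulate_tree_nomenclature(scfg)
  rice <- simulate_rice_varieties(scfg)
  grid <- simulate_covariate_grid(scfg, trees$truth)

  paths <- list(
    trees = file.path(out_dir, "trees.csv"),
    rice = file.path(out_dir, "rice_occurrence.csv"),
    centroids = file.path(out_dir, "centroids.csv"),
    truth_trees = file.path(out_dir, "truth_trees.csv"),
    truth_rice = file.path(out_dir, "truth_rice.csv"),
    planted_indicators = file.path(out_dir, "planted_indicators.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_name_table(trees$table, paths$trees)
  write_occurrence(rice$occurrence, paths$rice)
  utils::write.csv(as.data.frame(unclass(grid)), paths$centroids,
                   row.names = FALSE, fileEncoding = "UTF-8")
  write_partitions(list(trees$truth), paths$truth_trees)
  write_partitions(list(rice$truth), paths$truth_rice)
  utils::write.csv(data.frame(name = rice$planted_indicators),
                   paths$planted_indicators, row.names = FALSE)
  jsonlite::write_json(unclass(scfg), paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  message("cmd_simulate: wrote ", length(paths), " file(s) to ", out_dir)
  invisible(paths)
}

#' Cluster a name table into isogloss partitions
#'
#' Reads the input, computes the chosen dissimilarity (flora-corrected
#' shared-name index on a multi-species table, or Jaccard on an occurrence
#' table), runs Ward clustering, prunes at every requested K and writes the
#' partitions (CSV) and the dendrogram (Newick).
#'
#' @param config a `run_config`; `config$cluster` fields: `input` (CSV path),
#'   `distance` (`"shared-name"` or `"jaccard"`), `ward` (`"ward.D2"` or
#'   `"ward.D"`), `K` (integer vector), `min_species`, `strict`.
#' @param out_dir output directory; defaults to `config$out_dir`.
#' @return invisibly, list with the partitions, the dendrogram and the file
#'   paths.
#' @export
cmd_cluster <- function(config, out_dir = config$out_dir) {
  cc <- config$cluster
  if (is.null(cc$input)) stop("config error: cluster.input is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  distance <- match.arg(cc$distance, c("shared-name", "jaccard"))

  if (distance == "shared-name") {
    tab <- read_name_table(cc$input)
    if (all(tab$species == SINGLE_TAXON)) {
      stop("cmd_cluster(): input is a single-taxon (landrace) table; the ",
           "shared-name index needs species identities — use distance: jaccard",
           call. = FALSE)
    }
    tab <- filter_scarce_units(tab, min_species = cc$min_species %||% 5L)
    message("cmd_cluster: ", length(tab$units), " units, ",
            length(tab$species), " species, ",
            length(unique(tab$records$name)), " names")
    d <- shared_name_matrix(tab, strict = isTRUE(cc$strict))
  } else {
    first <- names(utils::read.csv(cc$input, nrows = 1, check.names = FALSE))
    occ <- if (identical(first[1:3], c("unit_id", "species_id", "name"))) {
      to_occurrence(read_name_table(cc$input))
    } else {
      read_occurrence(cc$input)
    }
    message("cmd_cluster: ", nrow(occ), " units, ", ncol(occ), " names")
    d <- jaccard_matrix(occ)
  }
  n_undef <- sum(!d$defined[upper.tri(d$defined)])
  message("cmd_cluster: ", n_undef, " undefined pair(s)")
  dend <- ward_cluster(d, method = cc$ward %||% "ward.D2")
  Ks <- as.integer(cc$K %||% 2:5)
  parts <- cut_range(dend, Ks)

  paths <- list(partitions = file.path(out_dir, "partitions.csv"),
                dendrogram = file.path(out_dir, "dendrogram.nwk"))
  write_partitions(parts, paths$partitions)
  write_newick(dend, paths$dendrogram)
  invisible(list(partitions = parts, dendrogram = dend, paths = paths))
}

#' Indicator-name analysis of an occurrence table against a partition
#'
#' @param config a `run_config`; `config$indval` fields: `occurrence` (CSV
#'   path), `partition` (partition CSV from [cmd_cluster()]), `K` (which
#'   depth to use), `n_perm`, `alpha`. Multi-species name tables are refused
#'   unless `force_multi_species` is set, because flora differences between
#'   units confound name-level indicators.
#' @param out_dir output directory; defaults to `config$out_dir`.
#' @return invisibly, list with the full result table, the significant
#'   indicators and the file path.
#' @export
cmd_indval <- function(config, out_dir = config$out_dir) {
  ic <- config$indval
  seed <- require_seed(config)
  if (is.null(ic$occurrence) || is.null(ic$partition)) {
    stop("config error: indval.occurrence and indval.partition are required",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  first <- names(utils::read.csv(ic$occurrence, nrows = 1, check.names = FALSE))
  if (identical(first[1:3], c("unit_id", "species_id", "name"))) {
    tab <- read_name_table(ic$occurrence)
    if (!all(tab$species == SINGLE_TAXON) && !isTRUE(ic$force_multi_species)) {
      stop("cmd_indval(): multi-species table; name indicators would be ",
           "confounded by flora differences (set indval.force_multi_species ",
           "to override)", call. = FALSE)
    }
    occ <- to_occurrence(tab)
  } else {
    occ <- read_occurrence(ic$occurrence)
  }
  pdf_ <- utils::read.csv(ic$partition, colClasses = c(unit_id = "character"))
  K <- ic$K %||% min(pdf_$K)
  pdf_ <- pdf_[pdf_$K == K, , drop = FALSE]
  if (nrow(pdf_) == 0L) stop("cmd_indval(): no partition rows at K = ", K, call. = FALSE)
  if (!setequal(pdf_$unit_id, rownames(occ))) {
    stop("cmd_indval(): unit rosters of occurrence table and partition differ",
         call. = FALSE)
  }
  part <- stats::setNames(pdf_$group, pdf_$unit_id)
  res <- indval_test(occ, part, n_perm = ic$n_perm %||% 999L, seed = seed,
                     alpha = ic$alpha %||% 0.05)
  sig <- indicators(res, alpha = ic$alpha %||% 0.05)
  message("cmd_indval: ", nrow(sig), " significant indicator(s) of ",
          nrow(res), " names at alpha = ", ic$alpha %||% 0.05,
          " (per group: ",
          paste(vapply(sort(unique(sig$best_group)),
                       function(g) sum(sig$best_group == g), integer(1)),
                collapse = ", "), ")")
  path <- file.path(out_dir, "indicators.csv")
  utils::write.csv(res, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(list(results = res, significant = sig, path = path))
}

#' Batch spatial association of partition maps with centroid layers
#'
#' Samples every requested partition onto the centroid roster (via the
#' grid's `unit` column), then runs [batch_association()] against the
#' declared categorical and numeric layers and writes one combined report
#' (V-measure rows carry `v`, `h`, `c`; factor-detector rows carry `q`, `p`;
#' every row records its pairwise-complete N).
#'
#' @param config a `run_config`; `config$associate` fields: `centroids`
#'   (CSV path), `layers` (named vector, layer -> kind), `partition`
#'   (partition CSV), `K` (integer vector of depths), `n_perm`.
#' @param out_dir output directory; defaults to `config$out_dir`.
#' @return invisibly, list with the report data.frame and the file path.
#' @export
cmd_associate <- function(config, out_dir = config$out_dir) {
  ac <- config$associate
  seed <- require_seed(config)
  if (is.null(ac$centroids) || is.null(ac$layers)) {
    stop("config error: associate.centroids and associate.layers are required",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- unlist(ac$layers)
  layers <- load_centroid_layers(ac$centroids,
                                 layer_spec = c(unit = "categorical", spec))

  partitions <- list()
  if (!is.null(ac$partition)) {
    pdf_ <- utils::read.csv(ac$partition, colClasses = c(unit_id = "character"))
    for (K in (ac$K %||% sort(unique(pdf_$K)))) {
      sub <- pdf_[pdf_$K == K, , drop = FALSE]
      if (nrow(sub) == 0L) stop("cmd_associate(): no partition rows at K = ", K,
                                call. = FALSE)
      lut <- stats::setNames(paste0("g", sub$group), sub$unit_id)
      partitions[[paste0("K", K)]] <- unname(lut[layers$unit])
    }
  } else {
    stop("config error: associate.partition is required", call. = FALSE)
  }
  thematic <- lapply(names(spec)[spec == "categorical"], function(ly) layers[[ly]])
  names(thematic) <- names(spec)[spec == "categorical"]
  covariates <- lapply(names(spec)[spec == "numeric"], function(ly) layers[[ly]])
  names(covariates) <- names(spec)[spec == "numeric"]

  report <- batch_association(partitions, thematic, covariates,
                              n_perm = ac$n_perm %||% 999L, seed = seed)
  path <- file.path(out_dir, "association.csv")
  utils::write.csv(report, path, row.names = FALSE, fileEncoding = "UTF-8")
  message("cmd_associate: ", nrow(report), " report row(s)")
  invisible(list(report = report, path = path))
}

#' Run the full pipeline: simulate, cluster, indval, associate
#'
#' Convenience driver over the staged commands, wiring each stage's outputs
#' into the next: the synthetic tree table is clustered with the shared-name
#' index, the landrace table with the Jaccard distance, indicator analysis
#' runs on the landrace partition at the planted depth, and the association
#' stage compares the tree partitions with the synthetic covariate grid.
#'
#' @param config a `run_config` (a seed is mandatory).
#' @param out_dir output directory; defaults to `config$out_dir`.
#' @return invisibly, named list of the per-stage results.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  seed <- require_seed(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cmd_simulate(config, out_dir)

  tree_cfg <- config
  tree_cfg$cluster$input <- sim$trees
  tree_cfg$cluster$distance <- "shared-name"
  tree_dir <- file.path(out_dir, "trees")
  trees <- cmd_cluster(tree_cfg, tree_dir)

  rice_cfg <- config
  rice_cfg$cluster$input <- sim$rice
  rice_cfg$cluster$distance <- "jaccard"
  rice_dir <- file.path(out_dir, "rice")
  rice <- cmd_cluster(rice_cfg, rice_dir)

  k_rice <- config$indval$K %||%
    (do.call(synthetic_config,
             c(config$simulate, list(seed = seed))))$n_groups_rice
  iv_cfg <- config
  iv_cfg$indval$occurrence <- sim$rice
  iv_cfg$indval$partition <- rice$paths$partitions
  iv_cfg$indval$K <- k_rice
  iv <- cmd_indval(iv_cfg, rice_dir)

  as_cfg <- config
  as_cfg$associate$centroids <- sim$centroids
  as_cfg$associate$layers <- as_cfg$associate$layers %||%
    c(truth = "categorical", degraded = "categorical", gradient = "numeric")
  as_cfg$associate$partition <- trees$paths$partitions
  assoc <- cmd_associate(as_cfg, tree_dir)

  invisible(list(simulate = sim, trees = trees, rice = rice,
                 indval = iv, associate = assoc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
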