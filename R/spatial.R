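# Centroid layer handling, V-measure and factor-detector q-statistic.

#' Load centroid layers from CSV
#'
#' The file must hold one row per centroid with columns `centroid_id`, `x`,
#' `y` and one column per layer. `layer_spec` declares each layer's kind;
#' numeric layers are parsed strictly (a non-numeric, non-missing cell is an
#' error naming the row), categorical layers are kept as character. Missing
#' cells (empty or NA) are preserved as missing.
#'
#' @param source CSV path or connection.
#' @param layer_spec named character vector, layer name -> `"categorical"` or
#'   `"numeric"`.
#' @return a `centroid_layers` object: data.frame of `centroid_id`, `x`, `y`
#'   plus typed layer columns, with the spec attached as attribute `"kinds"`.
#' @export
load_centroid_layers <- function(source, layer_spec) {
  stopifnot(length(layer_spec) > 0L, !is.null(names(layer_spec)),
            all(layer_spec %in% c("categorical", "numeric")))
  df <- utils::read.csv(source, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  for (col in c("centroid_id", "x", "y", names(layer_spec))) {
    if (!col %in% names(df)) {
      stop("load_centroid_layers(): missing column ", col, call. = FALSE)
    }
  }
  if (anyDuplicated(df$centroid_id)) {
    stop("load_centroid_layers(): duplicate centroid_id values", call. = FALSE)
  }
  out <- data.frame(centroid_id = df$centroid_id,
                    x = as.numeric(df$x), y = as.numeric(df$y),
                    stringsAsFactors = FALSE)
  if (anyNA(out$x) || anyNA(out$y) || any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    stop("load_centroid_layers(): non-finite coordinates", call. = FALSE)
  }
  for (ly in names(layer_spec)) {
    raw <- df[[ly]]
    raw[!is.na(raw) & !nzchar(trimws(raw))] <- NA
    if (layer_spec[[ly]] == "numeric") {
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !is.na(raw))
      if (length(bad) > 0L) {
        stop("load_centroid_layers(): layer '", ly, "' declared numeric but row ",
             bad[1], " holds '", raw[bad[1]], "'", call. = FALSE)
      }
      out[[ly]] <- val
    } else {
      out[[ly]] <- raw
    }
    n_miss <- sum(is.na(out[[ly]]))
    if (n_miss > 0L) message("load_centroid_layers: layer '", ly, "': ",
                             n_miss, " missing cell(s)")
  }
  structure(out, kinds = layer_spec, class = c("centroid_layers", "data.frame"))
}

#' Construct a centroid layer set in code
#' @param centroid_id,x,y identifier and planar coordinates.
#' @param layers named list of layer vectors (character = categorical,
#'   numeric = numeric).
#' @export
centroid_layers <- function(centroid_id, x, y, layers = list()) {
  out <- data.frame(centroid_id = as.character(centroid_id), x = x, y = y,
                    stringsAsFactors = FALSE)
  kinds <- character(0)
  for (ly in names(layers)) {
    out[[ly]] <- layers[[ly]]
    kinds[ly] <- if (is.numeric(layers[[ly]])) "numeric" else "categorical"
  }
  structure(out, kinds = kinds, class = c("centroid_layers", "data.frame"))
}

# even-odd ray casting for one ring; pts is n x 2, ring is m x 2 (internal)
ray_cast <- function(pts, ring) {
  n <- nrow(pts)
  inside <- rep(FALSE, n)
  m <- nrow(ring)
  j <- m
  for (i in seq_len(m)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  inside
}

point_in_polygon <- function(pts, coords) {
  # coords: GeoJSON polygon coordinates (list of rings, first = outer)
  inside <- rep(FALSE, nrow(pts))
  for (ring in coords) {
    ring_m <- do.call(rbind, lapply(ring, function(p) as.numeric(p[1:2])))
    inside <- xor(inside, ray_cast(pts, ring_m))   # even-odd: holes flip
  }
  inside
}

#' Label centroids by the polygon containing them
#'
#' Reads a GeoJSON FeatureCollection of (Multi)Polygons and assigns each
#' centroid the label of the first feature (in file order) containing it,
#' using even-odd ray casting; points inside a hole are not contained.
#' Centroids outside every polygon get a missing label.
#'
#' @param points a `centroid_layers` object (coordinates `x`, `y`).
#' @param geojson path to a GeoJSON FeatureCollection.
#' @param label_property name of the feature property holding the label.
#' @return character vector of labels (NA where uncontained), aligned with
#'   `points`.
#' @export
assign_points_to_polygons <- function(points, geojson, label_property = "label") {
  gj <- jsonlite::fromJSON(geojson, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("assign_points_to_polygons(): expected a GeoJSON FeatureCollection",
         call. = FALSE)
  }
  pts <- cbind(points$x, points$y)
  labels <- rep(NA_character_, nrow(pts))
  unassigned <- rep(TRUE, nrow(pts))
  for (feat in gj$features) {
    geom <- feat$geometry
    if (is.null(geom$type) || is.null(geom$coordinates)) {
      stop("assign_points_to_polygons(): feature without valid geometry", call. = FALSE)
    }
    lab <- feat$properties[[label_property]]
    if (is.null(lab)) {
      stop("assign_points_to_polygons(): feature lacks property '",
           label_property, "'", call. = FALSE)
    }
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("assign_points_to_polygons(): unsupported geometry type ",
           geom$type, call. = FALSE))
    if (!any(unassigned)) break
    hit <- rep(FALSE, nrow(pts))
    for (coords in polys) hit <- hit | point_in_polygon(pts, coords)
    take <- hit & unassigned
    labels[take] <- as.character(lab)
    unassigned[take] <- FALSE
  }
  labels
}

#' Cross-tabulate two categorical layers over pairwise-complete centroids
#'
#' Centroids missing in either layer are dropped from this pair only
#' (pairwise-complete deletion); different layer pairs may therefore use
#' different centroid counts.
#'
#' @param layerA,layerB vectors of class labels over the same centroid roster.
#' @return a `contingency_table`: counts matrix (classes of A x classes of B)
#'   with attribute `N`.
#' @export
contingency <- function(layerA, layerB) {
  if (length(layerA) != length(layerB)) {
    stop("contingency(): layers must share the centroid roster", call. = FALSE)
  }
  keep <- !is.na(layerA) & !is.na(layerB)
  if (sum(keep) == 0L) {
    stop("contingency(): no pairwise-complete centroids", call. = FALSE)
  }
  tab <- table(A = as.character(layerA[keep]), B = as.character(layerB[keep]))
  tab <- unclass(tab)
  structure(tab, N = sum(tab), class = c("contingency_table", "matrix", "array"))
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' V-measure, homogeneity and completeness of a contingency table
#'
#' Entropy-based comparison of two categorical partitions of the same
#' centroids. With rows read as classes C and columns as clusters K:
#' homogeneity \eqn{h = 1 - H(C|K)/H(C)} (each cluster contains members of a
#' single class), completeness \eqn{c = 1 - H(K|C)/H(K)} (each class falls in
#' a single cluster), and the V-measure is their harmonic mean
#' \eqn{v = 2hc/(h+c)} (\eqn{\beta = 1}). Degenerate marginals score 1:
#' `h = 1` when `H(C) = 0` and `c = 1` when `H(K) = 0`. Entropies use the
#' natural log; h, c and v are base-invariant ratios. All three lie in
#' [0, 1]; swapping the layers swaps h and c and leaves v unchanged.
#'
#' @param tab a `contingency_table` (or plain counts matrix).
#' @return list with `h`, `c`, `v`, `N`.
#' @export
v_measure <- function(tab) {
  tab <- unclass(tab)
  stopifnot(is.matrix(tab), all(tab >= 0))
  N <- sum(tab)
  if (N < 1) stop("v_measure(): empty contingency table", call. = FALSE)
  pC <- rowSums(tab) / N
  pK <- colSums(tab) / N
  HC <- entropy_nat(pC)
  HK <- entropy_nat(pK)
  # conditional entropies from the joint distribution
  pj <- tab / N
  HC_given_K <- -sum(pj[pj > 0] * log(sweep(tab, 2, colSums(tab), "/")[pj > 0]))
  HK_given_C <- -sum(pj[pj > 0] * log(sweep(tab, 1, rowSums(tab), "/")[pj > 0]))
  h <- if (HC == 0) 1 else 1 - HC_given_K / HC
  c_ <- if (HK == 0) 1 else 1 - HK_given_C / HK
  v <- if (h + c_ > 0) 2 * h * c_ / (h + c_) else 0
  list(h = h, c = c_, v = v, N = N)
}

#' Discretize a numeric layer into strata
#'
#' @param x numeric vector (missing values propagate to missing bins).
#' @param n_bins number of bins (>= 2); ignored when `breaks` is given.
#' @param method `"quantile"` (default; bins of near-equal occupancy) or
#'   `"interval"` (equal-width bins).
#' @param breaks optional user breakpoints (inner breakpoints or full
#'   boundary vector); overrides `method`.
#' @return factor of bin labels, with the breakpoints used attached as
#'   attribute `"breaks"`.
#' @export
discretize <- function(x, n_bins = 4L, method = c("quantile", "interval"),
                       breaks = NULL) {
  method <- match.arg(method)
  obs <- x[!is.na(x)]
  if (is.null(breaks)) {
    if (n_bins < 2L) stop("discretize(): n_bins must be >= 2", call. = FALSE)
    if (length(unique(obs)) < n_bins) {
      stop("discretize(): fewer distinct values (", length(unique(obs)),
           ") than bins (", n_bins, ")", call. = FALSE)
    }
    br <- if (method == "quantile") {
      unname(stats::quantile(obs, probs = seq(0, 1, length.out = n_bins + 1)))
    } else {
      seq(min(obs), max(obs), length.out = n_bins + 1)
    }
    if (anyDuplicated(br)) {
      stop("discretize(): degenerate binning — duplicated breakpoints", call. = FALSE)
    }
  } else {
    br <- sort(unique(breaks))
    if (min(obs) < min(br)) br <- c(min(obs), br)
    if (max(obs) > max(br)) br <- c(br, max(obs))
  }
  f <- cut(x, breaks = br, include.lowest = TRUE)
  message("discretize: breakpoints ", paste(signif(br, 6), collapse = ", "))
  attr(f, "breaks") <- br
  f
}

#' Factor-detector q-statistic of spatial stratified heterogeneity
#'
#' Measures how much of a numeric layer's variance a categorical
#' stratification explains: \eqn{q = 1 - \sum_h N_h \sigma_h^2 / (N \sigma^2)}
#' with population variances, equivalently \eqn{1 - SSW/SST} from a one-way
#' decomposition. q ranges from 0 (strata explain nothing) to 1 (the layer is
#' constant within every stratum). Missing cells in either input are dropped
#' pairwise. Significance is assessed either by permuting stratum labels
#' (plus-one-corrected p, seeded) or by the noncentral-F transform
#' \eqn{F = \frac{N - L}{L - 1}\,\frac{q}{1 - q}} with noncentrality
#' \eqn{\lambda = \frac{1}{\sigma^2}\left[\sum_h \bar y_h^2 N_h -
#' \frac{1}{N}\left(\sum_h \sqrt{N_h}\,\bar y_h\right)^2\right]}.
#'
#' @param y numeric response layer.
#' @param strata categorical explanatory layer over the same centroids.
#' @param significance `"permutation"` (default) or `"ncf"` (noncentral F).
#' @param n_perm permutations for the permutation route.
#' @param seed integer seed, required for the permutation route.
#' @return a `factor_detector` list: `q`, `p_value`, `method`, `L`, `N`,
#'   `sigma2` (global population variance) and a per-stratum `strata`
#'   data.frame (`stratum`, `N_h`, `mean`, `var_h`).
#' @export
factor_detector_q <- function(y, strata,
                              significance = c("permutation", "ncf"),
                              n_perm = 999L, seed = NULL) {
  significance <- match.arg(significance)
  if (length(y) != length(strata)) {
    stop("factor_detector_q(): layers must share the centroid roster", call. = FALSE)
  }
  keep <- !is.na(y) & !is.na(strata)
  y <- y[keep]; strata <- droplevels(factor(strata[keep]))
  N <- length(y)
  L <- nlevels(strata)
  if (L < 1L || N < L + 1L) {
    stop("factor_detector_q(): need pairwise-complete N >= L + 1", call. = FALSE)
  }
  pop_var <- function(v) mean((v - mean(v))^2)
  sigma2 <- pop_var(y)
  if (sigma2 == 0) {
    stop("factor_detector_q(): response is constant — q undefined", call. = FALSE)
  }
  q_of <- function(g) {
    ssw <- sum(vapply(split(y, g), function(v) length(v) * pop_var(v), numeric(1)))
    1 - ssw / (N * sigma2)
  }
  q <- q_of(strata)
  strata_summary <- do.call(rbind, lapply(levels(strata), function(h) {
    v <- y[strata == h]
    data.frame(stratum = h, N_h = length(v), mean = mean(v), var_h = pop_var(v),
               stringsAsFactors = FALSE)
  }))
  if (significance == "permutation") {
    if (is.null(seed)) stop("factor_detector_q(): seed required for permutation test",
                            call. = FALSE)
    set.seed(as.integer(seed))
    ge <- 0L
    for (b in seq_len(n_perm)) {
      if (q_of(sample(strata)) >= q - 1e-12) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + n_perm)
  } else {
    ybar_h <- strata_summary$mean; N_h <- strata_summary$N_h
    Fval <- (N - L) / (L - 1) * q / (1 - q)
    lambda <- (sum(ybar_h^2 * N_h) - (sum(sqrt(N_h) * ybar_h))^2 / N) / sigma2
    p <- stats::pf(Fval, L - 1, N - L, ncp = lambda, lower.tail = FALSE)
  }
  structure(list(q = q, p_value = p, method = significance, L = L, N = N,
                 sigma2 = sigma2, strata = strata_summary),
            class = "factor_detector")
}

#' @export
print.factor_detector <- function(x, ...) {
  cat("Factor detector: q = ", signif(x$q, 4), ", p = ", signif(x$p_value, 4),
      " (", x$method, "), L = ", x$L, ", N = ", x$N, "\n", sep = "")
  invisible(x)
}

#' Batch spatial association of isogloss partitions with thematic layers
#'
#' For each (partition layer, categorical layer) pair computes homogeneity,
#' completeness and V-measure, with the nomenclature partition as the classes
#' C and the thematic layer as the clusters K — so high homogeneity reads as
#' "the nomenclature is uniform within each thematic polygon" and low
#' completeness as "one nomenclature group spans several polygons". For each
#' (partition layer, numeric layer) pair it computes the factor-detector q
#' with the partition as strata. Deletion is pairwise-complete per pair, so N
#' can differ between rows.
#'
#' @param partitions named list of categorical vectors sampled at centroids
#'   (e.g. the planted or fitted partitions at several K).
#' @param thematic named list of categorical layer vectors.
#' @param covariates named list of numeric layer vectors.
#' @param n_perm,seed permutation settings for q significance; `seed` is
#'   incremented per covariate row so rows are independent but reproducible.
#' @return data.frame with one row per pair: `partition`, `layer`, `kind`,
#'   `v`, `h`, `c`, `q`, `p`, `N`.
#' @export
batch_association <- function(partitions, thematic = list(), covariates = list(),
                              n_perm = 999L, seed = 1L) {
  stopifnot(length(partitions) > 0L)
  rows <- list()
  for (pn in names(partitions)) {
    part <- partitions[[pn]]
    for (tn in names(thematic)) {
      tab <- contingency(part, thematic[[tn]])     # classes C x clusters K
      vm <- v_measure(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        partition = pn, layer = tn, kind = "categorical",
        v = vm$v, h = vm$h, c = vm$c, q = NA_real_, p = NA_real_, N = vm$N,
        stringsAsFactors = FALSE)
    }
    for (cn in names(covariates)) {
      fd <- factor_detector_q(covariates[[cn]], part, n_perm = n_perm,
                              seed = seed + length(rows))
      rows[[length(rows) + 1L]] <- data.frame(
        partition = pn, layer = cn, kind = "numeric",
        v = NA_real_, h = NA_real_, c = NA_real_, q = fd$q, p = fd$p_value,
        N = fd$N, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
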