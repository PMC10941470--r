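# Independent oracles and random-fixture generators used across the suite.
# Each oracle recomputes a quantity by a route the implementation does not
# share: brute-force loops, set algebra, ANOVA sums of squares, reference
# library calls.

# --- random fixtures ---------------------------------------------------------

random_folk_table <- function(n_units = 8, n_species = 20, n_names = 6,
                              p_record = 0.3, max_names = 2) {
  recs <- list()
  for (u in seq_len(n_units)) {
    for (s in seq_len(n_species)) {
      if (runif(1) < p_record) {
        k <- sample(max_names, 1)
        nm <- sample(paste0("n", seq_len(n_names)), k)
        recs[[length(recs) + 1L]] <- data.frame(
          unit_id = paste0("u", u), species_id = paste0("s", s), name = nm)
      }
    }
  }
  df <- do.call(rbind, recs)
  folk_table(df$unit_id, df$species_id, df$name, normalize = FALSE)
}

random_occurrence <- function(n_units = 14, n_names = 50, p = 0.4) {
  m <- matrix(rbinom(n_units * n_names, 1, p), n_units, n_names,
              dimnames = list(paste0("u", seq_len(n_units)),
                              paste0("n", seq_len(n_names))))
  keep <- colSums(m) > 0
  m[cbind(sample(n_units, sum(!keep), replace = TRUE), which(!keep))] <- 1L
  occurrence_table(m)
}

# --- dissimilarity oracles ---------------------------------------------------

# D = 1 - a/A by an explicit double loop over species and name sets
brute_D <- function(table, u1, u2) {
  rec <- table$records
  sp1 <- unique(rec$species_id[rec$unit_id == u1])
  sp2 <- unique(rec$species_id[rec$unit_id == u2])
  common <- intersect(sp1, sp2)
  if (length(common) == 0) return(list(D = NA_real_, a = 0, A = 0))
  a <- 0
  for (s in common) {
    n1 <- rec$name[rec$unit_id == u1 & rec$species_id == s]
    n2 <- rec$name[rec$unit_id == u2 & rec$species_id == s]
    if (any(n1 %in% n2)) a <- a + 1
  }
  list(D = 1 - a / length(common), a = a, A = length(common))
}

brute_jaccard_matrix <- function(occ) {
  m <- unclass(occ)
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    X <- colnames(m)[m[i, ] == 1]; Y <- colnames(m)[m[j, ] == 1]
    out[i, j] <- 1 - length(intersect(X, Y)) / length(union(X, Y))
  }
  out
}

# --- V-measure oracle: mutual-information route ------------------------------

oracle_vmeasure <- function(C, K) {
  keep <- !is.na(C) & !is.na(K)
  C <- as.character(C[keep]); K <- as.character(K[keep])
  N <- length(C)
  H <- function(labels) {
    p <- table(labels) / length(labels)
    -sum(p * log(p))
  }
  joint <- table(C, K) / N
  MI <- 0
  pc <- rowSums(joint); pk <- colSums(joint)
  for (i in seq_len(nrow(joint))) for (j in seq_len(ncol(joint))) {
    if (joint[i, j] > 0) MI <- MI + joint[i, j] * log(joint[i, j] / (pc[i] * pk[j]))
  }
  HC <- H(C); HK <- H(K)
  h <- if (HC == 0) 1 else unname(MI / HC)
  c_ <- if (HK == 0) 1 else unname(MI / HK)
  v <- if (h + c_ > 0) 2 * h * c_ / (h + c_) else 0
  list(h = h, c = c_, v = v)
}

# scikit-learn reference, one python call for a whole batch of label pairs
sklearn_vmeasure <- function(pairs) {
  infile <- tempfile(fileext = ".csv")
  outfile <- tempfile(fileext = ".csv")
  rows <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    data.frame(pair = i, C = as.character(pairs[[i]]$C),
               K = as.character(pairs[[i]]$K))
  }))
  utils::write.csv(rows, infile, row.names = FALSE)
  script <- testthat::test_path("vmeasure_oracle.py")
  status <- system2("python", c(script, infile, outfile))
  stopifnot(status == 0)
  utils::read.csv(outfile)
}

# --- factor-detector oracle: ANOVA sum-of-squares route ----------------------

oracle_q <- function(y, strata) {
  keep <- !is.na(y) & !is.na(strata)
  y <- y[keep]; strata <- factor(strata[keep])
  sst <- sum((y - mean(y))^2)
  ssw <- sum(unlist(lapply(split(y, strata), function(v) sum((v - mean(v))^2))))
  1 - ssw / sst
}

# --- IndVal oracle: per-name, per-group loops --------------------------------

brute_indval <- function(occ, grp) {
  m <- unclass(occ)
  grp <- as.integer(factor(grp))
  L <- max(grp)
  res <- list()
  for (nm in colnames(m)) {
    r <- numeric(L)
    for (g in seq_len(L)) r[g] <- mean(m[grp == g, nm])
    A <- r / sum(r)
    stat <- sqrt(A * r)
    res[[nm]] <- list(A = A, B = r, stat = stat,
                      best = which.max(stat), best_stat = max(stat))
  }
  res
}
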