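test_that("shared-name distance follows the printed formula on a hand case", {
  # s1 named {a},{a}; s2 named {b},{c}; s3 surveyed only in u1
  tab <- folk_table(c("u1", "u1", "u1", "u2", "u2"),
                    c("s1", "s2", "s3", "s1", "s2"),
                    c("a", "b", "x", "a", "c"))
  r <- shared_name_distance(tab, "u1", "u2")
  expect_equal(r$A, 2L)
  expect_equal(r$a, 1L)
  expect_equal(r$D, 0.5)

  # identity: every commonly surveyed species shares all its names
  expect_equal(shared_name_distance(tab, "u1", "u1")$D, 0)
  expect_error(shared_name_distance(tab, "u1", "zz"), "unknown unit")
})

test_that("pairs with no commonly surveyed species are undefined, not imputed", {
  tab <- folk_table(c("u1", "u2"), c("s1", "s2"), c("a", "b"))
  r <- shared_name_distance(tab, "u1", "u2")
  expect_false(r$defined)
  expect_true(is.na(r$D))

  expect_error(shared_name_matrix(tab, strict = TRUE), "commonly\\s+surveyed")
  m <- suppressMessages(shared_name_matrix(tab, strict = FALSE))
  expect_false(m$defined["u1", "u2"])
  expect_true(is.na(m$values["u1", "u2"]))
  expect_error(ward_cluster(m), "undefined")
})

test_that("shared-name matrix equals the brute-force double loop exactly", {
  set.seed(21)
  for (i in 1:10) {
    tab <- random_folk_table(n_units = 8, n_species = 20)
    m <- suppressMessages(shared_name_matrix(tab))
    for (pair in list(c(1, 2), c(3, 7), c(2, 8), c(4, 5))) {
      u1 <- tab$units[pair[1]]; u2 <- tab$units[pair[2]]
      oracle <- brute_D(tab, u1, u2)
      fast <- shared_name_distance(tab, u1, u2)
      expect_identical(fast$a, as.integer(oracle$a))
      expect_identical(fast$A, as.integer(oracle$A))
      if (is.na(oracle$D)) {
        expect_false(m$defined[u1, u2])
      } else {
        expect_equal(m$values[u1, u2], oracle$D)
        expect_equal(fast$D, oracle$D)
      }
    }
    # full-matrix consistency with the per-pair routine
    defined <- m$defined; vals <- m$values
    expect_true(isSymmetric(vals) || all(vals[defined] == t(vals)[t(defined)]))
    expect_equal(unname(diag(vals)), rep(0, length(tab$units)))
    expect_true(all(vals[defined] >= 0 & vals[defined] <= 1))
  }
})

test_that("two identical units are at distance zero everywhere", {
  tab <- folk_table(c("u1", "u1", "u2", "u2"), c("s1", "s2", "s1", "s2"),
                    c("a", "b", "a", "b"))
  m <- shared_name_matrix(tab)
  expect_equal(m$values["u1", "u2"], 0)
})

test_that("D responds correctly to appending species", {
  set.seed(31)
  for (i in 1:20) {
    tab <- random_folk_table(n_units = 4, n_species = 10)
    u1 <- tab$units[1]; u2 <- tab$units[2]
    base <- shared_name_distance(tab, u1, u2)
    if (!base$defined) next
    rec <- tab$records
    # appending a commonly surveyed species with a shared name never increases D
    shared_rec <- data.frame(unit_id = c(u1, u2), species_id = "sNEW",
                             name = "shared-name")
    t_shared <- folk_table(c(rec$unit_id, shared_rec$unit_id),
                           c(rec$species_id, shared_rec$species_id),
                           c(rec$name, shared_rec$name), normalize = FALSE)
    expect_lte(shared_name_distance(t_shared, u1, u2)$D, base$D + 1e-12)
    # appending a commonly surveyed species with disjoint names never decreases D
    disj_rec <- data.frame(unit_id = c(u1, u2), species_id = "sNEW",
                           name = c("only-1", "only-2"))
    t_disj <- folk_table(c(rec$unit_id, disj_rec$unit_id),
                         c(rec$species_id, disj_rec$species_id),
                         c(rec$name, disj_rec$name), normalize = FALSE)
    expect_gte(shared_name_distance(t_disj, u1, u2)$D, base$D - 1e-12)
  }
})

test_that("jaccard distance matches its set-algebra definition", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a"), c("b")), 1)
  expect_equal(jaccard_distance(c("a", "b"), c("a", "c")), 2 / 3)
  expect_error(jaccard_distance(character(0), character(0)), "both sets empty")
})

test_that("jaccard matrix equals brute-force set algebra and vegan", {
  set.seed(41)
  for (i in 1:5) {
    occ <- random_occurrence(n_units = 14, n_names = 40)
    m <- jaccard_matrix(occ)
    expect_equal(m$values, brute_jaccard_matrix(occ), tolerance = 1e-14)
    ref <- as.matrix(vegan::vegdist(unclass(occ), method = "jaccard", binary = TRUE))
    expect_equal(unname(m$values), unname(ref), tolerance = 1e-12)
  }
})

test_that("jaccard satisfies symmetry, range and the triangle inequality", {
  set.seed(43)
  for (i in 1:50) {
    sets <- lapply(1:3, function(j) sample(letters, sample(1:10, 1)))
    d12 <- jaccard_distance(sets[[1]], sets[[2]])
    d13 <- jaccard_distance(sets[[1]], sets[[3]])
    d23 <- jaccard_distance(sets[[2]], sets[[3]])
    expect_equal(d12, jaccard_distance(sets[[2]], sets[[1]]))
    expect_true(all(c(d12, d13, d23) >= 0 & c(d12, d13, d23) <= 1))
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("adding a name shared by both units never increases their distance", {
  set.seed(47)
  for (i in 1:20) {
    occ <- random_occurrence(n_units = 5, n_names = 15)
    m0 <- jaccard_matrix(occ)$values["u1", "u2"]
    m <- unclass(occ)
    m <- cbind(m, newname = 0L)
    m[c("u1", "u2"), "newname"] <- 1L
    m1 <- jaccard_matrix(occurrence_table(m))$values["u1", "u2"]
    expect_lte(m1, m0 + 1e-12)
  }
})

test_that("jaccard matrix refuses units with empty name inventories", {
  m <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
              dimnames = list(c("u1", "u2"), c("a", "b")))
  expect_error(jaccard_matrix(occurrence_table(m)), "empty name set.*u2")
})

test_that("dissimilarity CSV export writes undefined pairs as empty cells", {
  tab <- folk_table(c("u1", "u2", "u3", "u3"), c("s1", "s2", "s1", "s2"),
                    c("a", "b", "a", "b"))
  m <- suppressMessages(shared_name_matrix(tab))
  f <- tempfile(fileext = ".csv")
  write_dissimilarity(m, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_true(is.na(back[1, "u2"]))       # u1-u2 share no surveyed species
  expect_equal(back[1, "u3"], 0)
})
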