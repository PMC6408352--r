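test_that("long tables load into tensors of the right shape and content", {
  df <- make_long_df(c(10, 5, 3), c("cell_line", "ligand", "time"))
  Z <- load_long_table(df, axes = c("cell_line", "ligand", "time"))
  expect_equal(dim(Z), c(10L, 5L, 3L))

  # entry lookup by label tuple returns the row's value (row-major fill)
  expect_equal(tensor_entry(Z, "c1", "l1", "t1"), 1)
  expect_equal(tensor_entry(Z, "c1", "l1", "t3"), 3)
  expect_equal(tensor_entry(Z, "c10", "l5", "t3"), 150)

  # full 5-axis design: one row per scalar value
  df5 <- make_long_df(c(36, 14, 2, 3, 2),
                      c("cell_line", "ligand", "dose", "time", "protein"))
  expect_equal(nrow(df5), 36 * 14 * 2 * 3 * 2)
  Z5 <- load_long_table(df5, axes = names(df5)[1:5])
  expect_equal(dim(Z5), c(36L, 14L, 2L, 3L, 2L))

  # singleton
  Z1 <- load_long_table(data.frame(a = "only", value = 7), axes = "a")
  expect_equal(dim(Z1), 1L)
  expect_equal(tensor_entry(Z1, "only"), 7)

  # reads from a file too
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(make_long_df(c(2, 3)), f, row.names = FALSE)
  expect_equal(dim(load_long_table(f, axes = c("ax1", "ax2"))), c(2L, 3L))
})

test_that("incomplete, duplicated and non-numeric tables are rejected", {
  df <- make_long_df(c(2, 3), c("a", "b"))
  expect_error(load_long_table(df[-4, ], axes = c("a", "b")),
               "incomplete tensor.*a2.*b1")
  expect_error(load_long_table(rbind(df, df[1, ]), axes = c("a", "b")),
               "duplicate combination")
  df2 <- df; df2$value[3] <- "high"
  expect_error(load_long_table(df2, axes = c("a", "b")), "row 3")
  expect_error(data_tensor(array(c(1, NA), 2), list(a = c("x", "y"))),
               "not complete")
})

test_that("flattening matches the explicit row-major definition", {
  Z <- random_tensor(c(10, 5, 3))
  M <- flatten_tensor(Z, 2)
  expect_equal(dim(M$values), c(50L, 3L))
  # row r holds Z[i1, i2, ] with i2 fastest
  for (r in c(1, 7, 23, 50)) {
    i1 <- (r - 1) %/% 5 + 1; i2 <- (r - 1) %% 5 + 1
    expect_equal(unname(M$values[r, ]), unname(Z$values[i1, i2, ]))
  }
  # element count and multiset preserved
  expect_equal(sort(as.vector(M$values)), sort(as.vector(Z$values)))

  Z5 <- random_tensor(c(36, 14, 2, 3, 2))
  expect_equal(dim(flatten_tensor(Z5, 2)$values), c(504L, 12L))

  # flattening a matrix along its first axis is the identity
  Zm <- random_tensor(c(2, 2))
  expect_equal(unname(flatten_tensor(Zm, 1)$values), unname(Zm$values))

  expect_error(flatten_tensor(Z, 3), "d must satisfy")
  expect_error(flatten_tensor(Z, 0), "d must satisfy")
})

test_that("row normalization behaves as documented", {
  Z <- data_tensor(array(c(3, 2, 4, 4), c(2, 2)),
                   list(exp = c("a", "b"), t = c("t1", "t2")))
  M <- flatten_tensor(Z, 1)
  expect_equal(unname(normalize_rows(M, "unit-l2")$values[1, ]), c(0.6, 0.8))
  expect_equal(unname(normalize_rows(M, "max1")$values[2, ]), c(0.5, 1.0))
  expect_identical(normalize_rows(M, "none"), M)
  Zz <- data_tensor(array(c(3, 2, 0, 4, 4, 0), c(3, 2)),
                    list(exp = c("a", "b", "z"), t = c("t1", "t2")))
  expect_error(normalize_rows(flatten_tensor(Zz, 1), "unit-l2"),
               "all-zero row.*z")

  # idempotence on already-unit rows
  Mu <- normalize_rows(flatten_tensor(random_tensor(c(4, 3)), 1), "unit-l2")
  expect_equal(normalize_rows(Mu, "unit-l2")$values, Mu$values)
})

test_that("cosine similarity has exact unit diagonal, symmetry and range", {
  Z <- data_tensor(array(c(1, 0, 1, 0, 1, 1), c(3, 2)),
                   list(exp = c("e1", "e2", "e3"), t = c("t1", "t2")))
  S <- cosine_similarity(flatten_tensor(Z, 1))
  expect_equal(S$values[1, 2], 0)            # orthogonal
  expect_equal(S$values[1, 3], 1 / sqrt(2))  # hand dot product
  # collinearity
  Zc <- data_tensor(array(c(1, 2, 1, 2), c(2, 2)),
                    list(exp = c("u", "v"), t = c("t1", "t2")))
  expect_equal(cosine_similarity(flatten_tensor(Zc, 1))$values[1, 2], 1)

  M <- flatten_tensor(random_tensor(c(6, 4, 3)), 2)
  V <- cosine_similarity(M)$values
  expect_lt(max(abs(V - t(V))), 1e-12)
  expect_lt(max(abs(diag(V) - 1)), 1e-12)
  expect_true(all(V >= 0 & V <= 1 + 1e-12))  # non-negative inputs
})

test_that("similarity unflattening inverts flattening exactly", {
  for (shape in list(c(10, 5, 3), c(6, 5, 4, 3), c(2, 2, 2))) {
    for (d in seq_len(length(shape) - 1L)) {
      Z <- random_tensor(shape, seed = sum(shape) + d)
      S_mat <- cosine_similarity(flatten_tensor(Z, d))
      S <- unflatten_similarity(S_mat)
      expect_equal(dim(S$values), rep(shape[seq_len(d)], 2L))
      expect_equal(flatten_similarity(S), unname(S_mat$values))
      # entry correspondence under row-major ranking, spot checks
      dims <- shape[seq_len(d)]
      n1 <- prod(dims)
      withr::with_seed(d, idx <- sample(n1, min(4L, n1)))
      for (r in idx) for (s in idx) {
        i <- recticluster:::rowmajor_unrank(r, dims)
        j <- recticluster:::rowmajor_unrank(s, dims)
        expect_equal(do.call(`[`, c(list(S$values), as.list(c(i, j)))),
                     S_mat$values[r, s])
      }
      # multi-index symmetry
      expect_equal(S$values, aperm(S$values, c((d + 1):(2 * d), 1:d)))
    }
  }
  # (N1,) unflattening is the matrix itself
  V <- cosine_similarity(flatten_tensor(random_tensor(c(4, 2)), 1))
  expect_equal(unflatten_similarity(V, 4)$values, unname(V$values))
  expect_error(unflatten_similarity(V, c(3, 2)), "prod\\(dims\\)")
})

test_that("worked similarity example dimensions hold end to end", {
  Z <- random_tensor(c(36, 14, 2, 3, 2), seed = 99)
  M <- normalize_rows(flatten_tensor(Z, 2))
  S_mat <- cosine_similarity(M)
  expect_equal(dim(S_mat$values), c(504L, 504L))
  expect_equal(dim(unflatten_similarity(S_mat)$values), c(36L, 14L, 36L, 14L))
})

test_that("heterogeneity score averages pairwise dissimilarity", {
  # identical rows -> 0; orthogonal rows -> 1
  Zi <- data_tensor(array(rep(c(1, 2), each = 3), c(3, 2)),
                    list(exp = paste0("e", 1:3), t = c("t1", "t2")))
  Si <- cosine_similarity(flatten_tensor(Zi, 1))
  expect_equal(heterogeneity_score(Si, 1:3), 0)

  Zo <- data_tensor(diag(3), list(exp = paste0("e", 1:3), t = paste0("t", 1:3)))
  So <- cosine_similarity(flatten_tensor(Zo, 1))
  expect_equal(heterogeneity_score(So, 1:3), 1)

  # pairwise similarities {1, 0.5, 0.5} -> mean(0, .5, .5) = 1/3
  V <- matrix(c(1, 1, .5, 1, 1, .5, .5, .5, 1), 3)
  Sm <- sim_matrix(V, c(3, 1))
  expect_equal(heterogeneity_score(Sm, 1:3), 1 / 3)
  # invariant to relabelling of the subset
  expect_equal(heterogeneity_score(Sm, c(3, 1, 2)),
               heterogeneity_score(Sm, 1:3))

  expect_error(heterogeneity_score(Sm, 2), "at least two")
  Vn <- V; Vn[1, 2] <- Vn[2, 1] <- -0.2
  expect_error(heterogeneity_score(sim_matrix(Vn, c(3, 1)), 1:3),
               "non-negative")
})

test_that("heterogeneity score stays in [0,1] on random non-negative data", {
  for (seed in 1:5) {
    S <- cosine_similarity(flatten_tensor(random_tensor(c(5, 4), seed), 1))
    withr::with_seed(seed, sub <- sample(5, 3))
    h <- heterogeneity_score(S, sub)
    expect_gte(h, 0); expect_lte(h, 1)
  }
})

test_that("similarity CSV round trips with joined multi-index labels", {
  S <- cosine_similarity(normalize_rows(flatten_tensor(random_tensor(c(3, 2, 2)), 2)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_similarity_csv(S, f)
  S2 <- read_similarity_csv(f, c(3, 2))
  expect_equal(S2$values, S$values, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(S2$labels, S$labels)
  expect_true(all(grepl("|", S2$labels, fixed = TRUE)))
})
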