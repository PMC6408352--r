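test_that("X encoding matches cluster membership and its constraints", {
  # single cluster: all-zero tensor
  P1 <- rect_partition(c(2, 2), list(list(rows = 1:2, cols = 1:2)))
  expect_true(all(partition_to_x(P1) == 0))

  # all singletons: ones off the pair diagonal
  Ps <- rect_partition(c(2, 2), lapply(1:4, function(i) {
    list(rows = (i - 1) %/% 2 + 1, cols = (i - 1) %% 2 + 1)
  }))
  xs <- partition_to_x(Ps)
  expect_equal(sum(xs), 12)  # 16 entries minus 4 self pairs

  # row split: 0 within rows, 1 across (8 ones), via the membership table
  Pr <- rect_partition(c(2, 2), list(list(rows = 1, cols = 1:2),
                                     list(rows = 2, cols = 1:2)))
  xr <- partition_to_x(Pr)
  M <- partition_membership(Pr)
  for (i1 in 1:2) for (i2 in 1:2) for (j1 in 1:2) for (j2 in 1:2) {
    expect_equal(xr[i1, i2, j1, j2],
                 as.numeric(M[i1, i2] != M[j1, j2]))
  }
  expect_equal(sum(xr), 8)

  # every decoder-produced X satisfies all five constraint families
  for (P in list(P1, Ps, Pr,
                 rect_partition(c(3, 3), list(list(rows = c(1, 3), cols = c(1, 3)),
                                              list(rows = 2, cols = c(1, 3)),
                                              list(rows = 1:3, cols = 2))))) {
    expect_true(isTRUE(x_constraints_ok(partition_to_x(P))))
  }
})

test_that("X decoding recovers partitions and rejects invalid tensors", {
  expect_equal(length(x_to_partition(array(0, c(2, 2, 2, 2)))$clusters), 1L)

  # round trip over all rectangular partitions of small grids
  for (P in enumerate_rectangular_partitions(3, 2)) {
    P2 <- x_to_partition(partition_to_x(P))
    expect_equal(partition_membership(P2), partition_membership(P))
  }

  # anti-diagonal pairing is an equivalence but not rectangular
  M <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  x <- array(0, c(2, 2, 2, 2))
  v <- as.vector(M)
  x[] <- 1 - outer(v, v, "==")
  expect_error(x_to_partition(x), "not rectangular")

  # transitivity violation is named
  xb <- partition_to_x(rect_partition(c(3, 1), list(list(rows = 1:3, cols = 1))))
  xb[1, 1, 3, 1] <- xb[3, 1, 1, 1] <- 1
  expect_error(x_to_partition(xb), "transitivity")
})

test_that("Y encoding is one-hot and satisfies 1 - x = sum_k y_ik y_jk", {
  P1 <- rect_partition(c(2, 2), list(list(rows = 1:2, cols = 1:2)))
  expect_true(all(partition_to_y(P1, 1) == 1))

  Pr <- rect_partition(c(2, 2), list(list(rows = 1, cols = 1:2),
                                     list(rows = 2, cols = 1:2)))
  y3 <- partition_to_y(Pr, 3)
  expect_equal(dim(y3), c(2L, 2L, 3L))
  expect_true(all(y3[, , 3] == 0))
  expect_error(partition_to_y(Pr, 1), "smaller than the cluster count")

  for (seed in 1:8) {
    P <- sample_rectangular_partition(3, 3, 1 + seed %% 4, seed = seed)
    y <- partition_to_y(P)
    expect_true(all(apply(y, c(1, 2), sum) == 1))
    x <- partition_to_x(P)
    n1 <- 3; n2 <- 3
    for (i1 in 1:n1) for (i2 in 1:n2) for (j1 in 1:n1) for (j2 in 1:n2) {
      expect_equal(sum(y[i1, i2, ] * y[j1, j2, ]), 1 - x[i1, i2, j1, j2])
    }
  }
})

test_that("assignment decoding validates outer-product slices", {
  Pr <- rect_partition(c(2, 3), list(list(rows = 1, cols = 1:3),
                                     list(rows = 2, cols = 1:3)))
  expect_equal(partition_membership(y_to_partition(partition_to_y(Pr, 4))),
               partition_membership(Pr))
  y <- array(0, c(2, 2, 1))
  y[1, 1, 1] <- y[2, 2, 1] <- 1
  expect_error(y_to_partition(y), "unique-assignment")
  y2 <- array(0, c(2, 2, 2))
  y2[1, 1, 1] <- y2[2, 2, 1] <- 1; y2[1, 2, 2] <- y2[2, 1, 2] <- 1
  expect_error(y_to_partition(y2), "not an outer-product")
})

test_that("rectangular partition counts match the exhaustive filter", {
  expect_length(enumerate_rectangular_partitions(1, 1), 1L)
  expect_length(enumerate_rectangular_partitions(2, 1), 2L)
  expect_length(enumerate_rectangular_partitions(2, 2), 8L)
  # the pruned enumerator agrees with the filter-all-set-partitions oracle
  for (shape in list(c(2, 2), c(3, 2), c(2, 3), c(4, 2))) {
    fast <- enumerate_rectangular_partitions(shape[1], shape[2])
    naive <- enumerate_rectangular_partitions_naive(shape[1], shape[2])
    expect_length(fast, length(naive))
    key <- function(P) paste(partition_membership(P), collapse = "")
    expect_setequal(vapply(fast, key, ""), vapply(naive, key, ""))
    # no duplicates, canonical labelling
    expect_false(anyDuplicated(vapply(fast, key, "")) > 0)
  }
  expect_error(enumerate_rectangular_partitions(4, 4), "limited")
})

test_that("validation reports the violated invariant", {
  # L-shaped class on a 2x2 grid
  ML <- matrix(c(1L, 1L, 1L, 2L), 2, 2)
  expect_error(membership_to_partition(ML), "not rectangular")

  # disconnected rectangles are fine
  Pd <- rect_partition(c(3, 2), list(list(rows = c(1, 3), cols = 2),
                                     list(rows = 2, cols = 2),
                                     list(rows = 1:3, cols = 1)))
  expect_true(validate_partition(Pd)$valid)

  # overlap and gap
  Pbad <- structure(list(grid_shape = c(2L, 2L),
                         clusters = list(list(rows = 1:2, cols = 1:2),
                                         list(rows = 1L, cols = 1L)),
                         row_labels = c("r1", "r2"),
                         col_labels = c("c1", "c2")),
                    class = "rect_partition")
  rep_ <- validate_partition(Pbad)
  expect_false(rep_$valid)
  expect_match(paste(rep_$violations, collapse = " "), "overlap")
  Pgap <- structure(list(grid_shape = c(2L, 2L),
                         clusters = list(list(rows = 1L, cols = 1:2)),
                         row_labels = c("r1", "r2"),
                         col_labels = c("c1", "c2")),
                    class = "rect_partition")
  expect_match(paste(validate_partition(Pgap)$violations, collapse = " "),
               "coverage gap")
})

test_that("1 - X is block-diagonal after sorting cells by cluster", {
  for (seed in 1:5) {
    P <- sample_rectangular_partition(3, 4, 3, seed = seed)
    x <- partition_to_x(P)
    n <- 12
    Xf <- x; dim(Xf) <- c(n, n)
    memb <- as.vector(partition_membership(P))
    ord <- order(memb)
    B <- (1 - Xf)[ord, ord]
    sizes <- table(memb)
    off <- 0
    for (s in sizes) {
      blk <- B[(off + 1):(off + s), (off + 1):(off + s), drop = FALSE]
      expect_true(all(blk == 1))
      off <- off + s
    }
    expect_equal(sum(B), sum(sizes^2))  # zeros everywhere off the blocks
  }
})

test_that("rand index and partition IO behave", {
  P <- sample_rectangular_partition(4, 3, 3, seed = 2)
  expect_equal(rand_index(P, P), 1)
  Pw <- rect_partition(c(4, 3), list(list(rows = 1:4, cols = 1:3)))
  expect_lt(rand_index(P, Pw), 1)

  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_partition_json(P, fj)
  obj <- jsonlite::fromJSON(fj)
  expect_length(obj, length(P$clusters))
  write_partition_csv(P, fc)
  P2 <- read_partition_csv(fc)
  expect_equal(partition_membership(P2), partition_membership(P))
})
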