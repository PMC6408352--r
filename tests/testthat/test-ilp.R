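test_that("direct program structure and closed-form row counts", {
  S <- orthogonal_rows_S()
  prog <- build_direct_program(S, 0.5)
  expect_equal(prog$n_vars, 6L)  # one variable per unordered cell pair

  # closed-form "as built" counts agree with the materialized system
  for (shape in list(c(2, 2), c(2, 3), c(3, 2))) {
    Sr <- random_similarity_tensor(shape, seed = sum(shape))
    p <- build_direct_program(Sr, 1)
    expect_equal(length(ip_constraints(p)$rows), ip_row_count(p, "built"))
  }

  # the literally-written system for the 36 x 14 problem exceeds 1e6 rows
  S36 <- unflatten_similarity(diag(504), c(36, 14))
  p36 <- build_direct_program(S36, 0.5)
  expect_gt(ip_row_count(p36, "paper"), 1e6)

  expect_error(build_direct_program(S, -1), "non-negative")
  bad <- S; bad$values[1, 1, 2, 2] <- 2
  expect_error(build_direct_program(bad, 0.5), "not symmetric")
})

test_that("worked orthogonal-rows instance is solved to the known optima", {
  S <- orthogonal_rows_S()
  r1 <- solve_ip(build_direct_program(S, 0.5))
  expect_equal(r1$status, "optimal")
  expect_equal(r1$gap, 0)
  expect_equal(r1$objective_value, 12)
  P1 <- decode_direct(r1, c(2, 2))
  expect_equal(partition_membership(P1), matrix(c(1L, 2L, 1L, 2L), 2))

  r2 <- solve_ip(build_direct_program(S, 2))
  expect_equal(r2$objective_value, 28)
  expect_length(decode_direct(r2, c(2, 2))$clusters, 4L)

  # lambda = 0 with non-negative S: the single cluster is optimal
  r0 <- solve_ip(build_direct_program(S, 0))
  expect_equal(r0$objective_value,
               objective_direct(S, rect_partition(c(2, 2),
                 list(list(rows = 1:2, cols = 1:2))), 0))
})

test_that("direct objective evaluates the inner products exactly", {
  Sones <- unflatten_similarity(matrix(1, 4, 4), c(2, 2))
  P1 <- rect_partition(c(2, 2), list(list(rows = 1:2, cols = 1:2)))
  expect_equal(objective_direct(Sones, P1, 0), 16)

  expect_equal(objective_direct(orthogonal_rows_S(),
    rect_partition(c(2, 2), list(list(rows = 1, cols = 1:2),
                                 list(rows = 2, cols = 1:2))), 0.5), 12)

  # zero off-diagonal similarity: value is the diagonal sum for any P
  Sdiag <- unflatten_similarity(diag(4), c(2, 2))
  for (P in enumerate_rectangular_partitions(2, 2)) {
    expect_equal(objective_direct(Sdiag, P, 0), 4)
  }
  expect_error(objective_direct(Sones, rect_partition(c(3, 1),
    list(list(rows = 1:3, cols = 1))), 0), "does not match")
})

test_that("solver optimum equals the brute-force oracle on random instances", {
  for (shape in list(c(2, 2), c(3, 2), c(3, 3))) {
    for (seed in 1:6) {
      S <- random_similarity_tensor(shape, seed = seed * 11)
      for (lam in c(0, 0.5, 2)) {
        so <- solve_ip(build_direct_program(S, lam))
        br <- brute_force_direct(S, lam)
        expect_equal(so$objective_value, br$objective, tolerance = 1e-10)
        P <- decode_direct(so, shape)
        expect_true(validate_partition(P)$valid)
        expect_equal(objective_direct(S, P, lam), so$objective_value,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("structural (lazy) and matrix (full row) modes agree", {
  for (seed in 1:4) {
    S <- random_similarity_tensor(c(2, 3), seed = seed)
    for (lam in c(0.3, 1.5)) {
      prog <- build_direct_program(S, lam)
      expect_equal(solve_ip(prog, list(mode = "matrix"))$objective_value,
                   solve_ip(prog, list(mode = "structural"))$objective_value,
                   tolerance = 1e-10)
    }
    W <- cluster_flat(sim_matrix(flatten_similarity(
      random_similarity_tensor(c(2, 3), seed = seed + 50)), c(2, 3)), 2)
    progW <- build_refine_program(W)
    expect_equal(solve_ip(progW, list(mode = "matrix"))$objective_value,
                 solve_ip(progW, list(mode = "structural"))$objective_value)
  }
})

test_that("between-cluster pair count is non-decreasing in lambda", {
  for (seed in 1:4) {
    S <- random_similarity_tensor(c(3, 2), seed = 100 + seed)
    between <- vapply(c(0, 0.25, 0.5, 1, 2), function(lam) {
      sum(solve_ip(build_direct_program(S, lam))$assignment) * 2
    }, 1)
    expect_true(all(diff(between) >= 0))
  }
})

test_that("permuting grid labels permutes the solution, not its value", {
  S <- random_similarity_tensor(c(3, 3), seed = 5)
  lam <- 0.6
  base <- solve_ip(build_direct_program(S, lam))
  withr::with_seed(1, {
    pr <- sample(3); pc <- sample(3)
  })
  Sp <- structure(list(values = S$values[pr, pc, pr, pc], dims = c(3L, 3L)),
                  class = "similarity_tensor")
  perm <- solve_ip(build_direct_program(Sp, lam))
  expect_equal(perm$objective_value, base$objective_value, tolerance = 1e-10)
  Mb <- partition_membership(decode_direct(base, c(3, 3)))
  Mp <- partition_membership(decode_direct(perm, c(3, 3)))
  # same co-membership structure after undoing the permutation
  co <- function(M) outer(as.vector(M), as.vector(M), "==")
  expect_equal(co(Mp), co(Mb[pr, pc]))
})

test_that("refinement program contract: fixed points and nearest rectangles", {
  # a rectangular W is a fixed point with full agreement n1*n2
  P <- rect_partition(c(3, 4), list(list(rows = 1:2, cols = c(1, 3)),
                                    list(rows = 1:2, cols = c(2, 4)),
                                    list(rows = 3, cols = 1:4)))
  W <- partition_to_y(P, 3)
  res <- solve_ip(build_refine_program(W))
  expect_equal(res$objective_value, 12)
  expect_equal(partition_membership(decode_refine(res, c(3, 4), 3)),
               partition_membership(P))
  expect_equal(objective_refine(W, P), 12)

  # 2x2 anti-diagonal seed: best rectangular agreement is 2
  Wad <- array(0, c(2, 2, 2))
  Wad[1, 1, 1] <- Wad[2, 2, 1] <- 1
  Wad[1, 2, 2] <- Wad[2, 1, 2] <- 1
  rad <- solve_ip(build_refine_program(Wad))
  expect_equal(rad$objective_value, 2)
  expect_equal(brute_force_refine(Wad)$agreement, 2)
  Pad <- decode_refine(rad, c(2, 2), 2)
  expect_length(Pad$clusters, 2L)

  # upper bound <W, Y> <= n1*n2, equality iff W is rectangular
  for (seed in 1:6) {
    n1 <- 3; n2 <- 2; m <- 2
    withr::with_seed(seed, memb <- sample(m, n1 * n2, replace = TRUE))
    W2 <- array(0, c(n1, n2, m))
    W2[cbind(rep(1:n1, n2), rep(1:n2, each = n1), memb)] <- 1
    r <- solve_ip(build_refine_program(W2))
    expect_lte(r$objective_value, n1 * n2)
    expect_equal(r$objective_value, brute_force_refine(W2)$agreement)
    rect <- !inherits(try(y_to_partition(W2), silent = TRUE), "try-error")
    expect_equal(r$objective_value == n1 * n2, rect)
  }

  # row-count conventions
  pw <- build_refine_program(partition_to_y(sample_rectangular_partition(
    36, 14, 5, seed = 1), 5))
  expect_equal(ip_row_count(pw, "paper") - 36 * 14, 36^2 * 14^2 * 5)
  bad <- W; bad[1, 1, ] <- 0
  expect_error(build_refine_program(bad), "not a hard assignment")
})

test_that("decoding refuses non-certified results and exports LP text", {
  S <- orthogonal_rows_S()
  res <- solve_ip(build_direct_program(S, 0.5))
  res$status <- "limit"
  expect_error(decode_direct(res, c(2, 2)), "non-certified")
  expect_error(decode_refine(res, c(2, 2), 2), "non-certified")

  f <- withr::local_tempfile(fileext = ".lp")
  prog <- build_direct_program(S, 0.5)
  write_lp(prog, f)
  lp <- readLines(f)
  expect_equal(lp[1], "Maximize")
  expect_true(any(lp == "Binary"))
  # one line per equality row, two per two-sided inequality row
  cs <- ip_constraints(prog)
  n_lines <- sum(ifelse(cs$lower == cs$upper, 1L, 2L))
  expect_equal(sum(grepl("^ c[0-9]+", lp)), n_lines)
})
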