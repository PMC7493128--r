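# The candidate-threshold + one-tailed paired t + BH-FDR procedure and the
# node/path-length contrasts.

sym <- function(v, N = 4) {
  A <- matrix(0, N, N)
  A[upper.tri(A)] <- v
  A + t(A)
}

test_that("group mean differences subtract idle from the movement stage", {
  a <- sym(runif(6))
  b <- sym(runif(6))
  expect_true(all(group_mean_diff(list(a, b), list(a, b)) == 0))
  expect_equal(group_mean_diff(list(a), list(b)), a - b)
  expect_equal(group_mean_diff(list(a), list(b)),
               -group_mean_diff(list(b), list(a)))
  expect_error(group_mean_diff(list(a), list(a, b)), "same subjects")
})

test_that("candidate mask uses a strict 0.02 threshold on the upper triangle", {
  d <- sym(c(0.02, 0.021, -0.5, 0.019, 0.5, 0))
  mask <- candidate_edges(d)
  expect_false(mask[1, 2]) # exactly 0.02 is excluded
  expect_true(mask[1, 3]) # 0.021
  expect_true(mask[2, 4]) # 0.5
  expect_false(any(mask[lower.tri(mask, diag = TRUE)]))
  expect_false(any(candidate_edges(sym(rep(-0.1, 6)))))
})

test_that("one-tailed paired t matches the textbook value and t.test", {
  # three subjects, single-edge matrices with differences (1, 2, 3)
  mk <- function(x) sym(c(x, 0, 0, 0, 0, 0), 4)
  stage <- list(mk(1.2), mk(2.2), mk(3.2))
  idle <- list(mk(0.2), mk(0.2), mk(0.2))
  tt <- paired_t_one_tailed(stage, idle)
  row <- tt[tt$i == 1 & tt$j == 2, ]
  expect_equal(row$t, 2 / (1 / sqrt(3)), tolerance = 1e-12) # 3.4641
  expect_equal(row$p, pt(3.464102, df = 2, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(row$p, 0.0371, tolerance = 1e-3)
  ht <- t.test(c(1.2, 2.2, 3.2), c(0.2, 0.2, 0.2), paired = TRUE,
               alternative = "greater")
  expect_equal(row$p, ht$p.value, tolerance = 1e-12)
  # sign flip maps p -> 1 - p
  tt2 <- paired_t_one_tailed(idle, stage)
  expect_equal(tt2$p[tt2$i == 1 & tt2$j == 2], 1 - row$p, tolerance = 1e-12)
  # all-zero differences are guarded to p = 0.5
  expect_message(
    tt3 <- paired_t_one_tailed(list(mk(1), mk(1)), list(mk(1), mk(1))),
    "zero-variance"
  )
  expect_true(all(tt3$p == 0.5))
})

test_that("BH-FDR matches hand cases and a brute-force oracle", {
  expect_equal(bhfdr(0.03), 0.03)
  expect_equal(bhfdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhfdr(rep(1, 5)), rep(1, 5))
  expect_error(bhfdr(numeric(0)), "empty")
  expect_error(bhfdr(c(0.5, 1.2)), "0, 1")
  set.seed(123)
  for (rep in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bhfdr(p), bh_bruteforce(p), tolerance = 1e-15)
  }
})

test_that("edge_tests conjoins the candidate mask with FDR significance", {
  set.seed(11)
  N <- 5
  n_sub <- 8
  base <- lapply(seq_len(n_sub), function(s) sym(runif(10, 0.3, 0.4), N))
  stage <- lapply(base, function(A) {
    B <- A
    B[1, 2] <- B[2, 1] <- A[1, 2] + 0.2 # one real increase
    B
  })
  res <- edge_tests(stage, base)
  expect_s3_class(res, "edge_test_result")
  expect_equal(nrow(res), 10)
  sig <- significant_edges(res)
  expect_equal(nrow(sig), 1)
  expect_equal(c(sig$i, sig$j), c(1, 2))
  expect_true(all(res$q >= res$p))
  expect_true(all(res$significant == (res$candidate & res$q < 0.05)))
  g <- glance(res)
  expect_equal(g$n_significant, 1)
  expect_equal(g$n_subjects, n_sub)
  # restricting the FDR family to candidates is available
  res2 <- edge_tests(stage, base, fdr_family = "candidates")
  expect_true(all(is.na(res2$q[!res2$candidate])))
})

test_that("node-degree contrasts flag shifted nodes and only those", {
  set.seed(7)
  n_sub <- 12
  N <- 6
  base <- matrix(rnorm(n_sub * N, 10, 0.5), n_sub, N)
  colnames(base) <- paste0("ch", 1:N)
  shifted <- base
  shifted[, 3] <- shifted[, 3] + 10 * sd(base[, 3]) # ~10 between-subject SDs
  res <- node_degree_tests(list(REF = shifted, REST = base))
  expect_true(res$significant[res$node == "ch3"])
  expect_lte(sum(res$significant), N)
  same <- node_degree_tests(list(A = base, B = base))
  expect_equal(sum(same$significant), 0)
  expect_error(node_degree_tests(list(A = base, B = base[1:3, ])), "differ")
})

test_that("path-length contrasts report means, SDs, and guarded p-values", {
  set.seed(2)
  L1 <- c(2.0, 2.2, 1.9, 2.1, 2.05)
  Ls <- list(REF = L1, CAR = L1, REST = L1 + rnorm(5, 0, 0.01))
  expect_message(path_length_test(Ls), "identical")
  res <- suppressMessages(path_length_test(Ls))
  expect_equal(res$tests$p[res$tests$contrast == "REF vs CAR"], 1)
  expect_equal(nrow(res$summary), 3)
  expect_equal(res$summary$mean_L[1], mean(L1))
})
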