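test_that("tpm is count over total times one million", {
  expect_equal(tpm(10, 1e6), 10)
  expect_equal(tpm(0, 12345), 0)
  counts <- c(5, 10, 985)
  expect_equal(sum(tpm(counts, sum(counts))), 1e6)
  expect_error(tpm(1, 0), "total_clean")
})

test_that("two_library_test matches the brute-force summation oracle", {
  expect_equal(two_library_test(5, 5, 1e6, 1e6), 1.0)
  expect_error(two_library_test(0, 0, 1e5, 1e5), "untestable")
  # spec-style example: direct summation over y' with Pr(y') <= Pr(40)
  expect_equal(two_library_test(10, 40, 1e6, 1e6),
               oracle_two_lib(10, 40, 1e6, 1e6), tolerance = 1e-12)
  # grid over combined counts and library-size ratios
  for (N2 in c(1e5, 2.5e5)) {
    for (n in c(1, 2, 7, 50, 200)) {
      for (y in unique(c(0, 1, n %/% 3, n))) {
        x <- n - y
        expect_equal(two_library_test(x, y, 1e5, N2),
                     oracle_two_lib(x, y, 1e5, N2),
                     tolerance = 1e-12,
                     label = sprintf("x=%d y=%d N2=%g", x, y, N2))
      }
    }
  }
})

test_that("p decreases as the observed count moves away from the null", {
  x <- 20; N1 <- N2 <- 1e5
  ps <- vapply(20:60, function(y) two_library_test(x, y, N1, N2),
               numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("empirical type-I error is controlled at nominal 0.05", {
  set.seed(202)
  n_sim <- 500
  lam <- 20
  xs <- rpois(n_sim, lam)
  ys <- rpois(n_sim, lam)
  ok <- xs + ys >= 1
  p <- mapply(two_library_test, xs[ok], ys[ok],
              MoreArgs = list(N1 = 1e5, N2 = 1e5))
  expect_lte(mean(p < 0.05), 0.06)
})

test_that("bh_adjust reproduces the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  set.seed(4)
  for (i in 1:10) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))  # independent reference
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("fold_change handles zeros via the floor", {
  expect_equal(fold_change(10, 40), 2)
  expect_equal(fold_change(40, 10), -2)
  expect_equal(fold_change(0, 10.24, floor = 0.01), 10)
  expect_equal(fold_change(10, 40), -fold_change(40, 10))
  expect_error(fold_change(0, 0), "both TPMs")
})

test_that("classification respects the fold and alpha boundaries", {
  rows <- data.frame(log2fc = c(1.00, 0.99, -1.00, -0.5, 3),
                     adj_pvalue = c(1e-10, 1e-10, 1e-10, 1e-10, 0.02))
  cl <- classify_de(rows, alpha = 0.01, min_fold = 2)
  expect_equal(cl$results$status, c("up", "ns", "down", "ns", "ns"))
  expect_equal(cl$n_up, 1L)
  expect_equal(cl$n_down, 1L)
  # row order invariance
  perm <- sample(nrow(rows))
  cl2 <- classify_de(rows[perm, ], alpha = 0.01, min_fold = 2)
  expect_equal(cl2$results$status, cl$results$status[perm])
})

test_that("swapping libraries negates log2fc and swaps up and down", {
  set.seed(11)
  counts <- data.frame(mirna_id = sprintf("m%02d", 1:30),
                       count_control = rpois(30, 50),
                       count_knockdown = rpois(30, c(rep(50, 20),
                                                     rep(200, 10))))
  a <- de_test(counts, 1e5, 1.2e5)
  swapped <- data.frame(mirna_id = counts$mirna_id,
                        count_control = counts$count_knockdown,
                        count_knockdown = counts$count_control)
  b <- de_test(swapped, 1.2e5, 1e5)
  expect_equal(b$results$log2fc, -a$results$log2fc)
  expect_equal(b$results$pvalue, a$results$pvalue, tolerance = 1e-12)
  expect_equal(b$n_up, a$n_down)
  expect_equal(b$n_down, a$n_up)
})

test_that("sample_specific returns per-library exclusive miRNAs", {
  counts <- data.frame(mirna_id = c("a", "b", "c", "d"),
                       count_control = c(0L, 3L, 7L, 0L),
                       count_knockdown = c(7L, 5L, 0L, 0L))
  ss <- sample_specific(counts)
  expect_equal(ss$knockdown_specific, "a")
  expect_equal(ss$control_specific, "c")
  set.seed(12)
  tab <- data.frame(mirna_id = sprintf("m%d", 1:50),
                    count_control = rbinom(50, 3, 0.5),
                    count_knockdown = rbinom(50, 3, 0.5))
  ss2 <- sample_specific(tab)
  expect_equal(ss2$control_specific,
               tab$mirna_id[tab$count_control > 0 &
                              tab$count_knockdown == 0])
})

test_that("planted DE miRNAs are recovered on the shared fixture", {
  # reduced-depth single seed here; the full 10-seed depth-1e5 criterion
  # runs in the acceptance suite
  fix <- sim_fixture()
  qc <- quantify_known_mirna(fix$libs$control, fix$refs)
  qk <- quantify_known_mirna(fix$libs$knockdown, fix$refs)
  counts <- data.frame(mirna_id = qc$mirna$mirna_id,
                       count_control = qc$mirna$count,
                       count_knockdown = qk$mirna$count)
  res <- de_test(counts, fix$libs$control$total_clean,
                 fix$libs$knockdown$total_clean, alpha = 0.05)
  truth <- fix$refs$truth$de
  # at this reduced depth the planted effect shows in the estimates even
  # where significance is not yet reached; the powered 10-seed depth-1e5
  # recovery criterion lives in the acceptance suite
  lfc <- res$results$log2fc[match(truth$mirna_id, res$results$mirna_id)]
  expect_gt(cor(lfc, truth$log2fc), 0.8)
  called <- res$results$status[match(truth$mirna_id,
                                     res$results$mirna_id)]
  expect_true(all(called[truth$sign > 0] != "down"))
  expect_true(all(called[truth$sign < 0] != "up"))
})
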