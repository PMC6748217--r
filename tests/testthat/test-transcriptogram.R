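test_that("window averaging matches hand arithmetic and its limits", {
  m <- matrix(c(1, 2, 3, 4), 4, 2, dimnames = list(NULL, NULL))
  expr <- toy_expr(m)
  ord <- identity_order(expr)
  # radius 0 is the identity on the reordered matrix
  p0 <- window_average(expr, ord, radius = 0)
  expect_equal(unclass(p0)[, ], expr$values[ord$gene, ], ignore_attr = TRUE)
  # radius 1 at position 2: mean(1, 2, 3) = 2; truncated at the ends
  p1 <- window_average(expr, ord, radius = 1)
  expect_equal(unname(p1[2, 1]), 2)
  expect_equal(unname(p1[1, 1]), 1.5)
  expect_equal(unname(p1[4, 1]), 3.5)
  # radius >= N - 1: every position is the per-sample global mean
  p3 <- window_average(expr, ord, radius = 3)
  expect_true(all(abs(sweep(p3, 2, colMeans(expr$values))) < 1e-12))
  expect_warning(window_average(expr, ord, radius = 4), "radius")
})

test_that("window averaging equals a brute-force per-position mean", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    m <- matrix(rnorm(n * 3), n)
    expr <- toy_expr(m)
    ord <- gene_ordering(rownames(expr$values), sample(n))
    r <- sample(0:(n + 1), 1)
    prof <- suppressWarnings(window_average(expr, ord, radius = r))
    genes <- ord$gene
    brute <- t(vapply(seq_len(n), function(i) {
      idx <- genes[max(1, i - r):min(n, i + r)]
      colMeans(expr$values[idx, , drop = FALSE])
    }, numeric(3)))
    expect_equal(unclass(prof), brute, ignore_attr = TRUE)
  }
})

test_that("relative profile is the case-minus-control mean difference", {
  m <- matrix(rnorm(40), 10, 4)
  expr <- toy_expr(m, conditions = c("case", "case", "control", "control"))
  prof <- window_average(expr, identity_order(expr), radius = 0)
  rel <- relative_profile(prof)
  expect_equal(unname(rel), unname((m[, 1] + m[, 2]) / 2 - (m[, 3] + m[, 4]) / 2))
  # identical conditions give an all-zero series; a constant shift gives delta
  m2 <- cbind(m[, 1:2], m[, 1:2])
  expect_equal(max(abs(relative_profile(window_average(
    toy_expr(m2, c("case", "case", "control", "control")),
    identity_order(expr), 0)))), 0)
  m3 <- cbind(m[, 1:2] + 0.7, m[, 1:2])
  expect_equal(unname(relative_profile(window_average(
    toy_expr(m3, c("case", "case", "control", "control")),
    identity_order(expr), 0))), rep(0.7, 10))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.4), 0.4)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("moderated t reduces to the pooled t when the prior is off", {
  set.seed(3)
  m <- matrix(rnorm(25 * 8), 25)
  expr <- toy_expr(m, conditions = rep(c("control", "case"), each = 4))
  prof <- window_average(expr, identity_order(expr), radius = 2)
  res <- moderated_t(prof, d0 = 0)
  # independent pooled-t oracle
  for (i in c(1, 10, 25)) {
    o <- stats::t.test(prof[i, 5:8], prof[i, 1:4], var.equal = TRUE)
    expect_equal(res$t[i], unname(o$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], o$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t uses the shared variance in the infinite-prior limit", {
  set.seed(4)
  m <- matrix(rnorm(30 * 8), 30)
  expr <- toy_expr(m, conditions = rep(c("control", "case"), each = 4))
  prof <- window_average(expr, identity_order(expr), radius = 1)
  s02 <- 0.37
  res <- moderated_t(prof, d0 = Inf, s02 = s02)
  delta <- rowMeans(prof[, 5:8]) - rowMeans(prof[, 1:4])
  expect_equal(res$t, unname(delta / sqrt(s02 * (1 / 4 + 1 / 4))),
               tolerance = 1e-12)
  expect_equal(res$p, unname(2 * stats::pnorm(-abs(res$t))), tolerance = 1e-12)
})

test_that("default moderated t matches the closed form at the fitted prior", {
  set.seed(5)
  m <- matrix(rnorm(40 * 8, sd = rep(runif(40, 0.5, 2), 8)), 40)
  expr <- toy_expr(m, conditions = rep(c("control", "case"), each = 4))
  prof <- window_average(expr, identity_order(expr), radius = 0)
  fitted <- moderated_t(prof)
  d0 <- attr(fitted, "d0"); s02 <- attr(fitted, "s02")
  expect_true(d0 > 0)
  # direct-formula oracle with (d0, s02) fixed to the fitted values
  y <- unclass(prof)
  m1 <- rowMeans(y[, 1:4]); m2 <- rowMeans(y[, 5:8])
  s2 <- (apply(y[, 1:4], 1, var) * 3 + apply(y[, 5:8], 1, var) * 3) / 6
  s2post <- (d0 * s02 + 6 * s2) / (d0 + 6)
  t_oracle <- (m2 - m1) / sqrt(s2post * (1 / 4 + 1 / 4))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = d0 + 6)
  expect_equal(fitted$t, unname(t_oracle), tolerance = 1e-9)
  expect_equal(fitted$p, unname(p_oracle), tolerance = 1e-9)
  expect_true(all(fitted$padj >= fitted$p - 1e-15))
})

test_that("moderated t validates its inputs", {
  m <- matrix(1:12, 4, 3)
  expr <- toy_expr(m, conditions = c("case", "case", "control"))
  prof <- window_average(expr, identity_order(expr), radius = 0)
  expect_error(moderated_t(prof), ">= 2 samples")
  m2 <- matrix(rep(c(1, 2, 3, 4), 4), 4, 4)  # zero residual variance
  expr2 <- toy_expr(m2, conditions = rep(c("case", "control"), each = 2))
  prof2 <- window_average(expr2, identity_order(expr2), radius = 0)
  expect_error(moderated_t(prof2), "degenerate")
})

mk_tests <- function(padj, direction) {
  res <- data.frame(position = seq_along(padj),
                    gene = sprintf("g%03d", seq_along(padj)),
                    t = 0, p = padj, padj = padj, direction = direction,
                    stringsAsFactors = FALSE)
  class(res) <- c("position_tests", "data.frame")
  res
}

test_that("cluster calling finds maximal same-direction runs", {
  padj <- rep(1, 30); padj[10:20] <- 1e-5
  dirn <- rep("up", 30)
  cl <- call_clusters(mk_tests(padj, dirn), alpha = 0.001)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$start, 10); expect_equal(cl$end, 20)
  expect_equal(cl$direction, "up")
  expect_equal(cl$genes[[1]], sprintf("g%03d", 10:20))
  expect_equal(cl$n_genes, 11)
  # nothing significant: empty table
  expect_equal(nrow(call_clusters(mk_tests(rep(1, 10), rep("up", 10)))), 0)
})

test_that("gap tolerance merges runs but opposing runs block the merge", {
  padj <- rep(1, 30); padj[c(5:8, 12:15)] <- 1e-5
  dirn <- rep("up", 30)
  expect_equal(nrow(call_clusters(mk_tests(padj, dirn), gap = 0)), 2)
  merged <- call_clusters(mk_tests(padj, dirn), gap = 5)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(5, 15))
  # an opposing significant run in between prevents merging
  padj2 <- rep(1, 30); padj2[c(5:8, 10, 12:15)] <- 1e-5
  dirn2 <- rep("up", 30); dirn2[10] <- "down"
  cl2 <- call_clusters(mk_tests(padj2, dirn2), gap = 5)
  expect_equal(nrow(cl2), 3)
  expect_equal(cl2$direction, c("up", "down", "up"))
})

test_that("clusters are labelled left to right with interval gene membership", {
  padj <- rep(1, 50); padj[c(3:6, 20:25, 40:44)] <- 1e-6
  dirn <- rep("down", 50); dirn[20:25] <- "up"
  cl <- call_clusters(mk_tests(padj, dirn))
  expect_equal(cl$label, c("1", "2", "3"))
  expect_equal(cl$start, c(3, 20, 40))
  expect_equal(cl$direction, c("down", "up", "down"))
  expect_true(all(cl$min_padj <= 1e-6))
})
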