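test_that("correlation matrix matches the direct Pearson formula", {
  em <- expression_matrix(cbind(x = c(1, 2, 3), y = c(1, 2, 4),
                                z = c(3, 2, 1)),
                          cell_ids = paste0("c", 1:3))
  cm <- correlation_matrix(em)
  # hand evaluation: r_xy = 3 / (sqrt(2) * sqrt(42/9)) = 9 / sqrt(84)
  expect_equal(cm["x", "y"], 9 / sqrt(84), tolerance = 1e-12)
  expect_equal(cm["x", "x"], 1)
  expect_equal(cm["x", "z"], -1)          # exact anticorrelation
  expect_equal(cm, t(cm))
  expect_true(all(abs(cm) <= 1 + 1e-12))
  expect_error(correlation_matrix(random_expression(1, 3)), "2 cells")
})

test_that("constant genes get zero correlation, not NaN", {
  em <- expression_matrix(cbind(a = c(1, 2, 3), b = c(5, 5, 5)),
                          cell_ids = paste0("c", 1:3))
  cm <- correlation_matrix(em)
  expect_equal(cm["a", "b"], 0)
  expect_equal(cm["b", "b"], 1)
  expect_false(anyNA(cm))
})

test_that("greedy pooling honors the pool size and groups correlated pairs", {
  em <- random_expression(8, 6, seed = 2)
  cm <- correlation_matrix(em)

  p1 <- pool_genes(cm, 1)
  expect_equal(p1$l, 6L)                  # singletons
  expect_equal(sort(unique(p1$assignment$supergene)), 1:6)

  pall <- pool_genes(cm, 6)
  expect_equal(pall$l, 1L)                # one pool

  # two perfectly correlated pairs must pool together at k = 2
  set.seed(4)
  base <- matrix(rnorm(20), 10, 2)
  vals <- cbind(a = base[, 1], b = 2 * base[, 1] + 3,
                c = base[, 2], d = -base[, 2])
  cm2 <- correlation_matrix(expression_matrix(vals,
                                              cell_ids = paste0("c", 1:10)))
  p2 <- pool_genes(cm2, 2)
  expect_equal(p2$l, 2L)
  asn <- setNames(p2$assignment$supergene, p2$assignment$gene_id)
  expect_equal(asn[["a"]], asn[["b"]])
  expect_equal(asn[["c"]], asn[["d"]])    # |r| pools anticorrelated genes
})

test_that("pooling is a partition and l(k) is non-increasing in k", {
  for (seed in 1:5) {
    em <- random_expression(9, 11, seed = seed)
    cm <- correlation_matrix(em)
    ls <- vapply(1:11, function(k) {
      p <- pool_genes(cm, k)
      expect_equal(sort(p$assignment$gene_id), sort(colnames(em)))
      expect_true(all(table(p$assignment$supergene) <= k))
      p$l
    }, integer(1))
    expect_true(all(diff(ls) <= 0))
  }
})

test_that("sliding-window pool-size selection follows the plateau rule", {
  em <- random_expression(10, 12, seed = 6)
  # constant l(k) -> first window pair triggers; k* = mean of second window
  sel <- select_pool_size(em, k_grid = c(12, 13, 14, 15, 16, 17), window = 3)
  expect_true(sel$converged)
  expect_equal(sel$k, round(mean(c(13, 14, 15))))
  expect_equal(sel$l, 1L)

  # grid too short for two windows
  expect_error(select_pool_size(em, k_grid = c(2, 3), window = 3),
               "at least 2 windows")

  # a strictly halving l(k) sequence fires exactly where successive window
  # means first differ by < 2 (scan the profile directly as the oracle)
  sel2 <- select_pool_size(em, k_grid = 2:12, window = 3)
  prof <- sel2$profile
  lbar <- vapply(seq_len(nrow(prof) - 2),
                 function(i) mean(prof$l[i:(i + 2)]), numeric(1))
  first <- which(abs(diff(lbar)) < 2)[1] + 1L
  expect_equal(sel2$l, as.integer(round(lbar[first])))
})

test_that("never-met plateau warns and returns the last window", {
  # l(k) = ceiling(g/k) with many genes and a short steep grid keeps
  # window means more than 2 apart
  em <- random_expression(5, 60, seed = 8)
  expect_warning(
    sel <- select_pool_size(em, k_grid = c(2, 3, 4, 5), window = 2),
    "never met")
  expect_false(sel$converged)
})

test_that("supergene expression is the member mean and conserves totals", {
  em <- expression_matrix(rbind(c(2, 4, 10), c(1, 3, 5)),
                          c("c1", "c2"), c("a", "b", "z"))
  pooling <- list(assignment = tibble::tibble(gene_id = c("a", "b", "z"),
                                              supergene = c(1L, 1L, 2L)),
                  k = 2L, l = 2L)
  out <- supergene_expression(em, pooling)
  expect_equal(out$supergene_values["c1", ], c(SG1 = 3, SG2 = 10))
  expect_equal(out$supergene_values["c2", ], c(SG1 = 2, SG2 = 5))

  # random pools vs a brute-force per-cell mean loop
  em2 <- random_expression(7, 10, seed = 3)
  p <- pool_genes(correlation_matrix(em2), 3)
  sg <- supergene_expression(em2, p)$supergene_values
  for (cell in seq_len(7)) {
    for (pool in seq_len(p$l)) {
      members <- p$assignment$gene_id[p$assignment$supergene == pool]
      expect_equal(sg[cell, pool],
                   mean(unclass(em2)[cell, members]), ignore_attr = TRUE)
    }
  }
  # mean-pooling conservation: sum over pools of size * value = cell total
  sizes <- as.integer(table(p$assignment$supergene))
  expect_equal(as.numeric(sg %*% sizes), unname(rowSums(em2)))

  bad <- list(assignment = tibble::tibble(gene_id = "nope", supergene = 1L),
              k = 1L, l = 1L)
  expect_error(supergene_expression(em2, bad), "unknown|not covered")
})
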