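test_that("TPM normalizes to one million per sample without length terms", {
  ct <- data.frame(transcript_id = c("a", "b", "c"),
                   s1 = c(1L, 1L, 2L), s2 = c(10L, 0L, 0L))
  expr <- compute_tpm(ct)
  expect_equal(expr$tpm$s1, c(250000, 250000, 500000))
  expect_equal(expr$tpm$s2, c(1e6, 0, 0))
  expect_equal(sum(expr$tpm$s1), 1e6)
  set.seed(2)
  r <- compute_tpm(data.frame(transcript_id = letters[1:10],
                              s1 = rpois(10, 40) + 1L))
  expect_equal(sum(r$tpm$s1), 1e6)
  expect_warning(compute_tpm(data.frame(transcript_id = "a", s1 = 0L)), "zero")
})

test_that("per-gene relative abundances sum to one", {
  ct <- data.frame(transcript_id = c("t1", "t2", "t3"),
                   s1 = c(40L, 10L, 5L), s2 = c(39L, 11L, 5L))
  ab <- isoform_abundance(compute_tpm(ct),
                         c(t1 = "g1", t2 = "g1", t3 = "g2"),
                         novel_orf_ids = "t2")
  expect_equal(ab[gene_id == "g1" & transcript_id == "t1", relative_abundance],
               0.79)
  expect_equal(ab[transcript_id == "t3", relative_abundance], 1)
  expect_equal(ab[, sum(relative_abundance), by = "gene_id"]$V1, c(1, 1),
               tolerance = 1e-9)
  expect_true(ab[transcript_id == "t2", is_novel_orf])
})

test_that("novel-dominant flagging honours the long-transcript exclusion", {
  ref <- gene_catalog(list(
    make_tx("r1", 0, 4000, gene = "g1"),
    make_tx("r2", c(0, 5000), c(4500, 9500), gene = "g2"),
    make_tx("r3", 0, 2000, gene = "g3")))
  ab <- data.table::data.table(
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    transcript_id = c("n1", "r1", "n2", "r2", "r3"),
    total_count = c(62, 38, 70, 30, 10),
    relative_abundance = c(0.62, 0.38, 0.7, 0.3, 1),
    is_novel_orf = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  res <- flag_novel_dominant(ab, ref, length_cutoff = 8000)
  expect_equal(res$flagged$gene_id, "g1")          # g2 excluded: 9 kb reference
  expect_equal(res$excluded$gene_id, "g2")
  # a gene whose every isoform has a known ORF is never flagged
  expect_false("g3" %in% res$flagged$gene_id)
})

test_that("chi-squared matches the closed form and a permutation null", {
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  r <- chi_squared(tab)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(r$df, 1)
  same <- chi_squared(matrix(c(15, 15, 15, 15), 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(chi_squared(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "marginal")
  # permutation null with fixed margins
  set.seed(17)
  stat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  perm <- r2dtable(20000, rowSums(tab), colSums(tab))
  p_perm <- mean(vapply(perm, stat, numeric(1)) >= r$statistic - 1e-12)
  expect_equal(r$p_value, p_perm, tolerance = 0.02)
})

test_that("Mann-Whitney U matches exhaustive enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3))$statistic, 9)
  set.seed(19)
  x <- rnorm(8); y <- rnorm(8, 0.5)
  r <- mann_whitney(x, y)
  # enumeration over all assignments of ranks to the x-group
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- utils::combn(16, 8)
  u_null <- apply(combs, 2, function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  })
  p_exact <- mean(abs(u_null - 32) >= abs(u_obs - 32))
  expect_equal(r$statistic, u_obs)
  expect_equal(r$p_value, p_exact, tolerance = 1e-12)
  # identical samples: U = n*m/2 under midranks
  xx <- c(1, 2, 3, 4)
  expect_equal(mann_whitney(xx, xx)$statistic, 8)
})

test_that("Spearman is a Pearson correlation of midranks", {
  expect_equal(spearman(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman(1:10, -(1:10))$statistic, -1)
  set.seed(23)
  x <- sample(1:5, 30, TRUE); y <- x + sample(0:3, 30, TRUE)
  r <- spearman(x, y)
  midrank <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v))
      out[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    out
  }
  expect_equal(r$statistic, stats::cor(midrank(x), midrank(y)),
               tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("BH adjustment: worked example and monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(29)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj <= 1) && all(adj >= p))
})

test_that("over-representation equals hypergeometric enumeration", {
  bg <- sprintf("g%02d", 1:20)
  study <- bg[1:6]
  terms <- list(T1 = bg[1:10], T2 = bg, T3 = c("zz"))
  expect_message(res <- overrepresentation(study, bg, terms), "skipped")
  expect_equal(nrow(res), 2)
  expect_equal(res[term == "T2", p], 1)
  # enumeration oracle for T1: all 6-subsets of the background
  k_obs <- length(intersect(study, terms$T1))
  combs <- utils::combn(20, 6)
  k_null <- apply(combs, 2, function(ix) sum(ix <= 10))
  expect_equal(res[term == "T1", p], mean(k_null >= k_obs), tolerance = 1e-12)
  expect_error(overrepresentation(c("zz"), bg, terms), "subset")
})
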