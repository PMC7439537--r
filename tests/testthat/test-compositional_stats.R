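test_that("CLR transform matches hand computation and its row-sum property", {
  out <- clr_transform(matrix(c(1, 2, 4), 1), pseudocount = 0)
  expect_equal(as.numeric(out), c(-log(2), 0, log(2)))
  expect_equal(as.numeric(clr_transform(matrix(1, 1, 4), pseudocount = 0)),
               rep(0, 4))
  set.seed(1)
  t <- abundance_table(matrix(rpois(60, 40), 5, 12), "counts")
  clr <- clr_transform(t)
  expect_true(all(abs(rowSums(clr)) < 1e-9))
  # scale invariance at delta = 0 on positive data
  m <- matrix(rexp(40) + 0.1, 4, 10)
  expect_equal(unclass(clr_transform(m, 0)), unclass(clr_transform(7 * m, 0)),
               tolerance = 1e-12)
  expect_error(clr_transform(matrix(c(0, 1), 1), pseudocount = 0),
               "nonpositive")
})

test_that("Aitchison distances are Euclidean on CLR rows", {
  m <- rbind(a = c(0, 0), b = c(3, -3))
  d <- aitchison_distance_matrix(m)
  expect_equal(d["a", "b"], sqrt(18))
  expect_equal(unname(diag(d)), c(0, 0))
  # OTU-order permutation invariance
  set.seed(2)
  x <- matrix(rnorm(30), 5)
  expect_equal(aitchison_distance_matrix(x),
               aitchison_distance_matrix(x[, sample(6)]))
  expect_error(aitchison_distance_matrix(rbind(c(1, NA), c(0, 0))),
               "non-finite")
})

test_that("alpha diversity gives closed-form Shannon and richness", {
  t <- abundance_table(rbind(u = c(10, 10, 10, 10), s = c(7, 0, 0, 0),
                             h = c(5, 5, 0, 0)), "counts")
  a <- alpha_diversity(t)
  expect_equal(a$shannon, c(log(4), 0, log(2)))
  expect_equal(a$richness, c(4L, 1L, 2L))
  empty <- abundance_table(rbind(c(1, 1), c(0, 0)), "counts")
  expect_error(alpha_diversity(empty), "empty")
})

test_that("beta dispersion summaries enumerate the right pairs", {
  subjects <- c("S1", "S2", "S3")
  meta <- make_meta(subjects, rep("AX", 3), rep("female", 3),
                    timepoints = c("BL", "W6"))
  set.seed(3)
  clr <- matrix(rnorm(6 * 8), 6, dimnames = list(meta$sample_id, NULL))
  clr["S1_W6", ] <- clr["S1_BL", ]          # identical BL/W6 profile
  d <- aitchison_distance_matrix(clr)
  b <- beta_dispersion_summaries(d, meta)
  expect_equal(sum(b$inter$timepoint == "BL"), choose(3, 2))
  expect_equal(b$intra$distance[b$intra$subject_id == "S1"], 0)
  # subject without baseline is excluded with a warning
  meta2 <- meta[meta$sample_id != "S2_BL", ]
  expect_warning(
    b2 <- beta_dispersion_summaries(d[meta2$sample_id, meta2$sample_id], meta2),
    "S2")
  expect_false("S2" %in% b2$intra$subject_id)
})

test_that("PERMANOVA matches the complete-enumeration oracle on n = 6", {
  set.seed(4)
  # two tight clusters far apart: p attains the resolution floor
  pts <- rbind(matrix(rnorm(6, 0, 0.05), 3), matrix(rnorm(6, 10, 0.05), 3))
  d <- as.matrix(dist(pts))
  labels <- rep(c("a", "b"), each = 3)
  p_exact <- permanova_enumeration_p(d, labels)
  expect_equal(p_exact, 2 / 20)   # 2 of the 20 distinct arrangements tie F_obs
  res <- permanova(d, labels, n_perm = 1999, seed = 5)
  expect_lt(abs(res$p - p_exact), 2 / sqrt(1999))
  # moderate-signal case: permutation p close to the enumeration p
  pts2 <- rbind(matrix(rnorm(6, 0, 1), 3), matrix(rnorm(6, 1.2, 1), 3))
  d2 <- as.matrix(dist(pts2))
  p2_exact <- permanova_enumeration_p(d2, labels)
  res2 <- permanova(d2, labels, n_perm = 1999, seed = 5)
  expect_lt(abs(res2$p - p2_exact), 0.05)
  # relabeling symmetry: identical F
  res3 <- permanova(d, rep(c("b", "a"), each = 3), n_perm = 99, seed = 1)
  expect_equal(res3$pseudo_F, res$pseudo_F)
  expect_error(permanova(matrix(0, 4, 4), rep(c("a", "b"), 2)), "degenerate")
})

test_that("PERMANOVA pseudo-F agrees with vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(6)
  pts <- matrix(rnorm(14 * 5), 14)
  labels <- rep(c("a", "b"), each = 7)
  d <- as.matrix(dist(pts))
  ours <- permanova(d, labels, n_perm = 999, seed = 7)
  ref <- vegan::adonis2(as.dist(d) ~ g, data = data.frame(g = labels),
                        permutations = 999)
  expect_equal(ours$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_lt(abs(ours$p - ref$`Pr(>F)`[1]), 0.06)
})

test_that("rank tests reproduce exact enumeration p values", {
  # strict increase in all 8 pairs (distinct magnitudes so the signed-rank
  # distribution is exact): minimal two-sided p = 2/2^8
  before <- 1:8
  after <- before + (1:8) / 10
  r <- paired_rank_test(before, after)
  expect_equal(r$p, 2 / 2^8)
  expect_equal(r$direction, 1)
  expect_equal(paired_rank_test(after, before)$p, r$p)   # pair-order symmetry
  expect_warning(r0 <- paired_rank_test(1:5, 1:5), "zero")
  expect_equal(r0$p, 1)
  # fully separated 3 vs 3: exact two-sided p = 2/20
  u <- unpaired_rank_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(u$p, 0.1)
  expect_equal(unpaired_rank_test(c(10, 11, 12), c(1, 2, 3))$p, u$p)
  expect_error(unpaired_rank_test(numeric(0), 1:3), "empty")
})

test_that("Friedman + Dunn follows the rank algebra", {
  # columns in identical rank order for every subject: chi^2 = n(k-1)
  set.seed(7)
  m <- cbind(BL = rnorm(10, 0), W1 = rnorm(10, 5) + 20, W6 = rnorm(10, 0) + 40)
  fd <- friedman_dunn(m)
  expect_equal(unname(fd$omnibus$statistic), 10 * 2)
  expect_true(all(fd$pairwise$p <= 1))
  # Dunn z for the extreme pair: (1 - 3) / sqrt(k(k+1)/(6n)) with k=3, n=10
  z13 <- fd$pairwise$z[fd$pairwise$a == "BL" & fd$pairwise$b == "W6"]
  expect_equal(z13, (1 - 3) / sqrt(3 * 4 / 60))
  expect_error(friedman_dunn(m[, 1:2]), "paired_rank_test")
  # identical columns: omnibus p = 1
  same <- matrix(rep(rnorm(6), 3), ncol = 3)
  expect_equal(friedman_dunn(same)$omnibus$p, 1)
})

test_that("bh_fdr equals the step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.02, 0.01, 0.04, 0.03)), rep(0.04, 4))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))
    # monotone in p-rank
    expect_true(all(diff(bh_fdr(p)[order(p)]) > -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("feature test battery is invariant to sample order", {
  set.seed(9)
  x <- matrix(rnorm(80), 16, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[9:16, 1] <- x[9:16, 1] + 3
  f <- function(a, b) unpaired_rank_test(a, b)
  r1 <- feature_test_battery(x, f, 1:8, 9:16)
  perm <- sample(8)
  r2 <- feature_test_battery(x[c(perm, 8 + perm), ], f, 1:8, 9:16)
  expect_equal(r1$p, r2$p)
  expect_true(all(r1$q >= r1$p - 1e-12))
  expect_lt(r1$q[1], 0.05)
})
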