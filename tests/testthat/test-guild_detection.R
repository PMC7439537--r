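test_that("shift matrix is the per-subject CLR difference, antisymmetric", {
  subjects <- c("S1", "S2", "S3")
  meta <- make_meta(subjects, rep("AX", 3), rep("female", 3))
  set.seed(10)
  clr <- matrix(rnorm(9 * 6), 9, dimnames = list(meta$sample_id, paste0("o", 1:6)))
  clr["S2_W6", ] <- clr["S2_BL", ]   # unchanged subject
  s <- compute_shift_matrix(clr, meta, "BL", "W6")
  expect_equal(s["S1", ], clr["S1_W6", ] - clr["S1_BL", ])
  expect_equal(unname(s["S2", ]), rep(0, 6))
  expect_equal(compute_shift_matrix(clr, meta, "W6", "BL"), -s,
               ignore_attr = TRUE)
  # subject missing the endpoint is dropped and counted
  meta2 <- meta[meta$sample_id != "S3_W6", ]
  expect_message(s2 <- compute_shift_matrix(clr, meta2, "BL", "W6"), "1 subject")
  expect_identical(attr(s2, "dropped"), "S3")
  expect_error(compute_shift_matrix(clr, meta[meta$timepoint == "BL", ],
                                    "BL", "W6"), "no subject")
})

test_that("responsiveness screen applies the signed-rank rule", {
  set.seed(11)
  shifts <- cbind(up = abs(rnorm(12)) + 0.2,        # all positive: p = 2/2^12
                  sym = rep(c(-1, 1), 6),           # symmetric: p = 1
                  noise = rnorm(12, 0, 0.05))
  rownames(shifts) <- sprintf("S%02d", 1:12)
  keep <- screen_responsive_otus(shifts, 0.1)
  expect_true("up" %in% keep)
  expect_false("sym" %in% keep)
  expect_warning(none <- screen_responsive_otus(shifts, 1e-12), "no OTU")
  expect_length(none, 0)
})

test_that("1 - rho distance has the stated geometry", {
  set.seed(12)
  v <- rnorm(10)
  shifts <- cbind(a = v, b = v, c = -v, d = rnorm(10))
  cd <- shift_correlation_distance(shifts)
  expect_equal(cd$dist["a", "b"], 0)
  expect_equal(cd$dist["a", "c"], 2)
  expect_equal(cd$dist, t(cd$dist))
  expect_equal(unname(diag(cd$dist)), rep(0, 4))
  expect_error(shift_correlation_distance(cbind(a = v, k = rep(1, 10))), "k")
})

test_that("complete linkage agglomerates by maximum distance", {
  d <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.1
  tree <- complete_linkage_tree(d)
  expect_equal(tree$height, c(0.1, 1.0))
  first <- sort(tree$labels[-tree$merge[1, ]])
  expect_equal(first, c("A", "B"))
  # ultrametric input: cophenetic distances equal the input
  expect_equal(as.matrix(stats::cophenetic(tree))[rownames(d), colnames(d)], d)
  expect_error(complete_linkage_tree(matrix(0, 1, 1)), "2 leaves")
})

test_that("PERMANOVA tree cut recovers planted blocks and stops under the null", {
  set.seed(13)
  shifts <- make_guild_shifts(40, n_guild = 2, per_guild = 10,
                              rho_w = 0.8, rho_b = 0)
  cd <- shift_correlation_distance(shifts)
  tree <- complete_linkage_tree(cd$dist)
  a <- cut_tree_by_permanova(tree, cd$dist, n_perm = 199, seed = 14,
                             shifts = shifts)
  truth <- attr(shifts, "guild")
  expect_equal(adjusted_rand_index(truth[names(a$labels)], a$labels), 1)
  expect_true(all(c("node", "pseudo_F", "p", "decision") %in%
                    names(a$split_log)))
  # homogeneous correlation structure: the root split is almost always
  # rejected (each tested node runs at alpha = 0.05, so a rare false split
  # is by construction)
  k_hom <- vapply(1:10, function(s) {
    set.seed(100 + s)
    hom <- make_guild_shifts(40, n_guild = 1, per_guild = 12, rho_w = 0.5)
    cdh <- shift_correlation_distance(hom)
    ah <- cut_tree_by_permanova(complete_linkage_tree(cdh$dist), cdh$dist,
                                n_perm = 199, seed = 200 + s, shifts = hom)
    length(unique(ah$labels))
  }, numeric(1))
  expect_gte(sum(k_hom == 1), 8)
  # alpha_split = 0 can accept nothing
  a0 <- cut_tree_by_permanova(tree, cd$dist, alpha_split = 0,
                              n_perm = 99, seed = 16, shifts = shifts)
  expect_equal(length(unique(a0$labels)), 1L)
  # same seed reproduces assignments bit-identically
  a2 <- cut_tree_by_permanova(tree, cd$dist, n_perm = 199, seed = 14,
                              shifts = shifts)
  expect_identical(a$labels, a2$labels)
})

test_that("CARG numbering follows descending mean shift and labels partition", {
  set.seed(17)
  shifts <- make_guild_shifts(35, n_guild = 3, per_guild = 6, rho_w = 0.85,
                              effects = c(-1, 2, 0.5))
  cd <- shift_correlation_distance(shifts)
  tree <- complete_linkage_tree(cd$dist)
  a <- cut_tree_by_permanova(tree, cd$dist, n_perm = 199, seed = 18,
                             otu_shift = colMeans(shifts), shifts = shifts)
  expect_setequal(names(a$labels), colnames(shifts))
  carg_means <- tapply(colMeans(shifts)[names(a$labels)], a$labels, mean)
  ord <- carg_means[order(as.integer(sub("CARG", "", names(carg_means))))]
  expect_true(all(diff(ord) < 1e-12))   # CARG1 has the largest mean increase
})

test_that("CARG abundance is the member sum, bounded by closure", {
  rel <- abundance_table(rbind(c(0.01, 0.02, 0.97), c(0.5, 0.25, 0.25)),
                         "relative")
  colnames(rel$values) <- c("o1", "o2", "o3")
  a <- structure(list(labels = c(o1 = "CARG1", o2 = "CARG1", o3 = "CARG2")),
                 class = "carg_assignment")
  cargs <- carg_abundance_table(rel, a)
  expect_equal(unname(cargs$values[1, ]), c(0.03, 0.97))
  expect_true(all(rowSums(cargs$values) <= 1 + 1e-12))
  counts <- abundance_table(rbind(c(1, 2, 3)), "counts")
  expect_error(carg_abundance_table(counts, a), "relative")
})

test_that("co-response network retains planted edges and respects thresholds", {
  set.seed(19)
  v <- rnorm(10)
  shifts <- cbind(a = v, b = v + rnorm(10, 0, 1e-6), c = rnorm(10), d = rnorm(10))
  rownames(shifts) <- sprintf("S%02d", 1:10)
  net <- coresponse_network(shifts, n_perm = 500, seed = 20)
  ab <- net$edges[net$edges$source == "a" & net$edges$target == "b", ]
  expect_equal(ab$rho, 1, tolerance = 1e-9)
  expect_equal(ab$p, min(net$edges$p))  # |rho| = 1 attains the pooled floor
  expect_lt(ab$p, 0.001)
  expect_true(ab$retained)
  # rho threshold beyond 1 empties the network
  net2 <- coresponse_network(shifts, n_perm = 100, rho_threshold = 1.01,
                             seed = 20)
  expect_equal(sum(net2$edges$retained), 0L)
  # edge set shrinks monotonically in the thresholds
  net_loose <- coresponse_network(shifts, n_perm = 500, rho_threshold = 0.3,
                                  q_threshold = 0.2, seed = 20)
  loose <- with(net_loose$edges[net_loose$edges$retained, ],
                paste(source, target))
  tight <- with(net$edges[net$edges$retained, ], paste(source, target))
  expect_true(all(tight %in% loose))
  expect_warning(coresponse_network(cbind(shifts, k = rep(0, 10)),
                                    n_perm = 50, seed = 1), "k")
})

test_that("CARG artifacts export as TSV and valid Newick", {
  set.seed(21)
  shifts <- make_guild_shifts(30, n_guild = 2, per_guild = 5, rho_w = 0.8)
  cd <- shift_correlation_distance(shifts)
  tree <- complete_linkage_tree(cd$dist)
  a <- cut_tree_by_permanova(tree, cd$dist, n_perm = 99, seed = 22,
                             shifts = shifts)
  dir <- withr::local_tempdir()
  paths <- export_carg_artifacts(a, dir = dir)
  tab <- utils::read.delim(file.path(dir, "carg_assignment.tsv"))
  expect_setequal(tab$otu, colnames(shifts))
  nwk <- readLines(file.path(dir, "carg_dendrogram.nwk"))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, tree$labels)
  # cophenetic distances of the Newick equal the dendrogram's
  expect_equal(ape::cophenetic.phylo(phy)[tree$labels, tree$labels],
               as.matrix(stats::cophenetic(tree))[tree$labels, tree$labels],
               tolerance = 1e-4)
})
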