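#' Per-subject CLR shift matrix between two timepoints
#'
#' For each subject with samples at both timepoints, the row is
#' CLR(to_tp) - CLR(from_tp) across OTUs. Subjects missing either timepoint
#' are excluded and reported via the `dropped` attribute.
#'
#' @param clr CLR matrix (samples x OTUs) with sample ids as rownames.
#' @param meta Sample metadata with sample_id, subject_id, timepoint.
#' @param from_tp,to_tp Timepoint labels (e.g. "BL", "W6").
#' @return Numeric matrix subjects x OTUs with attribute `dropped` (subject
#'   ids lacking a timepoint).
#' @export
compute_shift_matrix <- function(clr, meta, from_tp = "BL", to_tp = "W6") {
  m <- unclass(clr)
  subjects <- unique(meta$subject_id)
  rows <- list(); dropped <- character(0)
  for (subj in subjects) {
    sm <- meta[meta$subject_id == subj, ]
    s_from <- sm$sample_id[sm$timepoint == from_tp]
    s_to <- sm$sample_id[sm$timepoint == to_tp]
    if (length(s_from) == 1 && length(s_to) == 1 &&
        all(c(s_from, s_to) %in% rownames(m))) {
      rows[[subj]] <- m[s_to, ] - m[s_from, ]
    } else {
      dropped <- c(dropped, subj)
    }
  }
  if (length(rows) == 0)
    stop(sprintf("no subject has both %s and %s samples", from_tp, to_tp))
  if (length(dropped))
    message(sprintf("compute_shift_matrix: %d subject(s) dropped (missing %s or %s)",
                    length(dropped), from_tp, to_tp))
  out <- do.call(rbind, rows)
  rownames(out) <- names(rows)
  attr(out, "dropped") <- dropped
  out
}

#' Screen OTUs responding to treatment
#'
#' Retains OTUs whose per-subject CLR shifts differ from zero by a
#' two-sided one-sample Wilcoxon signed-rank test at unadjusted
#' p < `alpha_screen`.
#'
#' @param shifts Subjects x OTUs shift matrix.
#' @param alpha_screen Screening significance level (default 0.1,
#'   unadjusted).
#' @return Character vector of retained OTU ids (possibly empty, warned).
#' @export
screen_responsive_otus <- function(shifts, alpha_screen = 0.1) {
  stopifnot(nrow(shifts) >= 5)
  p <- apply(shifts, 2, function(x) {
    nz <- x[x != 0]
    if (length(nz) == 0) return(1)
    suppressWarnings(stats::wilcox.test(nz, mu = 0)$p.value)
  })
  keep <- colnames(shifts)[p < alpha_screen]
  if (length(keep) == 0) warning("no OTU passed the responsiveness screen")
  keep
}

#' Spearman correlation and 1 - rho distance over OTU shifts
#'
#' Correlates the per-subject shift vectors of each OTU pair (average ranks
#' for ties) and converts to the distance 1 - rho in \[0, 2\].
#'
#' @param shifts Subjects x OTUs shift matrix.
#' @param otus OTU ids to include (default: all columns).
#' @return list: `rho` (correlation matrix), `dist` (1 - rho, zero
#'   diagonal).
#' @export
shift_correlation_distance <- function(shifts, otus = colnames(shifts)) {
  x <- shifts[, otus, drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 subjects")
  if (ncol(x) < 2) stop("need at least 2 OTUs")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant shift vector for OTU(s): %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  rho <- stats::cor(x, method = "spearman")
  d <- 1 - rho
  diag(d) <- 0
  list(rho = rho, dist = d)
}

#' Complete-linkage dendrogram over OTUs
#'
#' Agglomerative clustering with maximum linkage on a distance matrix;
#' ids ordered lexicographically beforehand so ties break deterministically.
#'
#' @param d Square distance matrix over OTUs.
#' @return An `hclust` object (leaves labelled by OTU id).
#' @export
complete_linkage_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least 2 leaves")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Cut a dendrogram into CARGs by recursive PERMANOVA
#'
#' Top-down traversal of the complete-linkage tree: at each internal node
#' the two child clusters are compared by a PERMANOVA pseudo-F on the
#' OTU-level distance matrix; a significant split (p < `alpha_split`) is
#' accepted and traversal recurses into children with >= 2 members,
#' otherwise the node's leaves are emitted as one co-abundance response
#' group (CARG). A singleton produced by an accepted split becomes its own
#' CARG; a 1-vs-1 node is never tested and is emitted as a single 2-member
#' CARG. CARGs are numbered CARG1..CARGk by descending mean member shift
#' when `otu_shift` is supplied (CARG1 = strongest mean increase), else by
#' tree order.
#'
#' Null distribution: because the two children were themselves picked by
#' the clustering to maximise separation, permuting OTU group labels alone
#' is anti-conservative (it would split even exchangeable OTUs). When
#' `shifts` is supplied, each node is instead tested against the "one
#' guild" hypothesis of exchangeable correlation at the node's own mean
#' Spearman rho: every Monte Carlo replicate draws that many exchangeable
#' shift vectors, rebuilds the 1 - rho distance matrix and its
#' complete-linkage tree, and scores that null tree's own root split —
#' the same selection step the observed statistic went through. Without
#' `shifts` the plain label-permutation null is used (and over-splits
#' correlated data; a warning is issued).
#'
#' @param tree `hclust` over the screened OTUs.
#' @param d The distance matrix the tree was built from.
#' @param alpha_split Split acceptance level (default 0.05, uncorrected).
#' @param n_perm Permutations per node test.
#' @param seed RNG seed.
#' @param otu_shift Optional named vector of mean CLR shift per OTU, used
#'   for CARG numbering.
#' @param shifts Subjects x OTUs shift matrix used to generate the
#'   selection-aware permutation null (recommended).
#' @return list of class `carg_assignment`: `labels` (named character
#'   vector OTU -> CARG), `split_log` (data.frame node, n_left, n_right,
#'   pseudo_F, p, decision), `tree`.
#' @export
cut_tree_by_permanova <- function(tree, d, alpha_split = 0.05,
                                  n_perm = 999, seed = 1L,
                                  otu_shift = NULL, shifts = NULL) {
  d <- as.matrix(d)
  stopifnot(setequal(tree$labels, rownames(d)))
  if (is.null(shifts)) {
    warning("no shift matrix supplied: label-permutation null is ",
            "anti-conservative for correlated OTUs")
  } else {
    stopifnot(all(tree$labels %in% colnames(shifts)))
  }
  merge <- tree$merge
  n_leaf <- length(tree$labels)
  # leaf sets per internal node
  members <- vector("list", nrow(merge))
  node_leaves <- function(id) {
    if (id < 0) tree$labels[-id] else members[[id]]
  }
  for (i in seq_len(nrow(merge)))
    members[[i]] <- c(node_leaves(merge[i, 1]), node_leaves(merge[i, 2]))

  set.seed(as.integer(seed))
  groups <- list()
  log_rows <- list()
  emit <- function(leaves) groups[[length(groups) + 1]] <<- leaves
  recurse <- function(node) {
    if (node < 0) { emit(tree$labels[-node]); return(invisible()) }
    left <- node_leaves(merge[node, 1])
    right <- node_leaves(merge[node, 2])
    if (length(left) == 1 && length(right) == 1) {
      # 1-vs-1: PERMANOVA degenerate, never tested
      emit(c(left, right))
      log_rows[[length(log_rows) + 1]] <<- data.frame(
        node = node, n_left = 1L, n_right = 1L, pseudo_F = NA_real_,
        p = NA_real_, decision = "untested_1v1", stringsAsFactors = FALSE)
      return(invisible())
    }
    ids <- c(left, right)
    labels <- c(rep("L", length(left)), rep("R", length(right)))
    if (is.null(shifts)) {
      res <- suppressWarnings(
        permanova(d[ids, ids], labels, n_perm = n_perm,
                  seed = sample.int(.Machine$integer.max, 1)))
      f_obs <- res$pseudo_F; p_val <- res$p
    } else {
      sub <- d[ids, ids]
      f_obs <- permanova_F(sub^2, as.integer(factor(labels)))
      rho_bar <- mean(1 - sub[upper.tri(sub)])
      p_val <- node_null_p(nrow(shifts), length(ids), rho_bar, f_obs, n_perm)
    }
    accept <- p_val < alpha_split
    log_rows[[length(log_rows) + 1]] <<- data.frame(
      node = node, n_left = length(left), n_right = length(right),
      pseudo_F = f_obs, p = p_val,
      decision = if (accept) "split" else "stop", stringsAsFactors = FALSE)
    if (accept) {
      recurse(merge[node, 1])
      recurse(merge[node, 2])
    } else {
      emit(ids)
    }
  }
  if (n_leaf == 1) {
    groups <- list(tree$labels)
  } else {
    recurse(nrow(merge))
  }

  # number CARGs by descending mean member shift
  if (!is.null(otu_shift)) {
    means <- vapply(groups, function(g) mean(otu_shift[g]), numeric(1))
    groups <- groups[order(means, decreasing = TRUE)]
  }
  labels <- character(0)
  for (i in seq_along(groups))
    labels[groups[[i]]] <- paste0("CARG", i)
  labels <- labels[tree$labels]
  split_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(node = integer(0), n_left = integer(0), n_right = integer(0),
               pseudo_F = numeric(0), p = numeric(0), decision = character(0))
  structure(list(labels = labels, split_log = split_log, tree = tree,
                 alpha_split = alpha_split),
            class = "carg_assignment")
}

#' @export
print.carg_assignment <- function(x, ...) {
  k <- length(unique(x$labels))
  cat(sprintf("CARG assignment: %d OTUs in %d CARG(s) (split alpha = %g)\n",
              length(x$labels), k, x$alpha_split))
  print(table(x$labels))
  invisible(x)
}

# Selection-aware node null: the "one guild" hypothesis is exchangeable
# correlation at the node's own mean Spearman rho. Each Monte Carlo draw
# generates m such shift vectors, rebuilds the 1 - rho distance and its
# complete-linkage tree, and scores that null tree's own best (root)
# split — the same selection step the observed statistic went through.
node_null_p <- function(n_subj, m, rho_bar, f_obs, n_perm) {
  r_p <- 2 * sin(pi * max(0, min(rho_bar, 0.99)) / 6)  # Spearman -> Pearson
  count <- 0L
  for (b in seq_len(n_perm)) {
    g <- stats::rnorm(n_subj)
    x <- sqrt(r_p) * g + sqrt(1 - r_p) * matrix(stats::rnorm(n_subj * m), n_subj)
    rk <- apply(x, 2, rank)
    db <- 1 - stats::cor(rk)
    diag(db) <- 0
    hb <- stats::hclust(stats::as.dist(db), method = "complete")
    fb <- permanova_F(db^2, stats::cutree(hb, k = 2))
    if (fb >= f_obs - 1e-12) count <- count + 1L
  }
  (1 + count) / (n_perm + 1)
}

#' Aggregate relative abundance per CARG
#'
#' CARG abundance per sample is the sum of its member OTUs' relative
#' abundances (computed prior to any statistics, matching the guild-level
#' convention). OTUs absent from the assignment are ignored.
#'
#' @param t Relative-mode [abundance_table()].
#' @param assignment A `carg_assignment`.
#' @return An [abundance_table()] over CARGs; rows are not re-closed so
#'   each CARG total stays bounded by 1.
#' @export
carg_abundance_table <- function(t, assignment) {
  stopifnot(inherits(t, "abundance_table"))
  if (t$mode != "relative") stop("carg_abundance_table requires relative mode")
  labels <- assignment$labels
  cargs <- sort(unique(labels))
  out <- sapply(cargs, function(cg) {
    members <- intersect(names(labels)[labels == cg], otu_ids(t))
    if (length(members) == 0) stop(sprintf("CARG %s has no member in table", cg))
    rowSums(t$values[, members, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(t$values),
                dimnames = list(sample_ids(t), cargs))
  structure(list(values = out, mode = "carg_relative", taxonomy = NULL),
            class = "abundance_table")
}

#' Permutation-tested Spearman co-response network
#'
#' For every OTU pair, Spearman rho between per-subject shift vectors with
#' a permutation p value (subject order of one member permuted `n_perm`
#' times), BH-FDR across all pairs, and edge retention at
#' |rho| >= `rho_threshold` AND q < `q_threshold`.
#'
#' Because Spearman's null distribution is distribution-free — it depends
#' only on the number of subjects, identically for every pair — the null
#' draws of all pairs are pooled: p = (1 + #\{pooled |rho*| >= |rho|\}) /
#' (N + 1) with N = `n_perm` times the number of null statistics per
#' permutation. Per-pair counting at 1000 permutations has a 1/1001
#' resolution floor that BH across hundreds of pairs can rarely clear;
#' pooling gives the fine-grained p values a q < 0.05 edge set requires.
#'
#' @param shifts Subjects x OTUs shift matrix.
#' @param otus OTU ids to include (default all).
#' @param n_perm Permutations (default 1000).
#' @param rho_threshold Absolute correlation cut-off (default 0.5).
#' @param q_threshold FDR cut-off (default 0.05).
#' @param seed RNG seed.
#' @return list of class `coresponse_network`: `edges` (data.frame source,
#'   target, rho, p, q, retained), `nodes` (otu, mean_shift, direction).
#' @export
coresponse_network <- function(shifts, otus = colnames(shifts),
                               n_perm = 1000, rho_threshold = 0.5,
                               q_threshold = 0.05, seed = 1L) {
  x <- shifts[, otus, drop = FALSE]
  n <- nrow(x)
  if (n < 5) stop("need at least 5 subjects")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("constant shift vector(s) skipped: %s",
                    paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  p_otu <- ncol(x)
  if (p_otu < 2) stop("fewer than 2 usable OTUs")
  r <- apply(x, 2, rank)
  obs <- stats::cor(r)  # Pearson on ranks = Spearman with average ranks
  ut <- which(upper.tri(obs), arr.ind = TRUE)
  obs_abs <- abs(obs[ut])
  set.seed(as.integer(seed))
  count_ge <- numeric(length(obs_abs))
  n_null <- 0
  off <- row(obs) != col(obs)
  for (b in seq_len(n_perm)) {
    perm <- stats::cor(r[sample.int(n), , drop = FALSE], r)
    v <- sort(abs(perm[off]))
    count_ge <- count_ge + (length(v) - findInterval(obs_abs - 1e-12, v))
    n_null <- n_null + length(v)
  }
  edges <- data.frame(
    source = colnames(x)[ut[, 1]], target = colnames(x)[ut[, 2]],
    rho = obs[ut], p = (1 + count_ge) / (n_null + 1),
    stringsAsFactors = FALSE)
  edges$q <- bh_fdr(edges$p)
  edges$retained <- abs(edges$rho) >= rho_threshold & edges$q < q_threshold
  nodes <- data.frame(otu = colnames(x), mean_shift = colMeans(x),
                      direction = sign(colMeans(x)), row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, n_perm = n_perm,
                 rho_threshold = rho_threshold, q_threshold = q_threshold),
            class = "coresponse_network")
}

#' @export
print.coresponse_network <- function(x, ...) {
  cat(sprintf("co-response network: %d nodes, %d/%d edges retained (|rho|>=%g, q<%g)\n",
              nrow(x$nodes), sum(x$edges$retained), nrow(x$edges),
              x$rho_threshold, x$q_threshold))
  invisible(x)
}

#' Export CARG artifacts
#'
#' Writes the assignment as a two-column TSV, the dendrogram as Newick
#' (merge heights as branch lengths), and the retained network edges as a
#' TSV ready for network viewers.
#'
#' @param assignment A `carg_assignment`.
#' @param network Optional `coresponse_network`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
export_carg_artifacts <- function(assignment, network = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p1 <- file.path(dir, "carg_assignment.tsv")
  utils::write.table(
    data.frame(otu = names(assignment$labels), carg = unname(assignment$labels)),
    p1, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p1)
  p2 <- file.path(dir, "carg_dendrogram.nwk")
  writeLines(hclust_to_newick(assignment$tree), p2)
  paths <- c(paths, p2)
  if (!is.null(network)) {
    p3 <- file.path(dir, "network_edges.tsv")
    utils::write.table(network$edges[network$edges$retained,
                                     c("source", "target", "rho", "q")],
                       p3, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

hclust_to_newick <- function(h) {
  # halved branch lengths make leaf-to-leaf path length equal the merge
  # height, i.e. the tree's cophenetic distances
  build <- function(id, parent_h) {
    if (id < 0) {
      sprintf("%s:%.6g", h$labels[-id], parent_h / 2)
    } else {
      hh <- h$height[id]
      sprintf("(%s,%s):%.6g", build(h$merge[id, 1], hh),
              build(h$merge[id, 2], hh), (parent_h - hh) / 2)
    }
  }
  root <- nrow(h$merge)
  sprintf("(%s,%s);", build(h$merge[root, 1], h$height[root]),
          build(h$merge[root, 2], h$height[root]))
}
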