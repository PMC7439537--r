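#' Centered log-ratio transform
#'
#' Maps each sample's composition to unconstrained log-ratio coordinates:
#' row i, OTU j becomes ln((x_ij + delta) / g_i) with g_i the geometric mean
#' of the adjusted row. Corrects for the unit-sum constraint of relative
#' abundance data; every output row sums to zero.
#'
#' Zero handling: for counts a pseudocount `pseudocount` is added to every
#' cell. For relative data the pseudocount is interpreted as a
#' count-equivalent at sequencing depth `depth` (i.e. `pseudocount/depth` is
#' added before the log).
#'
#' @param t An [abundance_table()] or a plain numeric matrix (samples x
#'   OTUs, treated as counts).
#' @param pseudocount Additive pseudocount on the count scale (default 0.5).
#' @param depth Assumed sequencing depth used to convert the pseudocount
#'   for relative-mode input (default 16000).
#' @return A numeric matrix of class `clr_matrix` with the input dimnames.
#' @examples
#' clr_transform(matrix(c(1, 2, 4), 1), pseudocount = 0)  # -ln2, 0, ln2
#' @export
clr_transform <- function(t, pseudocount = 0.5, depth = 16000) {
  if (inherits(t, "abundance_table")) {
    delta <- if (t$mode == "counts") pseudocount else pseudocount / depth
    v <- t$values + delta
  } else {
    v <- as.matrix(t) + pseudocount
  }
  if (any(v <= 0)) stop("nonpositive value after pseudocount adjustment")
  lv <- log(v)
  out <- lv - rowMeans(lv)
  class(out) <- c("clr_matrix", class(out))
  out
}

#' Aitchison distance matrix
#'
#' Pairwise Euclidean distance between CLR-transformed samples; the natural
#' metric on compositions.
#'
#' @param c A matrix of CLR coordinates (samples in rows).
#' @return A symmetric `dist`-backed square matrix with zero diagonal.
#' @export
aitchison_distance_matrix <- function(c) {
  m <- unclass(c)
  if (any(!is.finite(m))) stop("non-finite value in CLR matrix")
  if (nrow(m) < 2) stop("need at least 2 samples")
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Per-sample alpha diversity
#'
#' Shannon index (natural log) over nonzero proportions and richness (number
#' of OTUs with abundance > 0).
#'
#' @param t An [abundance_table()] (counts or relative).
#' @return data.frame with columns sample_id, shannon, richness.
#' @export
alpha_diversity <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  v <- t$values
  rs <- rowSums(v)
  if (any(rs == 0)) stop("empty sample")
  p <- v / rs
  shannon <- apply(p, 1, function(r) {
    r <- r[r > 0]
    -sum(r * log(r))
  })
  data.frame(sample_id = sample_ids(t), shannon = shannon,
             richness = as.integer(rowSums(v > 0)), row.names = NULL)
}

#' Inter- and intra-subject community dissimilarities
#'
#' Inter: all unordered sample pairs within the same arm and timepoint.
#' Intra: for each subject, the distance from baseline to each treatment
#' timepoint. Subjects missing baseline are excluded with a warning.
#'
#' @param d Square distance matrix with sample ids as dimnames.
#' @param meta Sample metadata (see [validate_metadata()]).
#' @param baseline Baseline timepoint label.
#' @return list with data.frames `inter` (arm, timepoint, sample_a,
#'   sample_b, distance) and `intra` (subject_id, arm, timepoint, distance).
#' @export
beta_dispersion_summaries <- function(d, meta, baseline = "BL") {
  stopifnot(all(meta$sample_id %in% rownames(d)))
  inter <- list()
  for (arm in unique(meta$arm)) for (tp in unique(meta$timepoint)) {
    ids <- meta$sample_id[meta$arm == arm & meta$timepoint == tp]
    if (length(ids) < 2) {
      if (length(ids) == 1)
        warning(sprintf("arm %s at %s has a single subject; no inter pairs",
                        arm, tp))
      next
    }
    pr <- utils::combn(ids, 2)
    inter[[length(inter) + 1]] <- data.frame(
      arm = arm, timepoint = tp, sample_a = pr[1, ], sample_b = pr[2, ],
      distance = d[cbind(pr[1, ], pr[2, ])], stringsAsFactors = FALSE)
  }
  intra <- list()
  for (subj in unique(meta$subject_id)) {
    rows <- meta[meta$subject_id == subj, ]
    bl <- rows$sample_id[rows$timepoint == baseline]
    if (length(bl) != 1) {
      warning(sprintf("subject %s lacks a %s sample; excluded from intra",
                      subj, baseline))
      next
    }
    other <- rows[rows$timepoint != baseline, ]
    if (nrow(other) == 0) next
    intra[[length(intra) + 1]] <- data.frame(
      subject_id = subj, arm = rows$arm[1], timepoint = other$timepoint,
      distance = d[bl, other$sample_id], stringsAsFactors = FALSE)
  }
  list(inter = do.call(rbind, inter), intra = do.call(rbind, intra))
}

permanova_ss <- function(d2, groups) {
  # d2: squared distances; groups: integer labels
  n <- nrow(d2)
  ut <- upper.tri(d2)
  ss_total <- sum(d2[ut]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within)
}

permanova_F <- function(d2, groups) {
  n <- nrow(d2)
  g <- length(unique(groups))
  ss <- permanova_ss(d2, groups)
  ss_between <- ss["total"] - ss["within"]
  unname((ss_between / (g - 1)) / (ss["within"] / (n - g)))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F on a distance matrix with a free permutation null:
#' F = [SS_between/(g-1)] / [SS_within/(N-g)], SS_total computed from squared
#' distances, p = (1 + #\{F* >= F\}) / (n_perm + 1).
#'
#' @param d Square symmetric distance matrix.
#' @param labels Grouping vector, length nrow(d).
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed.
#' @param exact For two groups and small n, enumerate all distinct label
#'   assignments instead of sampling; p is then the exact proportion of
#'   assignments with F* >= F (observed included).
#' @return list of class `permanova_result`: pseudo_F, p, n_perm,
#'   group_sizes.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L, exact = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (max(sizes) < 2) stop("at least one group must have size >= 2")
  if (all(d[upper.tri(d)] == 0)) stop("degenerate matrix: all distances zero")
  d2 <- d^2
  groups <- as.integer(factor(labels))
  f_obs <- permanova_F(d2, groups)
  if (exact) {
    if (length(sizes) != 2) stop("exact enumeration implemented for 2 groups")
    n1 <- sum(groups == 1)
    if (choose(n, n1) > 1e5) stop("too many assignments for exact enumeration")
    assignments <- utils::combn(n, n1)
    fs <- apply(assignments, 2, function(ix) {
      g <- rep(2L, n); g[ix] <- 1L
      permanova_F(d2, g)
    })
    p <- mean(fs >= f_obs - 1e-12)
    n_perm <- ncol(assignments)
  } else {
    set.seed(as.integer(seed))
    count <- 0L
    for (b in seq_len(n_perm)) {
      f_perm <- permanova_F(d2, groups[sample.int(n)])
      if (f_perm >= f_obs) count <- count + 1L
    }
    p <- (1 + count) / (n_perm + 1)
  }
  structure(list(pseudo_F = f_obs, p = p,
                 n_perm = n_perm, group_sizes = as.vector(sizes),
                 groups = names(sizes)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, p = %.4g (%d permutations; n = %s)\n",
              x$pseudo_F, x$p, x$n_perm,
              paste(x$group_sizes, collapse = "+")))
  invisible(x)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' @param x_before,x_after Paired numeric vectors.
#' @return list: statistic, p, n (pairs with nonzero difference), direction
#'   (sign of the median difference).
#' @export
paired_rank_test <- function(x_before, x_after) {
  stopifnot(length(x_before) == length(x_after))
  keep <- stats::complete.cases(x_before, x_after)
  diffs <- x_after[keep] - x_before[keep]
  nz <- diffs[diffs != 0]
  if (length(nz) == 0) {
    warning("all differences zero; p = 1")
    return(list(statistic = NA_real_, p = 1, n = 0L, direction = 0))
  }
  ht <- suppressWarnings(stats::wilcox.test(nz, mu = 0, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n = length(nz), direction = sign(stats::median(nz)))
}

#' Unpaired two-sided Mann-Whitney test
#'
#' @param x_a,x_b Numeric vectors (independent groups).
#' @return list: statistic (U), p, n per group, direction.
#' @export
unpaired_rank_test <- function(x_a, x_b) {
  x_a <- x_a[!is.na(x_a)]; x_b <- x_b[!is.na(x_b)]
  if (length(x_a) == 0 || length(x_b) == 0) stop("empty group")
  ht <- suppressWarnings(stats::wilcox.test(x_a, x_b, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n = c(length(x_a), length(x_b)),
       direction = sign(stats::median(x_a) - stats::median(x_b)))
}

#' Friedman omnibus test with Dunn-corrected pairwise comparisons
#'
#' Omnibus chi-squared over k >= 3 repeated measures (complete cases only),
#' then pairwise Dunn z statistics z = (Rbar_i - Rbar_j) / sqrt(k(k+1)/(6n))
#' with Bonferroni multiplication over the k(k-1)/2 pairs, capped at 1.
#'
#' @param m Numeric matrix, subjects x k timepoints (k >= 3), column names
#'   label the timepoints.
#' @return list: `omnibus` (statistic, df, p, n) and `pairwise` data.frame
#'   (a, b, z, p_unadj, p).
#' @export
friedman_dunn <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 3)
    stop("k < 3: use paired_rank_test for two timepoints")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2) stop("need at least 2 complete subjects")
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(k))
  ht <- stats::friedman.test(m)
  if (is.nan(ht$statistic)) {  # fully tied rows: no evidence of difference
    ht$statistic[] <- 0
    ht$p.value <- 1
  }
  ranks <- t(apply(m, 1, rank))
  rbar <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  pw <- data.frame(
    a = colnames(m)[pairs[1, ]], b = colnames(m)[pairs[2, ]],
    z = (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se,
    stringsAsFactors = FALSE)
  pw$p_unadj <- 2 * stats::pnorm(-abs(pw$z))
  pw$p <- pmin(1, pw$p_unadj * n_pairs)
  list(omnibus = list(statistic = unname(ht$statistic),
                      df = unname(ht$parameter), p = ht$p.value, n = n),
       pairwise = pw)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q values: q_(i) = min over j >= i of m * p_(j) / j,
#' returned in the input order. Monotone in p-rank.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @return Vector of q values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(1, q_sorted)
  q
}

#' Run a battery of per-feature tests with FDR
#'
#' Applies a two-group or paired test per feature (column) and appends BH
#' q values across the battery.
#'
#' @param x Numeric matrix, observations x features.
#' @param f A function (column_a, column_b) -> list(statistic, p, direction),
#'   e.g. built on [paired_rank_test()].
#' @param a_rows,b_rows Row indices for the two conditions.
#' @return data.frame: feature, statistic, p, q, direction.
#' @export
feature_test_battery <- function(x, f, a_rows, b_rows) {
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("F", seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(j) {
    r <- f(x[a_rows, j], x[b_rows, j])
    data.frame(feature = feats[j], statistic = r$statistic %||% NA_real_,
               p = r$p, direction = r$direction %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out[, c("feature", "statistic", "p", "q", "direction")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
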