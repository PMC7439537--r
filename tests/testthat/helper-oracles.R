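# Independent oracles and fixture builders used across the suite.

# Shift matrix with planted guilds: subjects x (n_guild * per_guild) matrix,
# within-guild correlation rho_w, between-guild rho_b, optional per-guild
# mean effect so screening retains the OTUs.
make_guild_shifts <- function(n_subjects, n_guild = 4, per_guild = 10,
                              rho_w = 0.8, rho_b = 0, effects = NULL) {
  z0 <- rnorm(n_subjects)
  zg <- matrix(rnorm(n_subjects * n_guild), n_subjects)
  n_otu <- n_guild * per_guild
  guild <- rep(seq_len(n_guild), each = per_guild)
  shifts <- sapply(seq_len(n_otu), function(j) {
    g <- guild[j]
    base <- sqrt(rho_b) * z0 + sqrt(rho_w - rho_b) * zg[, g] +
      sqrt(1 - rho_w) * rnorm(n_subjects)
    if (!is.null(effects)) base + effects[g] else base
  })
  colnames(shifts) <- sprintf("OTU%03d", seq_len(n_otu))
  rownames(shifts) <- sprintf("S%02d", seq_len(n_subjects))
  attr(shifts, "guild") <- setNames(guild, colnames(shifts))
  shifts
}

# Complete-enumeration PERMANOVA oracle: exact p over all label
# rearrangements (distinct permutations of the multiset of labels).
permanova_enumeration_p <- function(d, labels) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  f_of <- function(lab) {
    groups <- unique(lab)
    ut <- upper.tri(d2)
    ss_total <- sum(d2[ut]) / n
    ss_within <- 0
    for (g in groups) {
      idx <- which(lab == g)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ((ss_total - ss_within) / (length(groups) - 1)) /
      (ss_within / (n - length(groups)))
  }
  f_obs <- f_of(labels)
  perms <- combinat_perms(labels)
  fs <- apply(perms, 1, f_of)
  mean(fs >= f_obs - 1e-12)
}

# all distinct arrangements of a label vector (small n only)
combinat_perms <- function(labels) {
  n <- length(labels)
  idx_perms <- permutations_of(seq_len(n))
  m <- t(apply(idx_perms, 1, function(ix) labels[ix]))
  unique(m)
}

permutations_of <- function(v) {
  if (length(v) == 1) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# Brute-force BH definition: q_i = min over j with p_j >= p_i of m*p_j/rank_j
bh_bruteforce <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    j <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[j] / r[j]))
  }, numeric(1))
}

# Pair-counting ARI oracle (direct contingency-free definition)
ari_bruteforce <- function(a, b) {
  n <- length(a)
  pairs <- combn(n, 2)
  sa <- a[pairs[1, ]] == a[pairs[2, ]]
  sb <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(sa & sb); n00 <- sum(!sa & !sb)
  n10 <- sum(sa & !sb); n01 <- sum(!sa & sb)
  np <- ncol(pairs)
  expected <- (n11 + n10) * (n11 + n01) / np
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == expected) return(1)
  (n11 - expected) / (max_idx - expected)
}

# Exhaustive best-subset oracle (sizes 1-2, adjusted R^2, same covariate)
exhaustive_subset <- function(y, block, covariate) {
  feats <- colnames(block)
  score <- function(subset) {
    X <- block[, subset, drop = FALSE]
    if (!is.null(covariate)) X <- cbind(cv = covariate, X)
    summary(lm(y ~ ., data = data.frame(y = y, X)))$adj.r.squared
  }
  cand <- c(as.list(feats), combn(feats, 2, simplify = FALSE))
  r2 <- vapply(cand, score, numeric(1))
  sort(cand[[which.max(r2)]])
}

# tiny metadata builder
make_meta <- function(subjects, arms, sexes, timepoints = c("BL", "W1", "W6")) {
  design <- study_design()
  do.call(rbind, lapply(timepoints, function(tp) {
    data.frame(sample_id = paste(subjects, tp, sep = "_"),
               subject_id = subjects, arm = arms, sex = sexes,
               dose = unname(design$dose_by_sex[sexes]), timepoint = tp,
               stringsAsFactors = FALSE)
  }))
}
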