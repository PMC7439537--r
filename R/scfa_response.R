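#' Derived SCFA measures for one sample
#'
#' Total SCFA is the sum of acetate, propionate and butyrate (micromol/g);
#' the percent of each is its share of that total; the
#' propionate:butyrate ratio is undefined (NA, warned) when butyrate is 0;
#' total branched SCFA is isobutyrate + isovalerate.
#'
#' @param acetate,propionate,butyrate,isobutyrate,isovalerate
#'   Concentrations, micromol/g wet feces.
#' @return list: total_scfa, pct_acetate, pct_propionate, pct_butyrate,
#'   prop_to_but_ratio, total_bscfa.
#' @export
derive_scfa_measures <- function(acetate, propionate, butyrate,
                                 isobutyrate = 0, isovalerate = 0) {
  stopifnot(acetate >= 0, propionate >= 0, butyrate >= 0,
            isobutyrate >= 0, isovalerate >= 0)
  total <- acetate + propionate + butyrate
  if (total == 0) stop("total SCFA is zero")
  ratio <- if (butyrate > 0) propionate / butyrate else {
    warning("butyrate is zero; propionate:butyrate ratio undefined")
    NA_real_
  }
  list(total_scfa = total,
       pct_acetate = 100 * acetate / total,
       pct_propionate = 100 * propionate / total,
       pct_butyrate = 100 * butyrate / total,
       prop_to_but_ratio = ratio,
       total_bscfa = isobutyrate + isovalerate)
}

#' Derived SCFA measures for a sample table
#'
#' Vectorised wrapper around [derive_scfa_measures()] for a data.frame as
#' returned by [read_scfa_table()].
#'
#' @param scfa data.frame with sample_id and the five SCFA columns.
#' @return data.frame of derived measures keyed by sample_id.
#' @export
derive_scfa_table <- function(scfa) {
  out <- lapply(seq_len(nrow(scfa)), function(i) {
    d <- withCallingHandlers(
      derive_scfa_measures(scfa$acetate[i], scfa$propionate[i],
                           scfa$butyrate[i], scfa$isobutyrate[i],
                           scfa$isovalerate[i]),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(sample_id = scfa$sample_id[i], as.data.frame(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify a subject's temporal propionate response
#'
#' A subject is a W6-responder when fecal propionate keeps rising late in
#' the intervention (Delta W6 - W1 > 0), a W6-nonresponder when it declines
#' (Delta < 0), and indeterminate on an exact tie. Baseline is carried for
#' reporting only; the rule is scale-invariant.
#'
#' @param propionate_bl,propionate_w1,propionate_w6 Concentrations,
#'   micromol/g.
#' @return list: label in {"W6-responder", "W6-nonresponder",
#'   "indeterminate"}, delta_w6_w1, baseline.
#' @export
classify_w6_responder <- function(propionate_bl, propionate_w1,
                                  propionate_w6) {
  if (any(is.na(c(propionate_bl, propionate_w1, propionate_w6)))) {
    warning("missing timepoint; responder label indeterminate")
    return(list(label = "indeterminate", delta_w6_w1 = NA_real_,
                baseline = propionate_bl))
  }
  delta <- propionate_w6 - propionate_w1
  label <- if (delta > 0) "W6-responder"
           else if (delta < 0) "W6-nonresponder"
           else "indeterminate"
  list(label = label, delta_w6_w1 = delta, baseline = propionate_bl)
}

#' Responder labels for a cohort
#'
#' @param scfa data.frame with sample_id, propionate.
#' @param meta Sample metadata (sample_id, subject_id, timepoint).
#' @param timepoints Labels for baseline, week 1 and week 6.
#' @return data.frame: subject_id, label, delta_w6_w1, baseline.
#' @export
classify_cohort_responders <- function(scfa, meta,
                                       timepoints = c("BL", "W1", "W6")) {
  prop <- stats::setNames(scfa$propionate, scfa$sample_id)
  out <- lapply(unique(meta$subject_id), function(subj) {
    sm <- meta[meta$subject_id == subj, ]
    get <- function(tp) {
      sid <- sm$sample_id[sm$timepoint == tp]
      if (length(sid) == 1 && sid %in% names(prop)) prop[[sid]] else NA_real_
    }
    r <- suppressWarnings(
      classify_w6_responder(get(timepoints[1]), get(timepoints[2]),
                            get(timepoints[3])))
    data.frame(subject_id = subj, label = r$label,
               delta_w6_w1 = r$delta_w6_w1, baseline = r$baseline,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare SCFA trajectories between responder groups
#'
#' Within each group: Friedman omnibus + Dunn pairwise over the timepoints.
#' Between groups: Mann-Whitney at each timepoint. Groups below the minimum
#' size are skipped with a message; indeterminate subjects are excluded.
#'
#' @param labels data.frame from [classify_cohort_responders()].
#' @param values Matrix subjects x timepoints of the SCFA measure (rownames
#'   = subject ids, colnames = timepoint labels).
#' @param min_n Minimum group size for a test (default 3).
#' @return list: `within` (per-group friedman_dunn results), `between`
#'   (data.frame timepoint, statistic, p, q).
#' @export
responder_group_comparison <- function(labels, values, min_n = 3) {
  labels <- labels[labels$label != "indeterminate", ]
  grp <- split(labels$subject_id, labels$label)
  within <- list()
  for (g in names(grp)) {
    ids <- intersect(grp[[g]], rownames(values))
    if (length(ids) < min_n) {
      message(sprintf("group %s too small (n=%d); within-group test skipped",
                      g, length(ids)))
      next
    }
    within[[g]] <- friedman_dunn(values[ids, , drop = FALSE])
  }
  between <- NULL
  if (length(grp) == 2 && all(lengths(grp) >= min_n)) {
    a <- intersect(grp[[1]], rownames(values))
    b <- intersect(grp[[2]], rownames(values))
    rows <- lapply(colnames(values), function(tp) {
      r <- unpaired_rank_test(values[a, tp], values[b, tp])
      data.frame(timepoint = tp, statistic = r$statistic, p = r$p,
                 stringsAsFactors = FALSE)
    })
    between <- do.call(rbind, rows)
    between$q <- bh_fdr(between$p)
  } else {
    message("between-group tests skipped (need two groups of adequate size)")
  }
  list(within = within, between = between)
}

#' Area under a weekly stool-diary curve
#'
#' Linear trapezoid over the 7 weekly scores (baseline through week 6,
#' unit spacing): AUC = sum over t of (s_t + s_{t+1}) / 2. Interior missing
#' weeks are linearly interpolated; a missing endpoint is an error. Scores
#' are 0-4 hedonic, so with 7 points AUC lies in \[0, 24\].
#'
#' @param scores Numeric vector of 7 weekly scores (BL, W1..W6).
#' @return The AUC (score x weeks).
#' @export
hedonic_auc <- function(scores) {
  if (length(scores) != 7) stop("expected 7 weekly scores (BL..W6)")
  if (is.na(scores[1]) || is.na(scores[7]))
    stop("missing endpoint score; cannot extrapolate")
  if (anyNA(scores)) {
    ok <- which(!is.na(scores))
    scores <- stats::approx(ok, scores[ok], xout = seq_along(scores))$y
  }
  if (any(scores < 0 | scores > 4)) stop("scores must lie in [0, 4]")
  sum((scores[-7] + scores[-1]) / 2)
}
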