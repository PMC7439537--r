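#' Configuration for the synthetic intervention study
#'
#' Defaults state the emulated world: a ~31-subject two-arm trial (16
#' fiber / 15 control), three timepoints, 100 OTUs after filtering, four
#' planted guilds whose CLR shifts are correlated within guilds
#' (rho_w = 0.8) and uncorrelated between (rho_b = 0), SCFA responses
#' linearly linked to guild shifts, and two temporal propionate archetypes
#' (half responders).
#'
#' @param n_subjects Total subjects (split across arms, fiber arm gets the
#'   extra one).
#' @param sex_ratio Fraction of female subjects.
#' @param n_otus Number of OTUs.
#' @param guild_sizes Integer vector of planted guild sizes (sum <=
#'   n_otus; remaining OTUs are unstructured background).
#' @param rho_w,rho_b Within-/between-guild shift correlation,
#'   0 <= rho_b < rho_w <= 1.
#' @param guild_effects Treatment effect per guild, CLR units at week 6
#'   for an average-susceptibility subject.
#' @param responder_fraction Fraction of subjects on the late-responder
#'   trajectory (week 6 propionate above week 1).
#' @param scfa_beta Propionate link coefficient per guild (micromol/g per
#'   CLR unit of guild shift).
#' @param scfa_sigma SCFA noise SD, micromol/g.
#' @param shift_sigma SD of the stochastic CLR shift component.
#' @param susceptibility_sigma Log-normal sigma of the per-subject
#'   susceptibility scalar.
#' @param depth Sequencing depth per sample (multinomial closure).
#' @param seed Integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 31, sex_ratio = 0.5, n_otus = 100,
                       guild_sizes = c(8, 6, 5, 5), rho_w = 0.8,
                       rho_b = 0.0, guild_effects = c(2.0, 1.2, 0.8, -0.8),
                       responder_fraction = 0.5,
                       scfa_beta = c(2.0, 1.0, 0, 0), scfa_sigma = 2.0,
                       shift_sigma = 0.6, susceptibility_sigma = 0.4,
                       depth = 16000, seed = 1L) {
  stopifnot(sum(guild_sizes) <= n_otus,
            length(guild_effects) == length(guild_sizes),
            length(scfa_beta) == length(guild_sizes),
            rho_b >= 0, rho_b < rho_w, rho_w <= 1,
            depth > 0, responder_fraction >= 0, responder_fraction <= 1)
  structure(list(n_subjects = n_subjects, sex_ratio = sex_ratio,
                 n_otus = n_otus, guild_sizes = guild_sizes,
                 rho_w = rho_w, rho_b = rho_b,
                 guild_effects = guild_effects,
                 responder_fraction = responder_fraction,
                 scfa_beta = scfa_beta, scfa_sigma = scfa_sigma,
                 shift_sigma = shift_sigma,
                 susceptibility_sigma = susceptibility_sigma,
                 depth = depth, seed = as.integer(seed)),
            class = "sim_config")
}

clamp_score <- function(x) {
  out <- pmax(pmin(round(x), 4), 0)  # matrix first: pmin/pmax keep arg-1 attrs
  storage.mode(out) <- "integer"
  out
}

#' Generate a complete synthetic two-arm intervention dataset
#'
#' Baseline log-abundances follow a heavy-tailed (log-normal) spectrum and
#' are closed to `depth` reads by multinomial sampling per sample. In the
#' fiber (AX) arm, week-1/week-6 log-abundance shifts are
#' guild effect x subject susceptibility plus noise correlated within
#' guilds; the control (MCC) arm receives noise only. Fecal propionate at
#' week 6 is baseline plus a linear combination of the subject's true
#' guild shifts plus noise; the week-1 value is placed so that the
#' subject's responder archetype controls the sign of the week-1 to
#' week-6 change exactly. Acetate and butyrate are weakly linked to the
#' same shifts. Deterministic for a given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return list: `counts` (counts-mode [abundance_table()], all samples),
#'   `meta` (sample metadata), `scfa` (per-sample SCFA data.frame),
#'   `diaries` (subject x week consistency/frequency scores), `diet`
#'   (subjects x diet features), `truth` (guild labels, archetypes,
#'   susceptibility, link betas, true shift matrices, config).
#' @export
generate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  design <- study_design()
  n <- cfg$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  sex <- ifelse(seq_len(n) <= round(n * cfg$sex_ratio), "female", "male")
  # arm assignment stratified by sex, AX gets the extra subject
  arm <- character(n)
  for (s in unique(sex)) {
    idx <- sample(which(sex == s))
    half <- ceiling(length(idx) / 2)
    arm[idx[seq_len(half)]] <- "AX"
    arm[idx[-seq_len(half)]] <- "MCC"
  }
  dose <- design$dose_by_sex[sex]

  n_guild <- length(cfg$guild_sizes)
  guild <- integer(cfg$n_otus)
  guild[seq_len(sum(cfg$guild_sizes))] <- rep(seq_len(n_guild), cfg$guild_sizes)
  otus <- sprintf("OTU%03d", seq_len(cfg$n_otus))
  names(guild) <- otus

  archetype <- ifelse(
    seq_len(n) %in% sample(n, round(n * cfg$responder_fraction)),
    "W6-responder", "W6-nonresponder")
  susceptibility <- stats::rlnorm(n, 0, cfg$susceptibility_sigma)

  # baseline: log-normal abundance spectrum + persistent subject effects
  mu <- stats::rnorm(cfg$n_otus, 0, 2)
  subj_eff <- matrix(stats::rnorm(n * cfg$n_otus, 0, 0.75), n, cfg$n_otus)
  log_bl <- sweep(subj_eff, 2, mu, "+")

  # time factors per archetype: responders build up, nonresponders overshoot
  tf <- function(arch, tp) {
    if (tp == "W1") ifelse(arch == "W6-responder", 0.5, 1.0)
    else            ifelse(arch == "W6-responder", 1.0, 0.4)
  }

  draw_noise <- function() {
    z0 <- stats::rnorm(n)                       # global factor (rho_b)
    zg <- matrix(stats::rnorm(n * n_guild), n)  # guild factors
    e <- matrix(stats::rnorm(n * cfg$n_otus), n)
    noise <- matrix(0, n, cfg$n_otus)
    for (j in seq_len(cfg$n_otus)) {
      g <- guild[j]
      noise[, j] <- if (g > 0)
        sqrt(cfg$rho_b) * z0 + sqrt(cfg$rho_w - cfg$rho_b) * zg[, g] +
          sqrt(1 - cfg$rho_w) * e[, j]
      else e[, j]
    }
    cfg$shift_sigma * noise
  }

  shift_at <- function(tp) {
    det <- matrix(0, n, cfg$n_otus)
    t_fac <- tf(archetype, tp)
    for (j in which(guild > 0)) {
      eff <- cfg$guild_effects[guild[j]]
      det[, j] <- ifelse(arm == "AX", eff * susceptibility * t_fac, 0)
    }
    list(det = det, total = det + draw_noise())
  }
  w1 <- shift_at("W1")
  w6 <- shift_at("W6")

  close_counts <- function(log_ab) {
    p <- exp(log_ab)
    p <- p / rowSums(p)
    t(apply(p, 1, function(pr) stats::rmultinom(1, cfg$depth, pr)[, 1]))
  }
  tps <- design$timepoints
  count_list <- list(BL = close_counts(log_bl),
                     W1 = close_counts(log_bl + w1$total),
                     W6 = close_counts(log_bl + w6$total))
  sample_id <- as.vector(vapply(tps, function(tp) paste(subjects, tp, sep = "_"),
                                character(n)))
  counts <- do.call(rbind, count_list)
  rownames(counts) <- sample_id
  colnames(counts) <- otus

  meta <- data.frame(
    sample_id = sample_id,
    subject_id = rep(subjects, times = length(tps)),
    arm = rep(arm, times = length(tps)),
    sex = rep(sex, times = length(tps)),
    dose = rep(unname(dose), times = length(tps)),
    timepoint = rep(tps, each = n), stringsAsFactors = FALSE)

  # true guild-level shifts (deterministic component, mean over members)
  guild_shift <- function(det) {
    sapply(seq_len(n_guild), function(g)
      rowMeans(det[, guild == g, drop = FALSE]))
  }
  gs_w1 <- guild_shift(w1$det); gs_w6 <- guild_shift(w6$det)

  prop_bl <- pmax(1, stats::rnorm(n, 15, 3))
  link_w6 <- as.vector(gs_w6 %*% cfg$scfa_beta)
  link_w1 <- as.vector(gs_w1 %*% cfg$scfa_beta)
  prop_w6 <- pmax(0.5, prop_bl + link_w6 + stats::rnorm(n, 0, cfg$scfa_sigma))
  arch_sign <- ifelse(archetype == "W6-responder", 1, -1)
  incr <- abs(link_w6 - link_w1) + abs(stats::rnorm(n, 0, cfg$scfa_sigma)) + 0.1
  prop_w1 <- pmax(0.5, prop_w6 - arch_sign * incr)
  # keep the archetype sign exact even after flooring at 0.5
  bad <- (prop_w6 - prop_w1) * arch_sign <= 0
  prop_w1[bad] <- prop_w6[bad] - arch_sign[bad] * 0.5

  ace_bl <- pmax(1, stats::rnorm(n, 60, 8))
  but_bl <- pmax(0.5, stats::rnorm(n, 15, 3))
  scfa_rows <- function(tp, prop, link_frac) {
    link <- if (tp == "BL") 0 else if (tp == "W1") link_w1 else link_w6
    data.frame(
      sample_id = paste(subjects, tp, sep = "_"),
      acetate = pmax(0.5, ace_bl + 0.5 * link +
                       stats::rnorm(n, 0, cfg$scfa_sigma)),
      propionate = prop,
      butyrate = pmax(0.1, but_bl + 0.3 * link +
                        stats::rnorm(n, 0, cfg$scfa_sigma)),
      isobutyrate = abs(stats::rnorm(n, 2, 0.5)),
      isovalerate = abs(stats::rnorm(n, 2, 0.5)),
      ph = stats::rnorm(n, 7, 0.3),
      moisture = stats::runif(n, 0.6, 0.85), stringsAsFactors = FALSE)
  }
  scfa <- rbind(scfa_rows("BL", prop_bl), scfa_rows("W1", prop_w1),
                scfa_rows("W6", prop_w6))

  weeks <- c("BL", paste0("W", 1:6))
  diary <- function() {
    m <- clamp_score(matrix(2 + stats::rnorm(n * 7, 0, 0.7), n, 7))
    dimnames(m) <- list(subjects, weeks)
    m
  }
  diaries <- list(consistency = diary(), frequency = diary())

  diet_feats <- c("total_grains", "whole_grains", "total_fiber",
                  "protein", "fat", "sugars")
  base_diet <- stats::rnorm(n)
  diet <- sapply(diet_feats, function(f)
    0.6 * base_diet + 0.8 * stats::rnorm(n))
  rownames(diet) <- subjects

  truth <- list(guild = guild, archetype = stats::setNames(archetype, subjects),
                susceptibility = stats::setNames(susceptibility, subjects),
                scfa_beta = cfg$scfa_beta,
                guild_shift_w1 = gs_w1, guild_shift_w6 = gs_w6,
                true_shift_w6 = w6$det, config = cfg)
  rownames(truth$true_shift_w6) <- subjects
  colnames(truth$true_shift_w6) <- otus

  list(counts = abundance_table(counts, mode = "counts"),
       meta = meta, scfa = scfa, diaries = diaries, diet = diet,
       truth = truth)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Label vectors over the same items (same length/order, or
#'   both named over a common set).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0) stop("disjoint item sets")
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Score guild recovery against the simulator's ground truth
#'
#' @param truth `truth` component of [generate_study()] output.
#' @param assignment A `carg_assignment` over (a subset of) the OTUs.
#' @return ARI between the CARG labels and the planted guild labels,
#'   restricted to the screened OTUs.
#' @export
evaluate_guild_recovery <- function(truth, assignment) {
  labels <- assignment$labels
  common <- intersect(names(labels), names(truth$guild))
  if (length(common) == 0) stop("disjoint OTU sets between truth and assignment")
  adjusted_rand_index(truth$guild[common], labels[common])
}

#' Check whether the planted predictor block won the screen
#'
#' @param truth `truth` component of [generate_study()] output (unused
#'   beyond interface symmetry when `planted_block` is given explicitly).
#' @param screen An `mlr_screen` result.
#' @param planted_block Name of the block containing the planted
#'   predictor.
#' @param response Response name to inspect (default "propionate").
#' @return list: `selected` (planted block q < 0.05 AND lowest rel_aicc
#'   for the response), `significant` (q < 0.05 alone), `q`, `rel_aicc`.
#' @export
evaluate_prediction_recovery <- function(truth, screen, planted_block,
                                         response = "propionate") {
  sub <- screen[screen$response == response, ]
  if (nrow(sub) == 0) stop("response not present in screen")
  row <- sub[sub$block == planted_block, ]
  if (nrow(row) == 0) stop("planted block not present in screen")
  sig <- row$q < 0.05
  best <- row$rel_aicc <= min(sub$rel_aicc) + 1e-12
  list(selected = sig && best, significant = sig,
       q = row$q, rel_aicc = row$rel_aicc)
}
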