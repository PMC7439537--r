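#' Study design constants for a two-arm fiber intervention
#'
#' Captures the fixed design of a parallel two-arm trial: treatment arms,
#' sex-specific daily fiber dose, the half-dose run-in, and the ordered
#' sampling timepoints.
#'
#' @param arms Character vector of arm labels.
#' @param dose_by_sex Named numeric vector, grams/day of fiber per sex.
#' @param half_dose_days Integer, number of initial days at half dose.
#' @param timepoints Ordered character vector of sampling timepoints.
#'
#' @return An object of class `study_design` with fields `arms`,
#'   `dose_by_sex`, `half_dose_by_sex` (exactly `dose_by_sex / 2`),
#'   `half_dose_days` and `timepoints`.
#' @examples
#' d <- study_design()
#' d$half_dose_by_sex[["female"]]  # 12.5
#' @export
study_design <- function(arms = c("AX", "MCC"),
                         dose_by_sex = c(female = 25, male = 35),
                         half_dose_days = 2L,
                         timepoints = c("BL", "W1", "W6")) {
  stopifnot(length(arms) >= 2, !anyDuplicated(arms))
  if (is.null(names(dose_by_sex)) || any(!nzchar(names(dose_by_sex))))
    stop("dose_by_sex must be a named vector")
  if (any(dose_by_sex <= 0)) stop("doses must be positive")
  if (anyDuplicated(timepoints)) stop("timepoints must be distinct")
  structure(list(
    arms = as.character(arms),
    dose_by_sex = dose_by_sex,
    half_dose_by_sex = dose_by_sex / 2,
    half_dose_days = as.integer(half_dose_days),
    timepoints = as.character(timepoints)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Two-arm intervention design\n")
  cat("  arms:      ", paste(x$arms, collapse = ", "), "\n")
  cat("  dose g/d:  ", paste(sprintf("%s=%g", names(x$dose_by_sex), x$dose_by_sex),
                             collapse = ", "), "\n")
  cat("  half dose: ", paste(sprintf("%s=%g", names(x$half_dose_by_sex),
                                     x$half_dose_by_sex), collapse = ", "),
      sprintf(" (first %d days)\n", x$half_dose_days))
  cat("  timepoints:", paste(x$timepoints, collapse = " -> "), "\n")
  invisible(x)
}

#' Construct an abundance table
#'
#' Samples-by-OTUs matrix of either raw counts or relative abundances, the
#' canonical container consumed by every downstream operation.
#'
#' @param values Numeric matrix, samples in rows, OTUs in columns. Dimnames
#'   are used as sample and OTU ids when present.
#' @param mode `"counts"` (non-negative integers) or `"relative"` (rows sum
#'   to 1).
#' @param taxonomy Optional character vector of per-OTU taxonomy labels.
#' @return An `abundance_table` object.
#' @export
abundance_table <- function(values, mode = c("counts", "relative"),
                            taxonomy = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("OTU", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicate OTU ids")
  if (any(!is.finite(values))) stop("non-finite abundance values")
  if (any(values < 0)) stop("negative abundance values")
  if (mode == "counts" && any(abs(values - round(values)) > 1e-8))
    stop("counts mode requires integer values")
  if (mode == "relative") {
    # sums strictly below 1 are allowed: abundance-filtered tables are
    # subcompositions and deliberately not re-closed
    rs <- rowSums(values)
    if (any(rs > 1 + 1e-9) || any(rs <= 0))
      stop("relative mode requires each row to sum to 1 (or below, for subcompositions)")
  }
  if (!is.null(taxonomy)) {
    stopifnot(length(taxonomy) == ncol(values))
    taxonomy <- stats::setNames(as.character(taxonomy), colnames(values))
  }
  structure(list(values = values, mode = mode, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d OTUs (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

sample_ids <- function(t) rownames(t$values)
otu_ids <- function(t) colnames(t$values)

#' Read an abundance table from TSV
#'
#' First column holds sample ids and the header row OTU ids; a transposed
#' dialect (OTUs in rows) is accepted via `transposed = TRUE` and normalised
#' to samples x OTUs.
#'
#' @param path Path to a tab-separated file.
#' @param mode `"counts"` or `"relative"`.
#' @param transposed Logical; set when rows are OTUs and columns samples.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, mode = c("counts", "relative"),
                                 transposed = FALSE) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected an id column plus at least one data column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop(sprintf("duplicate sample ID in %s", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transposed) m <- t(m)
  abundance_table(m, mode = mode)
}

#' Write an abundance table as TSV
#' @param t An [abundance_table()].
#' @param path Output path.
#' @export
write_abundance_table <- function(t, path) {
  df <- data.frame(sample_id = sample_ids(t), t$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundance
#'
#' @param t An [abundance_table()] in counts mode; every row sum must be
#'   positive.
#' @return The closed table (rows sum to 1, mode `"relative"`).
#' @export
to_relative_abundance <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  if (t$mode != "counts") stop("expected a counts-mode table")
  rs <- rowSums(t$values)
  if (any(rs == 0)) {
    bad <- sample_ids(t)[rs == 0]
    stop(sprintf("all-zero sample(s): %s", paste(bad, collapse = ", ")))
  }
  abundance_table(t$values / rs, mode = "relative", taxonomy = t$taxonomy)
}

#' Remove low-abundance OTUs
#'
#' Drops OTUs whose mean relative abundance across all samples falls below
#' `threshold` (default 0.15%). Counts are converted internally; retained
#' rows are NOT re-closed — downstream operations decide.
#'
#' @param t An [abundance_table()].
#' @param threshold Mean relative abundance cut-off in (0,1).
#' @return The filtered table, OTU order preserved, original mode.
#' @export
filter_low_abundance <- function(t, threshold = 0.0015) {
  stopifnot(inherits(t, "abundance_table"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  rel <- if (t$mode == "counts") to_relative_abundance(t)$values else t$values
  keep <- colMeans(rel) >= threshold
  if (!any(keep)) stop("all OTUs removed by abundance filter")
  abundance_table(t$values[, keep, drop = FALSE], mode = t$mode,
                  taxonomy = if (!is.null(t$taxonomy)) t$taxonomy[keep])
}

#' Rarefy counts by subsampling without replacement
#'
#' Samples whose library size exceeds `depth` are subsampled (multivariate
#' hypergeometric) to exactly `depth` reads; smaller samples pass through
#' unchanged. Deterministic for a given `seed`.
#'
#' @param t Counts-mode [abundance_table()].
#' @param depth Target depth (reads per sample), >= 1.
#' @param seed Integer RNG seed.
#' @return A counts-mode table.
#' @export
rarefy <- function(t, depth = 16000, seed = 1L) {
  stopifnot(inherits(t, "abundance_table"))
  if (t$mode != "counts") stop("rarefy requires counts mode")
  if (depth < 1) stop("depth must be >= 1")
  v <- t$values
  out <- v
  set.seed(as.integer(seed))
  for (i in seq_len(nrow(v))) {
    tot <- sum(v[i, ])
    if (tot > depth) {
      # expand reads to OTU labels, draw `depth` without replacement
      pool <- rep.int(seq_len(ncol(v)), v[i, ])
      drawn <- sample(pool, depth, replace = FALSE)
      out[i, ] <- tabulate(drawn, nbins = ncol(v))
    }
  }
  abundance_table(out, mode = "counts", taxonomy = t$taxonomy)
}

#' Read a per-sample SCFA concentration table
#'
#' TSV with a `sample_id` column and the five SCFA columns (acetate,
#' propionate, butyrate, isobutyrate, isovalerate; micromol/g wet feces).
#' Optional `ph` and `moisture` columns are kept; other extras are dropped
#' with a warning.
#'
#' @param path Path to a TSV file.
#' @return A data.frame keyed by `sample_id`.
#' @export
read_scfa_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "acetate", "propionate", "butyrate",
           "isobutyrate", "isovalerate")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop(sprintf("missing required SCFA column(s): %s",
                 paste(missing, collapse = ", ")))
  extra <- setdiff(names(df), c(req, "ph", "moisture"))
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  conc <- df[, setdiff(names(df), c("sample_id", "ph", "moisture")), drop = FALSE]
  if (any(as.matrix(conc) < 0, na.rm = TRUE))
    stop("negative SCFA concentration")
  if ("moisture" %in% names(df) &&
      any(df$moisture < 0 | df$moisture > 1, na.rm = TRUE))
    stop("moisture must lie in [0, 1]")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  df
}

#' Validate sample metadata against a study design
#'
#' Checks sample ids, (subject, timepoint) uniqueness, arm and timepoint
#' labels, and sex-consistent dosing.
#'
#' @param meta data.frame with columns sample_id, subject_id, arm, sex,
#'   dose, timepoint.
#' @param design A [study_design()].
#' @return `meta`, invisibly, after validation.
#' @export
validate_metadata <- function(meta, design = study_design()) {
  req <- c("sample_id", "subject_id", "arm", "sex", "dose", "timepoint")
  missing <- setdiff(req, names(meta))
  if (length(missing))
    stop(sprintf("metadata missing column(s): %s", paste(missing, collapse = ", ")))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  key <- paste(meta$subject_id, meta$timepoint)
  if (anyDuplicated(key)) stop("duplicate (subject_id, timepoint) pair")
  bad_arm <- setdiff(unique(meta$arm), design$arms)
  if (length(bad_arm))
    stop(sprintf("unknown arm label(s): %s", paste(bad_arm, collapse = ", ")))
  bad_tp <- setdiff(unique(meta$timepoint), design$timepoints)
  if (length(bad_tp))
    stop(sprintf("unknown timepoint label(s): %s", paste(bad_tp, collapse = ", ")))
  expected <- design$dose_by_sex[meta$sex]
  if (any(is.na(expected)))
    stop("sex label not covered by design dose_by_sex")
  if (any(meta$dose != expected))
    stop("dose inconsistent with sex under the study design")
  invisible(meta)
}

#' Weight ratio of two monosaccharide percentages
#'
#' For arabinoxylan the arabinose-to-xylose ratio indexes branching density
#' of the fiber (arabinose decorates a linear xylose backbone).
#'
#' @param arabinose_pct,xylose_pct Monosaccharide content, weight percent.
#' @return The arabinose/xylose weight ratio.
#' @examples
#' round(arabinose_xylose_ratio(32.5, 57.8), 2)  # 0.56
#' @export
arabinose_xylose_ratio <- function(arabinose_pct, xylose_pct) {
  stopifnot(arabinose_pct >= 0, xylose_pct > 0)
  arabinose_pct / xylose_pct
}
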