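#' Per-feature significance tests between enriched and control samples
#'
#' Two-sample Welch t-test (two-sided, unequal variance) per aligned
#' feature, comparing all 15N2-enriched samples against all control
#' samples pooled across isolates. Degenerate features are handled
#' explicitly: when both groups have zero variance and equal means the
#' p-value is 1; when the means differ with zero variance in both
#' groups, a machine-epsilon variance floor is applied so the statistic
#' is defined (the p-value is then numerically 0).
#'
#' @param fm a `feature_matrix` (raw intensities; a
#'   `rel_intensity_matrix` is also accepted) whose sample sheet carries
#'   a `condition` column with values `"15N"` / `"14N"`.
#' @param log_transform if TRUE, test log10(x + 1)-transformed
#'   intensities; default FALSE (raw scale).
#' @return data.frame with one row per feature: `feature`, `mz`,
#'   `mean_15N`, `mean_14N`, `fold_change` (15N mean / 14N mean, with the
#'   zero denominator replaced by the smallest nonzero intensity / 10),
#'   and `p`.
#' @export
test_features <- function(fm, log_transform = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"),
            "condition" %in% names(fm$samples))
  cond <- fm$samples$condition
  if (!all(cond %in% c("15N", "14N"))) {
    stop('conditions must be "15N" or "14N"', call. = FALSE)
  }
  g1 <- cond == "15N"
  g2 <- cond == "14N"
  if (sum(g1) < 2 || sum(g2) < 2) {
    stop("each condition needs at least 2 samples", call. = FALSE)
  }
  x <- fm$intensities
  xt <- if (log_transform) log10(x + 1) else x
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(xt[, g1, drop = FALSE])
  m2 <- rowMeans(xt[, g2, drop = FALSE])
  v1 <- apply(xt[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(xt[, g2, drop = FALSE], 1, stats::var)

  eps <- .Machine$double.eps
  degenerate <- v1 == 0 & v2 == 0
  v1f <- ifelse(degenerate, eps, v1)
  v2f <- ifelse(degenerate, eps, v2)
  se2 <- v1f / n1 + v2f / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1f / n1)^2 / (n1 - 1) + (v2f / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[degenerate & m1 == m2] <- 1

  # fold change on raw group means; zero control mean replaced by
  # (smallest nonzero raw intensity) / 10 so the ratio stays defined
  m1_raw <- rowMeans(x[, g1, drop = FALSE])
  m2_raw <- rowMeans(x[, g2, drop = FALSE])
  nz <- x[x > 0]
  pseudo <- if (length(nz)) min(nz) / 10 else 1
  fc <- m1_raw / ifelse(m2_raw == 0, pseudo, m2_raw)

  feat <- if (is.null(rownames(x))) sprintf("F%04d", seq_len(nrow(x))) else
    rownames(x)
  data.frame(feature = feat, mz = fm$mz,
             mean_15N = m1_raw, mean_14N = m2_raw,
             fold_change = fc, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up false-discovery-rate adjustment: the adjusted value of the
#' rank-i ordered p-value is min over j >= i of m * p_(j) / j, capped at
#' 1. Order-preserving.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Select biomarkers of nitrogen fixation
#'
#' Retains features that pass both the FDR and fold-change rules:
#' q-value at most `q_threshold` (inclusive) and fold change strictly
#' greater than `fc_threshold`.
#'
#' @param tests data.frame from [test_features()] (needs columns
#'   `feature`, `p`, `fold_change`).
#' @param q_threshold FDR threshold, default 0.05 (inclusive).
#' @param fc_threshold fold-change threshold, default 1 (strict).
#' @return the retained rows with a `q` column added (BH over all input
#'   features).
#' @export
select_biomarkers <- function(tests, q_threshold = 0.05,
                              fc_threshold = 1) {
  stopifnot(all(c("feature", "p", "fold_change") %in% names(tests)))
  tests$q <- bh_qvalues(tests$p)
  keep <- tests$q <= q_threshold & tests$fold_change > fc_threshold
  tests[keep, , drop = FALSE]
}

#' BNF ratio for one isolate
#'
#' For a given isolate, averages each biomarker's relative intensity
#' over that isolate's replicates within each atmosphere, restricts to
#' biomarkers common to both conditions (nonzero mean in both), sums the
#' common biomarkers per condition, and returns the 15N/14N ratio of the
#' sums. The ratio is undetermined (NA, group F) when the common set is
#' empty or the 14N sum is zero.
#'
#' @param rim a `rel_intensity_matrix` whose sample sheet has
#'   `isolate_id` and `condition` columns.
#' @param biomarkers data.frame from [select_biomarkers()].
#' @param isolate_id isolate to score.
#' @param include_all if TRUE, skip the common-to-both restriction and
#'   sum every biomarker in both conditions.
#' @return one-row data.frame: `isolate_id`, `n_common`, `sum_rel_15N`,
#'   `sum_rel_14N`, `bnf_ratio`, `group`.
#' @export
bnf_ratio <- function(rim, biomarkers, isolate_id, include_all = FALSE) {
  stopifnot(inherits(rim, "rel_intensity_matrix"),
            all(c("isolate_id", "condition") %in% names(rim$samples)))
  if (!isolate_id %in% rim$samples$isolate_id) {
    stop("unknown isolate: ", isolate_id, call. = FALSE)
  }
  s15 <- rim$samples$isolate_id == isolate_id & rim$samples$condition == "15N"
  s14 <- rim$samples$isolate_id == isolate_id & rim$samples$condition == "14N"
  if (!any(s15) || !any(s14)) {
    stop("isolate needs samples in both conditions", call. = FALSE)
  }
  rows <- match(biomarkers$feature, rownames(rim$intensities))
  if (anyNA(rows)) stop("biomarker features absent from matrix", call. = FALSE)
  m15 <- rowMeans(rim$intensities[rows, s15, drop = FALSE])
  m14 <- rowMeans(rim$intensities[rows, s14, drop = FALSE])
  common <- if (include_all) rep(TRUE, length(rows)) else m15 > 0 & m14 > 0
  sum15 <- sum(m15[common])
  sum14 <- sum(m14[common])
  ratio <- if (!any(common) || sum14 == 0) NA_real_ else sum15 / sum14
  data.frame(isolate_id = isolate_id, n_common = sum(common),
             sum_rel_15N = sum15, sum_rel_14N = sum14,
             bnf_ratio = ratio, group = assign_group(ratio),
             stringsAsFactors = FALSE)
}

#' Assign an isolate to a BNF group
#'
#' Groups by BNF ratio x: A for x >= 4, B for 3 <= x < 4, C for
#' 2 <= x < 3, D for 1 <= x < 2, E for x < 1, F for an undetermined
#' ratio (NA). The published group ranges are open at both ends; each
#' interval here is closed on the left so that x = 4, 3, 2, 1 are
#' assigned to the higher group, consistent with ratios greater than or
#' equal to 1 counting as sufficient fixation. Boundaries are
#' configurable through `breaks`.
#'
#' @param ratio numeric vector of BNF ratios (NA = undetermined).
#' @param breaks increasing left-closed boundaries separating E/D/C/B/A,
#'   default `c(1, 2, 3, 4)`.
#' @return character vector of groups in \{"A".."F"\}.
#' @export
assign_group <- function(ratio, breaks = c(1, 2, 3, 4)) {
  stopifnot(length(breaks) == 4, !is.unsorted(breaks))
  if (any(!is.na(ratio) & ratio < 0)) {
    stop("BNF ratios cannot be negative", call. = FALSE)
  }
  out <- character(length(ratio))
  out[is.na(ratio)] <- "F"
  ok <- !is.na(ratio)
  out[ok] <- c("E", "D", "C", "B", "A")[
    findInterval(ratio[ok], breaks) + 1L]
  out
}

#' Run the full BNF biomarker assay
#'
#' Pipeline wrapper: tests every feature across all isolates pooled
#' (enriched vs control), selects biomarkers by FDR and fold change,
#' converts the matrix to relative intensities, and scores every isolate
#' with its BNF ratio and group.
#'
#' @inheritParams test_features
#' @inheritParams select_biomarkers
#' @inheritParams bnf_ratio
#' @return list of class `bnf_result`: `tests`, `biomarkers`, `results`
#'   (one row per isolate), `summary` (group -> isolate count).
#' @export
bnf_assay <- function(fm, q_threshold = 0.05, fc_threshold = 1,
                      log_transform = FALSE, include_all = FALSE) {
  stopifnot("isolate_id" %in% names(fm$samples))
  tests <- test_features(fm, log_transform = log_transform)
  biomarkers <- select_biomarkers(tests, q_threshold, fc_threshold)
  rim <- relative_intensities(fm)
  isolates <- unique(fm$samples$isolate_id)
  results <- do.call(rbind, lapply(isolates, function(iso) {
    if (nrow(biomarkers) == 0) {
      data.frame(isolate_id = iso, n_common = 0L, sum_rel_15N = 0,
                 sum_rel_14N = 0, bnf_ratio = NA_real_, group = "F",
                 stringsAsFactors = FALSE)
    } else {
      bnf_ratio(rim, biomarkers, iso, include_all = include_all)
    }
  }))
  structure(list(tests = tests, biomarkers = biomarkers,
                 results = results, summary = bnf_summary(results)),
            class = "bnf_result")
}

#' Summarize BNF groups
#'
#' @param results data.frame with a `group` column (from [bnf_assay()]).
#' @return data.frame `group` / `n_isolates` over all six groups.
#' @export
bnf_summary <- function(results) {
  groups <- factor(results$group, levels = c("A", "B", "C", "D", "E", "F"))
  data.frame(group = levels(groups),
             n_isolates = as.integer(table(groups)),
             stringsAsFactors = FALSE)
}

#' @export
print.bnf_result <- function(x, ...) {
  cat(sprintf("bnf_result: %d features tested, %d biomarkers, %d isolates\n",
              nrow(x$tests), nrow(x$biomarkers), nrow(x$results)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
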