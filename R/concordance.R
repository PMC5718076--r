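#' Modality columns of a cohort volume table
#'
#' The comparator modalities reported against ATV: manual and
#' semi-automated FTV and the 13 MTV thresholds.
#'
#' @param thresholds MTV threshold percents (default 20..80 by 5).
#' @return Character vector of column names.
#' @export
modality_columns <- function(thresholds = seq(20, 80, by = 5)) {
  c("ftv_manual", "ftv_semi", paste0("mtv_", thresholds))
}

#' Validate a per-patient cohort volume table
#'
#' A cohort table has one row per patient with columns \code{patient_id},
#' \code{atv}, \code{ftv_manual}, \code{ftv_semi} and \code{mtv_20} ...
#' \code{mtv_80} (all volumes in cm^3). Missing cells are allowed; each
#' paired statistic uses the complete pairs for its modality.
#'
#' @param table a data.frame.
#' @param thresholds expected MTV threshold percents.
#' @return The validated data.frame (invisibly classed
#'   \code{cohort_volumes}).
#' @export
cohort_table <- function(table, thresholds = seq(20, 80, by = 5)) {
  stopifnot(is.data.frame(table))
  need <- c("patient_id", "atv", modality_columns(thresholds))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0)
    stop("cohort table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  vols <- table[setdiff(need, "patient_id")]
  if (any(vapply(vols, function(v) any(v < 0, na.rm = TRUE), logical(1))))
    stop("volumes must be non-negative", call. = FALSE)
  class(table) <- unique(c("cohort_volumes", class(table)))
  table
}

#' Paired difference of means against ATV
#'
#' The primary concordance statistic: \code{mean(atv) - mean(modality)}
#' over the complete pairs, its percent form relative to the ATV mean,
#' and a two-tailed paired-samples test p-value. A positive difference
#' means the modality under-estimates ATV on average.
#'
#' @param table a cohort table (see \code{\link{cohort_table}}).
#' @param modality name of the comparator column.
#' @param test \code{"t"} for the paired t test (default) or
#'   \code{"wilcoxon"} for the signed-rank alternative.
#' @return List with \code{diff_cm3}, \code{pct}, \code{p} and \code{n}
#'   (number of complete pairs).
#' @export
paired_difference <- function(table, modality, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(modality %in% names(table), "atv" %in% names(table))
  ok <- stats::complete.cases(table[c("atv", modality)])
  if (sum(ok) < 2)
    stop("fewer than 2 complete (atv, ", modality, ") pairs",
         call. = FALSE)
  atv <- table$atv[ok]
  mod <- table[[modality]][ok]
  if (mean(atv) == 0)
    stop("mean ATV is zero; percent difference undefined", call. = FALSE)
  d <- atv - mod
  diff <- mean(atv) - mean(mod)
  pct <- 100 * diff / mean(atv)
  p <- if (stats::sd(d) == 0) {
    # degenerate: all per-patient differences identical
    if (diff == 0) 1 else NaN
  } else if (test == "t") {
    stats::t.test(atv, mod, paired = TRUE)$p.value
  } else {
    stats::wilcox.test(atv, mod, paired = TRUE, exact = FALSE)$p.value
  }
  list(diff_cm3 = diff, pct = pct, p = p, n = sum(ok))
}

#' Pearson correlation of a modality with ATV
#'
#' Sample product-moment correlation over the complete pairs with the
#' two-tailed p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param table a cohort table.
#' @param modality name of the comparator column.
#' @return List with \code{r}, \code{p} and \code{n}.
#' @export
pearson_correlation <- function(table, modality) {
  stopifnot(modality %in% names(table), "atv" %in% names(table))
  ok <- stats::complete.cases(table[c("atv", modality)])
  if (sum(ok) < 3)
    stop("fewer than 3 complete (atv, ", modality, ") pairs",
         call. = FALSE)
  atv <- table$atv[ok]
  mod <- table[[modality]][ok]
  if (stats::sd(atv) == 0 || stats::sd(mod) == 0)
    stop("zero variance in atv or ", modality,
         "; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(atv, mod, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Build the full concordance report
#'
#' One row per comparator modality against ATV: cohort mean, paired
#' difference of means, percent difference, paired-test p-value, Pearson
#' r and its p-value. The modality with the smallest absolute paired
#' difference and the one with the largest correlation are flagged.
#'
#' @param table a cohort table (validated by \code{\link{cohort_table}}).
#' @param thresholds MTV threshold percents present in the table.
#' @param test paired-test choice, see \code{\link{paired_difference}}.
#' @return An object of class \code{concordance_report}: a data.frame
#'   with columns \code{modality}, \code{n}, \code{mean_cm3},
#'   \code{paired_diff_cm3}, \code{pct_diff}, \code{p_paired},
#'   \code{pearson_r}, \code{p_pearson}; attributes \code{atv_mean},
#'   \code{closest_modality}, \code{best_correlated}.
#' @export
build_report <- function(table, thresholds = seq(20, 80, by = 5),
                         test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  table <- cohort_table(table, thresholds)
  mods <- modality_columns(thresholds)
  rows <- lapply(mods, function(m) {
    ok <- stats::complete.cases(table[c("atv", m)])
    pd <- paired_difference(table, m, test = test)
    pc <- tryCatch(pearson_correlation(table, m),
                   error = function(e) list(r = NA_real_, p = NA_real_,
                                            n = sum(ok)))
    data.frame(modality = m, n = pd$n,
               mean_cm3 = mean(table[[m]][ok]),
               paired_diff_cm3 = pd$diff_cm3, pct_diff = pd$pct,
               p_paired = pd$p, pearson_r = pc$r, p_pearson = pc$p,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "atv_mean") <- mean(table$atv, na.rm = TRUE)
  attr(rep, "closest_modality") <-
    rep$modality[which.min(abs(rep$paired_diff_cm3))]
  attr(rep, "best_correlated") <-
    if (all(is.na(rep$pearson_r))) NA_character_ else
      rep$modality[which.max(rep$pearson_r)]
  class(rep) <- c("concordance_report", "data.frame")
  rep
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Tumour volume concordance report (ATV mean %.1f cm^3)\n",
              attr(x, "atv_mean")))
  fmt <- data.frame(
    modality = x$modality,
    mean_cm3 = round_half_up(x$mean_cm3, 1),
    diff_cm3 = round_half_up(x$paired_diff_cm3, 1),
    pct = round_half_up(x$pct_diff, 1),
    p_paired = signif(x$p_paired, 3),
    r = round_half_up(x$pearson_r, 3),
    p_pearson = signif(x$p_pearson, 3))
  print(fmt, row.names = FALSE)
  cat("closest to ATV: ", attr(x, "closest_modality"),
      "; best correlated: ", attr(x, "best_correlated"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.concordance_report <- function(object, ...) {
  list(atv_mean = attr(object, "atv_mean"),
       closest_modality = attr(object, "closest_modality"),
       best_correlated = attr(object, "best_correlated"),
       n_modalities = nrow(object))
}
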