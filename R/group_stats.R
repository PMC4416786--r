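#' Unpaired two-tailed t-test between two groups
#'
#' Wraps [stats::t.test()] with the conventions used for group comparisons
#' of brain distribution metrics: unpaired, two-tailed, pooled-variance
#' Student's test by default (Welch's test is available via
#' `var_equal = FALSE`), significance flagged at `alpha` (default 0.05).
#' Groups with fewer than two observations cannot be tested and yield a
#' not-testable result instead of an error.
#'
#' @param group_a,group_b Numeric vectors of per-animal values.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance Student's test if `TRUE` (default),
#'   Welch's otherwise.
#' @return One-row data.frame: `testable`, `t`, `df`, `p`, `significant`,
#'   `stars` ("**" for p < 0.01, "*" for p < 0.05, "" otherwise).
#' @examples
#' ttest_unpaired(1:5, 2:6)  # t = -1, df = 8, p ~ 0.347
#' @export
ttest_unpaired <- function(group_a, group_b, alpha = 0.05,
                           var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    return(data.frame(testable = FALSE, t = NA_real_, df = NA_real_,
                      p = NA_real_, significant = NA, stars = ""))
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    # degenerate variance: identical constants are "no difference";
    # distinct constants separate with certainty
    df0 <- length(group_a) + length(group_b) - 2
    if (mean(group_a) == mean(group_b)) {
      return(data.frame(testable = TRUE, t = 0, df = df0, p = 1,
                        significant = FALSE, stars = ""))
    }
    t0 <- sign(mean(group_a) - mean(group_b)) * Inf
    return(data.frame(testable = TRUE, t = t0, df = df0, p = 0,
                      significant = TRUE, stars = "**"))
  }
  res <- t.test(group_a, group_b, var.equal = var_equal,
                alternative = "two.sided")
  p <- res$p.value
  data.frame(testable = TRUE, t = unname(res$statistic),
             df = unname(res$parameter), p = p, significant = p < alpha,
             stars = significance_stars(p))
}

#' Significance stars in the figure-legend convention
#'
#' @param p Numeric vector of p-values.
#' @return `"**"` for p < 0.01, `"*"` for p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Group summaries (n, mean, SD, SEM) of a per-animal metric
#'
#' Summarizes a per-animal table by drug x genotype x treatment.  Groups
#' with a single animal report SD 0 by convention and are flagged
#' (`single_value`) so downstream tables can annotate them.
#'
#' @param records Data.frame containing `drug`, `genotype`, the value
#'   column, and optionally `treatment`.
#' @param value_col Name of the column to summarize (e.g. `"kp"`).
#' @return Data.frame with one row per group: `drug`, `genotype`,
#'   `treatment`, `n`, `mean`, `sd`, `sem`, `single_value`.
#' @export
summarize_groups <- function(records, value_col = "kp") {
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  stopifnot(value_col %in% names(records),
            all(c("drug", "genotype") %in% names(records)))
  if (!"treatment" %in% names(records)) records$treatment <- ""
  records$treatment[is.na(records$treatment)] <- ""
  key <- interaction(records$drug, records$genotype, records$treatment,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    v <- d[[value_col]]
    n <- length(v)
    s <- if (n > 1L) sd(v) else 0
    data.frame(drug = d$drug[1L], genotype = d$genotype[1L],
               treatment = d$treatment[1L], n = n, mean = mean(v), sd = s,
               sem = s / sqrt(n), single_value = n == 1L)
  }))
  rownames(out) <- NULL
  out[order(out$drug, out$genotype, out$treatment), , drop = FALSE]
}

#' Blocker-to-control ratio table of group mean Kp
#'
#' For every drug x genotype group treated with an efflux blocker, the
#' ratio of the group's mean Kp to the mean Kp of the untreated control
#' group of the same drug and genotype.  The ratio is a ratio of group
#' means, so no variability is attached to it.  Blocker groups without a
#' matching control are skipped with a warning.
#'
#' @param summaries Output of [summarize_groups()] on Kp, where untreated
#'   control groups have `treatment` equal to `""` (or `control_label`).
#' @param control_label Treatment label identifying control groups.
#' @return Data.frame: `drug`, `genotype`, `blocker`, `ratio`,
#'   `mean_blocker`, `mean_control`.
#' @export
blocker_ratio_table <- function(summaries, control_label = "") {
  stopifnot(all(c("drug", "genotype", "treatment", "mean")
                %in% names(summaries)))
  ctrl <- summaries[summaries$treatment == control_label, , drop = FALSE]
  blk <- summaries[summaries$treatment != control_label, , drop = FALSE]
  rows <- lapply(seq_len(nrow(blk)), function(i) {
    m <- ctrl[ctrl$drug == blk$drug[i] &
                ctrl$genotype == blk$genotype[i], , drop = FALSE]
    if (nrow(m) == 0L) {
      warning("no control group for ", blk$drug[i], "/", blk$genotype[i],
              " with blocker ", blk$treatment[i], "; entry skipped",
              call. = FALSE)
      return(NULL)
    }
    data.frame(drug = blk$drug[i], genotype = blk$genotype[i],
               blocker = blk$treatment[i],
               ratio = blk$mean[i] / m$mean[1L],
               mean_blocker = blk$mean[i], mean_control = m$mean[1L])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(drug = character(), genotype = character(),
                      blocker = character(), ratio = numeric(),
                      mean_blocker = numeric(), mean_control = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Report-layer rounding of Kp,uu values
#'
#' Distribution tables print Kp,uu to three decimal places when the value
#' is below 1 and to three significant figures otherwise.  Rounding is
#' presentation-only: raw values are retained in all computations.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @examples
#' round_kpuu(c(0.0018794, 1.59591))  # 0.002, 1.60
#' @export
round_kpuu <- function(x) {
  ifelse(abs(x) < 1, round(x, 3), signif(x, 3))
}
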