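#' Per-transition absolute amounts by stable-isotope dilution
#'
#' Each SRM/MRM transition pairs an analyte peptide peak with the
#' corresponding isotope-labeled internal-standard (IS) peak acquired in
#' the same run.  The absolute amount per ug injected protein is
#' \deqn{amount = \frac{A_{analyte}}{A_{IS}} \times
#'   \frac{IS_{fmol}}{protein_{ug}}.}
#' Rows with a zero IS peak area cannot be quantified; they are marked
#' invalid (amount `NA`) and reported with a warning rather than silently
#' dropped.
#'
#' @param transitions Data.frame with columns `area_analyte`, `area_is`,
#'   `is_amount_fmol`, `protein_injected_ug` (plus any identifying columns,
#'   carried through).
#' @return The input with added columns `amount` (fmol/ug protein) and
#'   `valid`.
#' @examples
#' quantify_transitions(data.frame(area_analyte = 1e5, area_is = 1e5,
#'                                 is_amount_fmol = 500,
#'                                 protein_injected_ug = 33.3))$amount
#' @export
quantify_transitions <- function(transitions) {
  req <- c("area_analyte", "area_is", "is_amount_fmol",
           "protein_injected_ug")
  miss <- setdiff(req, names(transitions))
  if (length(miss)) {
    stop("transition table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  with(transitions, {
    if (any(area_analyte < 0 | area_is < 0, na.rm = TRUE))
      stop("peak areas must be nonnegative", call. = FALSE)
    if (any(is_amount_fmol <= 0 | protein_injected_ug <= 0, na.rm = TRUE))
      stop("is_amount_fmol and protein_injected_ug must be positive",
           call. = FALSE)
  })
  valid <- transitions$area_is > 0
  if (any(!valid)) {
    warning(sum(!valid), " transition measurement(s) with zero internal-",
            "standard area excluded from quantification", call. = FALSE)
  }
  amount <- rep(NA_real_, nrow(transitions))
  amount[valid] <- transitions$area_analyte[valid] /
    transitions$area_is[valid] *
    transitions$is_amount_fmol[valid] /
    transitions$protein_injected_ug[valid]
  transitions$amount <- amount
  transitions$valid <- valid
  transitions
}

#' Limit of quantification from blank measurements
#'
#' Estimates a per-transition limit of quantification (LOQ) as `k_noise`
#' times the standard deviation of blank-equivalent amounts for that
#' transition (default `k_noise = 3`).  A molecule's reported LOQ is the
#' minimum over its transitions' LOQs (the most sensitive transition sets
#' the reporting limit).  Transitions with fewer than `min_blanks` blank
#' measurements fall back to `loq_fallback` with a warning.
#'
#' @param blanks Blank/noise-region measurements in the transition schema
#'   (quantified internally with [quantify_transitions()]).
#' @param k_noise Noise multiplier (default 3).
#' @param min_blanks Minimum blanks per transition (default 3).
#' @param loq_fallback Fallback LOQ (fmol/ug) when blanks are insufficient.
#' @return Data.frame with columns `molecule`, `transition_id`, `loq`,
#'   `n_blanks`, `fallback_used`.
#' @export
compute_loq <- function(blanks, k_noise = 3, min_blanks = 3,
                        loq_fallback = NULL) {
  stopifnot(all(c("molecule", "transition_id") %in% names(blanks)))
  q <- quantify_transitions(blanks)
  grp <- interaction(q$molecule, q$transition_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(q, grp), function(d) {
    amounts <- d$amount[d$valid]
    if (length(amounts) < min_blanks) {
      if (is.null(loq_fallback)) {
        stop("insufficient blank measurements for transition ",
             d$molecule[1L], "/", d$transition_id[1L],
             " and no `loq_fallback` configured", call. = FALSE)
      }
      warning("insufficient blanks for ", d$molecule[1L], "/",
              d$transition_id[1L], "; using fallback LOQ ", loq_fallback,
              call. = FALSE)
      return(data.frame(molecule = d$molecule[1L],
                        transition_id = d$transition_id[1L],
                        loq = loq_fallback, n_blanks = length(amounts),
                        fallback_used = TRUE))
    }
    data.frame(molecule = d$molecule[1L], transition_id = d$transition_id[1L],
               loq = k_noise * sd(amounts), n_blanks = length(amounts),
               fallback_used = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Molecule-level LOQ (minimum over transitions)
#'
#' @param loq_table Output of [compute_loq()].
#' @return Data.frame `molecule`, `loq`.
#' @export
molecule_loq <- function(loq_table) {
  out <- aggregate(loq ~ molecule, data = loq_table, FUN = min)
  out[order(out$molecule), , drop = FALSE]
}

# Per-transition positivity for one molecule x group: a transition set is
# positive when its peaks co-elute with the internal standard in every run
# and its mean quantified amount reaches the per-transition LOQ.
transition_positivity <- function(q, loq_table) {
  spl <- split(q, q$transition_id)
  do.call(rbind, lapply(spl, function(d) {
    loq <- loq_table$loq[loq_table$molecule == d$molecule[1L] &
                           loq_table$transition_id == d$transition_id[1L]]
    if (length(loq) != 1L) {
      stop("no LOQ for transition ", d$molecule[1L], "/",
           d$transition_id[1L], call. = FALSE)
    }
    amt <- mean(d$amount[d$valid])
    data.frame(molecule = d$molecule[1L], transition_id = d$transition_id[1L],
               mean_amount = amt, loq = loq,
               positive = all(d$rt_match) && isTRUE(amt >= loq) && amt > 0)
  }))
}

#' Expression call from the four-transition positivity rule
#'
#' A molecule is called expressed when positive peaks are observed in three
#' or four of its four SRM/MRM transition sets; with two or fewer positive
#' sets it is reported as under the limit of quantification (ULQ).  A
#' transition set is positive when its signal co-elutes with the internal
#' standard (`rt_match`) in every run and its mean amount reaches the
#' per-transition LOQ.
#'
#' @param transitions Quantified transition rows for one molecule in one
#'   group (exactly 4 distinct `transition_id` values; typically 4
#'   transitions x 3 runs).  Must contain `rt_match`.
#' @param loq_table Per-transition LOQ table from [compute_loq()].
#' @return A list with `expressed` (logical), `positive_count`, and
#'   `transitions` (per-transition positivity detail).
#' @export
assess_positivity <- function(transitions, loq_table) {
  stopifnot(all(c("molecule", "transition_id", "rt_match")
                %in% names(transitions)))
  if (length(unique(transitions$molecule)) != 1L) {
    stop("assess_positivity() expects a single molecule", call. = FALSE)
  }
  n_tr <- length(unique(transitions$transition_id))
  if (n_tr != 4L) {
    stop("schema error: molecule '", transitions$molecule[1L], "' has ",
         n_tr, " transition sets; exactly 4 are required", call. = FALSE)
  }
  if (!"amount" %in% names(transitions)) {
    transitions <- quantify_transitions(transitions)
  }
  pos <- transition_positivity(transitions, loq_table)
  n_pos <- sum(pos$positive)
  list(expressed = n_pos >= 3L, positive_count = n_pos, transitions = pos)
}

#' Protein expression summary with ULQ censoring
#'
#' For an expressed molecule the reported level is the mean of the
#' quantified amounts pooled over its positive transition sets and all
#' runs, with the SEM (SD/sqrt(n)) over the same pool — so the SEM reflects
#' between-transition and between-run technical variability, not
#' inter-individual variability.  Sub-LOQ transition sets do not contribute
#' to the mean (including them would bias the level downward).  A molecule
#' that fails the positivity rule is reported as ULQ with the
#' molecule-level LOQ (minimum over its transitions).
#'
#' @param transitions Quantified transition rows for one molecule in one
#'   group (4 transition sets).
#' @param loq_table Per-transition LOQ table from [compute_loq()].
#' @param group Group label carried into the output (default taken from a
#'   `group` column if present).
#' @return One-row data.frame: `molecule`, `group`, `status`
#'   ("expressed"/"ULQ"), `level`, `sem`, `loq`, `n_values`,
#'   `positive_count`.
#' @export
summarize_expression <- function(transitions, loq_table, group = NULL) {
  if (is.null(group)) {
    group <- if ("group" %in% names(transitions))
      as.character(transitions$group[1L]) else NA_character_
  }
  if (!"amount" %in% names(transitions)) {
    transitions <- quantify_transitions(transitions)
  }
  pos <- assess_positivity(transitions, loq_table)
  mol <- as.character(transitions$molecule[1L])
  mol_loq <- min(pos$transitions$loq)
  if (!pos$expressed) {
    return(data.frame(molecule = mol, group = group, status = "ULQ",
                      level = NA_real_, sem = NA_real_, loq = mol_loq,
                      n_values = 0L, positive_count = pos$positive_count))
  }
  keep <- pos$transitions$transition_id[pos$transitions$positive]
  pool <- transitions$amount[transitions$valid &
                               transitions$transition_id %in% keep]
  n <- length(pool)
  s <- if (n > 1L) sd(pool) else 0
  data.frame(molecule = mol, group = group, status = "expressed",
             level = mean(pool), sem = s / sqrt(n), loq = mol_loq,
             n_values = n, positive_count = pos$positive_count)
}

#' Expression table over molecules and groups
#'
#' Runs [summarize_expression()] for every molecule x group combination in
#' a transition table, using per-transition LOQs computed from a blank
#' table (or supplied directly).
#'
#' @param transitions Transition measurements with columns `molecule`,
#'   `group`, `transition_id`, `run_id`, `rt_match` and the quantification
#'   columns of [quantify_transitions()].
#' @param blanks Optional blank measurements for [compute_loq()].
#' @param loq_table Optional precomputed per-transition LOQ table (used
#'   when `blanks` is `NULL`).
#' @param k_noise,loq_fallback Passed to [compute_loq()].
#' @return Data.frame with one row per molecule x group (see
#'   [summarize_expression()]).
#' @export
qtap_expression_table <- function(transitions, blanks = NULL,
                                  loq_table = NULL, k_noise = 3,
                                  loq_fallback = NULL) {
  stopifnot(all(c("molecule", "group") %in% names(transitions)))
  if (is.null(loq_table)) {
    if (is.null(blanks)) {
      stop("either `blanks` or `loq_table` must be supplied", call. = FALSE)
    }
    loq_table <- compute_loq(blanks, k_noise = k_noise,
                             loq_fallback = loq_fallback)
  }
  q <- quantify_transitions(transitions)
  grp <- interaction(q$molecule, q$group, drop = TRUE)
  out <- do.call(rbind, lapply(split(q, grp), function(d) {
    summarize_expression(d, loq_table)
  }))
  rownames(out) <- NULL
  out[order(out$molecule, out$group), , drop = FALSE]
}

#' Fold change between two expression results, honouring censoring
#'
#' When both sides are expressed the fold change is the point ratio of the
#' levels.  When the denominator is ULQ only a lower bound
#' (`a$level / b$loq`) can be stated; when the numerator is ULQ, an upper
#' bound (`a$loq / b$level`); when both are ULQ the ratio is undefined.
#'
#' @param a,b One-row data.frames as produced by [summarize_expression()]
#'   (numerator and denominator respectively).
#' @return One-row data.frame: `numerator`, `denominator`, `kind`
#'   ("point", "lower_bound", "upper_bound" or "undefined") and `value`.
#' @examples
#' a <- data.frame(molecule = "Mdr1a", group = "C57BL6_WT",
#'                 status = "expressed", level = 22.3, loq = 0.1)
#' b <- data.frame(molecule = "hMDR1", group = "HMDR1",
#'                 status = "expressed", level = 0.355, loq = 0.1)
#' fold_change(a, b)  # 62.8-fold
#' @export
fold_change <- function(a, b) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  a_exp <- a$status == "expressed"
  b_exp <- b$status == "expressed"
  if (a_exp && b_exp) {
    kind <- "point"; value <- a$level / b$level
  } else if (a_exp && !b_exp) {
    kind <- "lower_bound"; value <- a$level / b$loq
  } else if (!a_exp && b_exp) {
    kind <- "upper_bound"; value <- a$loq / b$level
  } else {
    kind <- "undefined"; value <- NA_real_
  }
  data.frame(numerator = paste0(a$molecule, "[", a$group, "]"),
             denominator = paste0(b$molecule, "[", b$group, "]"),
             kind = kind, value = value)
}

#' Between-group comparison of pooled transition-level amounts
#'
#' Unpaired two-tailed Student's t-test on the pooled transition x run
#' amounts of a molecule in two groups.  Because the capillary preparation
#' is pooled tissue measured in technical replicates, this is
#' technical-replicate inference, and it is only defined when the molecule
#' is expressed in both groups — a ULQ side makes the comparison
#' not-testable (censored).
#'
#' @param values_a,values_b Numeric vectors of pooled amounts (fmol/ug),
#'   or `NULL`/empty for a ULQ group.
#' @param alpha Significance level for the flag (default 0.01, the
#'   convention used for expression tables).
#' @param var_equal Use the pooled-variance Student's test (default TRUE).
#' @return One-row data.frame: `testable`, `t`, `df`, `p`, `significant`.
#' @export
compare_expression_groups <- function(values_a, values_b, alpha = 0.01,
                                      var_equal = TRUE) {
  if (is.null(values_a) || is.null(values_b) ||
      length(values_a) < 2L || length(values_b) < 2L) {
    return(data.frame(testable = FALSE, t = NA_real_, df = NA_real_,
                      p = NA_real_, significant = NA))
  }
  res <- ttest_unpaired(values_a, values_b, alpha = alpha,
                        var_equal = var_equal)
  cbind(data.frame(testable = TRUE), res[, c("t", "df", "p", "significant")])
}

#' Format an expression-table cell
#'
#' Expressed molecules render as `"level ± sem"`; censored molecules as
#' `"U.L.Q.(< loq)"`, both at three significant figures.
#'
#' @param row One row of an expression table.
#' @return Character scalar.
#' @export
format_expression_cell <- function(row) {
  if (row$status == "expressed") {
    paste0(format_sig3(row$level), " ± ", format_sig3(row$sem))
  } else {
    paste0("U.L.Q.(< ", format_sig3(row$loq), ")")
  }
}

# Three-significant-figure formatting in the style of expression tables
# (keeps trailing zeros: 0.0990, 1.04, 22.3).
format_sig3 <- function(x) {
  out <- formatC(signif(x, 3), digits = 3, format = "fg", flag = "#")
  sub("\\.$", "", out)
}
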