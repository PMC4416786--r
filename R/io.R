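# Required columns per input table kind.
TABLE_SCHEMAS <- list(
  concentrations = c("animal_id", "genotype", "drug", "treatment",
                     "c_plasma_ng_ml", "c_brain_homog_ng_ml",
                     "homogenate_dilution"),
  dialysis = c("drug", "genotype", "replicate_id", "c_buffer_side",
               "c_plasma_side", "incubation_h"),
  slices = c("drug", "slice_id", "slice_weight", "c_buffer_final",
             "c_slice_homog", "slice_dilution", "end_ph",
             "ldh_release_fraction"),
  srm = c("molecule", "probe_set", "group", "transition_id", "run_id",
          "area_analyte", "area_is", "is_amount_fmol",
          "protein_injected_ug", "rt_match"),
  srm_blanks = c("molecule", "transition_id", "run_id", "area_analyte",
                 "area_is", "is_amount_fmol", "protein_injected_ug"))

finding <- function(file, table, row, column, severity, message) {
  data.frame(file = file, table = table, row = row, column = column,
             severity = severity, message = message)
}

empty_findings <- function() {
  data.frame(file = character(), table = character(), row = integer(),
             column = character(), severity = character(),
             message = character())
}

check_nonneg <- function(df, file, table, cols) {
  out <- list()
  for (cl in cols) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] < 0)
    for (i in bad) {
      out[[length(out) + 1L]] <- finding(
        file, table, i, cl, "error",
        sprintf("negative value %g (must be >= 0)", df[[cl]][i]))
    }
  }
  out
}

check_positive <- function(df, file, table, cols) {
  out <- list()
  for (cl in cols) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] <= 0)
    for (i in bad) {
      out[[length(out) + 1L]] <- finding(
        file, table, i, cl, "error",
        sprintf("non-positive value %g (must be > 0)", df[[cl]][i]))
    }
  }
  out
}

validate_table <- function(df, kind, file = kind) {
  req <- TABLE_SCHEMAS[[kind]]
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    return(do.call(rbind, lapply(miss, function(cl)
      finding(file, kind, NA_integer_, cl, "error", "missing column"))))
  }
  out <- list()
  if (kind == "concentrations") {
    out <- c(out, check_nonneg(df, file, kind,
                               c("c_plasma_ng_ml", "c_brain_homog_ng_ml")))
    bad <- which(!is.na(df$homogenate_dilution) &
                   df$homogenate_dilution < 1)
    for (i in bad) {
      out[[length(out) + 1L]] <- finding(
        file, kind, i, "homogenate_dilution", "error",
        "dilution fold must be >= 1")
    }
    bad <- which(!df$genotype %in% GENOTYPES)
    for (i in bad) {
      out[[length(out) + 1L]] <- finding(
        file, kind, i, "genotype", "warning",
        sprintf("unknown genotype '%s'", df$genotype[i]))
    }
  } else if (kind == "dialysis") {
    out <- c(out, check_nonneg(df, file, kind,
                               c("c_buffer_side", "c_plasma_side")))
  } else if (kind == "slices") {
    out <- c(out, check_positive(df, file, kind,
                                 c("slice_weight", "slice_dilution")))
    out <- c(out, check_nonneg(df, file, kind,
                               c("c_buffer_final", "c_slice_homog")))
    bad <- which(!is.na(df$ldh_release_fraction) &
                   (df$ldh_release_fraction < 0 |
                      df$ldh_release_fraction > 1))
    for (i in bad) {
      out[[length(out) + 1L]] <- finding(
        file, kind, i, "ldh_release_fraction", "error",
        "must be a fraction in [0, 1]")
    }
  } else if (kind %in% c("srm", "srm_blanks")) {
    out <- c(out, check_nonneg(df, file, kind,
                               c("area_analyte", "area_is")))
    out <- c(out, check_positive(df, file, kind,
                                 c("is_amount_fmol",
                                   "protein_injected_ug")))
    if (kind == "srm") {
      for (mol in unique(df$molecule)) {
        n_tr <- length(unique(df$transition_id[df$molecule == mol]))
        if (n_tr != 4L) {
          out[[length(out) + 1L]] <- finding(
            file, kind, NA_integer_, "transition_id", "error",
            sprintf("molecule '%s' has %d transition sets; exactly 4 required",
                    mol, n_tr))
        }
      }
    }
  }
  if (length(out) == 0L) return(empty_findings())
  do.call(rbind, out)
}

#' Read and validate an input table
#'
#' Thin CSV readers for the five input table kinds.  With
#' `validate = TRUE` (default) schema or invariant violations raise an
#' itemized error.
#'
#' @param path CSV file path.
#' @param validate Raise an error on validation findings of severity
#'   "error".
#' @return Data.frame.
#' @name readers
NULL

read_table_kind <- function(path, kind, validate = TRUE) {
  if (!file.exists(path)) {
    stop("cannot read '", path, "': no such file", call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (validate) {
    f <- validate_table(df, kind, file = basename(path))
    if (any(f$severity == "error")) {
      stop("invalid ", kind, " table '", basename(path), "':\n",
           paste(sprintf("  [%s row %s] %s: %s", f$table, f$row, f$column,
                         f$message)[f$severity == "error"],
                 collapse = "\n"), call. = FALSE)
    }
  }
  df
}

#' @rdname readers
#' @export
read_concentrations <- function(path, validate = TRUE)
  read_table_kind(path, "concentrations", validate)

#' @rdname readers
#' @export
read_dialysis <- function(path, validate = TRUE)
  read_table_kind(path, "dialysis", validate)

#' @rdname readers
#' @export
read_slices <- function(path, validate = TRUE)
  read_table_kind(path, "slices", validate)

#' @rdname readers
#' @export
read_srm <- function(path, validate = TRUE)
  read_table_kind(path, "srm", validate)

#' @rdname readers
#' @export
read_srm_blanks <- function(path, validate = TRUE)
  read_table_kind(path, "srm_blanks", validate)

#' Validate a set of input files
#'
#' Checks each supplied file against its table schema and row-level
#' invariants (nonnegative concentrations, dilution folds >= 1, LDH
#' fractions in \[0,1\], positive IS amounts, exactly four transition sets
#' per molecule, ...).  Findings are returned, not raised, so callers can
#' report all of them at once.
#'
#' @param paths Named list/vector of file paths; names identify the table
#'   kind (`concentrations`, `dialysis`, `slices`, `srm`, `srm_blanks`).
#' @return Data.frame of findings (`file`, `table`, `row`, `column`,
#'   `severity`, `message`); zero rows when everything is valid.
#' @export
validate_inputs <- function(paths) {
  kinds <- names(paths)
  bad <- setdiff(kinds, names(TABLE_SCHEMAS))
  if (length(bad)) {
    stop("unknown table kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(kinds, function(k) {
    p <- paths[[k]]
    if (!file.exists(p)) {
      return(finding(basename(p), k, NA_integer_, NA_character_, "error",
                     "file not found"))
    }
    df <- tryCatch(read.csv(p, stringsAsFactors = FALSE),
                   error = function(e)
                     finding(basename(p), k, NA_integer_, NA_character_,
                             "error", paste("unreadable:",
                                            conditionMessage(e))))
    if (is.data.frame(df) && "severity" %in% names(df)) return(df)
    validate_table(df, k, file = basename(p))
  })
  if (length(out) == 0L) return(empty_findings())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
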