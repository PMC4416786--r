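#' Fraction unbound in plasma from equilibrium dialysis
#'
#' At equilibrium the buffer side of the dialysis cell contains only unbound
#' drug at the same unbound concentration as the plasma side, so each
#' replicate estimates \eqn{f_{u,p} = C_{buffer} / C_{plasma}}.  Both sides
#' are assumed matrix-matched and identically diluted before analysis, so
#' any common dilution cancels in the ratio.  Replicates with a
#' non-positive plasma-side concentration are invalid and dropped; if all
#' replicates of a drug/genotype are invalid the assay has failed and an
#' error is raised.  Replicate ratios above 1 are physically impossible but
#' can arise from measurement noise; they are retained and flagged rather
#' than truncated, and a warning is emitted if the mean exceeds 1.
#'
#' @param records Data.frame with columns `drug`, `replicate_id`,
#'   `c_buffer_side`, `c_plasma_side` and optionally `genotype` (plasma
#'   source) and `incubation_h`.
#' @return A list with `summary` (one row per drug x genotype: `n`,
#'   `f_u_plasma`, `sd`, `sem`, `n_above_1`) and `replicates` (per-replicate
#'   ratios with an `above_1` flag).
#' @examples
#' rec <- data.frame(drug = "oxycodone", replicate_id = 1:3,
#'                   c_buffer_side = c(68, 69, 67.5),
#'                   c_plasma_side = c(100, 101, 99))
#' compute_fu_plasma(rec)$summary
#' @export
compute_fu_plasma <- function(records) {
  req <- c("drug", "replicate_id", "c_buffer_side", "c_plasma_side")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("dialysis records are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"genotype" %in% names(records)) records$genotype <- ""
  records$genotype[is.na(records$genotype)] <- ""
  if (any(records$c_buffer_side < 0, na.rm = TRUE)) {
    stop("negative buffer-side concentration in dialysis records",
         call. = FALSE)
  }
  valid <- is.finite(records$c_plasma_side) & records$c_plasma_side > 0 &
    is.finite(records$c_buffer_side)
  key <- interaction(records$drug, records$genotype, drop = TRUE)
  reps <- records[valid, , drop = FALSE]
  if (nrow(reps) == 0L) {
    stop("equilibrium-dialysis assay failure: no valid replicates",
         call. = FALSE)
  }
  failed <- setdiff(levels(key), levels(droplevels(key[valid])))
  if (length(failed)) {
    stop("equilibrium-dialysis assay failure (no valid replicate) for: ",
         paste(failed, collapse = ", "), call. = FALSE)
  }
  reps$f_u <- reps$c_buffer_side / reps$c_plasma_side
  reps$above_1 <- reps$f_u > 1
  grp <- interaction(reps$drug, reps$genotype, drop = TRUE)
  summ <- do.call(rbind, lapply(split(reps, grp), function(d) {
    n <- nrow(d)
    s <- if (n > 1L) sd(d$f_u) else 0
    data.frame(drug = d$drug[1L], genotype = d$genotype[1L], n = n,
               f_u_plasma = mean(d$f_u), sd = s, sem = s / sqrt(n),
               n_above_1 = sum(d$above_1))
  }))
  rownames(summ) <- NULL
  if (any(summ$f_u_plasma > 1)) {
    warning("mean fraction unbound exceeds 1 for: ",
            paste(summ$drug[summ$f_u_plasma > 1], collapse = ", "),
            " (measurement noise; value retained)", call. = FALSE)
  }
  list(summary = summ,
       replicates = reps[, c("drug", "genotype", "replicate_id",
                             "f_u", "above_1")])
}

#' Viability QC for brain-slice records
#'
#' A slice is considered non-viable when the end-of-incubation buffer pH
#' drops below 7.25 or when the released fraction of maximum releasable
#' lactate dehydrogenase (LDH) exceeds a threshold.  Non-viable slices are
#' excluded from the Vu,brain estimate.
#'
#' @param records Data.frame with at least `slice_id`, `end_ph`,
#'   `ldh_release_fraction`.
#' @param ldh_threshold Maximum acceptable LDH release fraction (default
#'   0.25; the criterion itself is assay-specific and configurable).
#' @param min_ph Minimum acceptable end-of-incubation pH (default 7.25).
#' @return The records with added columns `qc_pass` (logical) and
#'   `qc_reasons` (";"-separated failure reasons, empty when passing).
#' @examples
#' qc_slices(data.frame(slice_id = 1, end_ph = 7.2,
#'                      ldh_release_fraction = 0.1))
#' @export
qc_slices <- function(records, ldh_threshold = 0.25, min_ph = 7.25) {
  stopifnot(all(c("slice_id", "end_ph", "ldh_release_fraction")
                %in% names(records)))
  if (any(is.na(records$end_ph))) {
    stop("end_ph must be present for every slice", call. = FALSE)
  }
  bad_ph <- records$end_ph < min_ph
  bad_ldh <- records$ldh_release_fraction > ldh_threshold
  reasons <- mapply(function(p, l) {
    paste(c(if (p) sprintf("pH<%.2f", min_ph),
            if (l) sprintf("LDH>%.2f", ldh_threshold)), collapse = ";")
  }, bad_ph, bad_ldh)
  records$qc_pass <- !(bad_ph | bad_ldh)
  records$qc_reasons <- as.character(reasons)
  records
}

#' Unbound volume of distribution in brain from slice records
#'
#' After incubation of brain slices in drug-containing buffer, the amount
#' of drug per g slice relative to the final (unbound) buffer concentration
#' gives the unbound volume of distribution,
#' \deqn{V_{u,brain} = \frac{A_{slice} - V_{film} C_{buffer}}{C_{buffer}},}
#' where \eqn{A_{slice} = C_{slice,homog} \times D} is the slice amount per
#' g tissue recovered from the homogenate (dilution factor `D`) and
#' \eqn{V_{film}} corrects for adherent surface buffer film (default 0;
#' configurable since published slice protocols use a small nonzero value).
#' Only QC-passing slices (see [qc_slices()]) contribute to the mean.
#'
#' @param records Data.frame with columns `drug`, `slice_id`,
#'   `slice_weight`, `c_buffer_final`, `c_slice_homog`, `slice_dilution`,
#'   `end_ph`, `ldh_release_fraction`.
#' @param v_film Adherent surface-fluid volume, ml/g (default 0).
#' @param ldh_threshold,min_ph QC thresholds passed to [qc_slices()].
#' @return A list with `summary` (per drug: `n_slices`, `n_pass`,
#'   `v_u_brain` mean over passing slices, `sd`, `sem`) and `slices`
#'   (per-slice values with QC status).
#' @export
compute_vu_brain <- function(records, v_film = 0, ldh_threshold = 0.25,
                             min_ph = 7.25) {
  req <- c("drug", "slice_id", "c_buffer_final", "c_slice_homog",
           "slice_dilution", "end_ph", "ldh_release_fraction")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("slice records are missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  records <- qc_slices(records, ldh_threshold = ldh_threshold,
                       min_ph = min_ph)
  if (any(records$c_buffer_final <= 0)) {
    stop("brain-slice assay failure: non-positive final buffer ",
         "concentration", call. = FALSE)
  }
  a_slice <- records$c_slice_homog * records$slice_dilution
  records$v_u_slice <-
    (a_slice - v_film * records$c_buffer_final) / records$c_buffer_final
  summ <- do.call(rbind, lapply(split(records, records$drug), function(d) {
    ok <- d[d$qc_pass, , drop = FALSE]
    if (nrow(ok) == 0L) {
      stop("brain-slice QC failure: no viable slice for drug '",
           d$drug[1L], "'", call. = FALSE)
    }
    s <- if (nrow(ok) > 1L) sd(ok$v_u_slice) else 0
    data.frame(drug = d$drug[1L], n_slices = nrow(d), n_pass = nrow(ok),
               v_u_brain = mean(ok$v_u_slice), sd = s,
               sem = s / sqrt(nrow(ok)))
  }))
  rownames(summ) <- NULL
  list(summary = summ,
       slices = records[, c("drug", "slice_id", "v_u_slice",
                            "qc_pass", "qc_reasons")])
}
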