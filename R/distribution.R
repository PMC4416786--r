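#' Vascular space parameters for residual-blood correction
#'
#' Brain homogenate prepared from non-perfused brain contains residual
#' intravascular blood.  The correction uses two apparent vascular spaces of
#' the brain vasculature: one for plasma water and one for plasma proteins,
#' both in ml per g brain.  Which of the two a drug "sees" depends on its
#' plasma protein binding, so the effective plasma space is the
#' \eqn{f_{u,p}}-weighted blend of the two (see
#' [effective_plasma_space()]).
#'
#' The defaults (10.3 and 8.0 ul/g) are literature estimates for rodent
#' brain; they are configuration parameters, not constants — measured or
#' study-specific values should be supplied where available.
#'
#' @param v_water Apparent vascular space of plasma water, ml/g brain.
#' @param v_protein Apparent vascular space of plasma proteins, ml/g brain.
#' @return A list of class `vascular_params` with elements `v_water` and
#'   `v_protein`.
#' @examples
#' vascular_params()
#' vascular_params(v_water = 0.0103, v_protein = 0.008)
#' @export
vascular_params <- function(v_water = 0.0103, v_protein = 0.0080) {
  if (!is.numeric(v_water) || length(v_water) != 1L ||
      is.na(v_water) || v_water < 0 || v_water >= 1) {
    stop("`v_water` must be a single value in [0, 1) (ml/g brain)",
         call. = FALSE)
  }
  if (!is.numeric(v_protein) || length(v_protein) != 1L ||
      is.na(v_protein) || v_protein < 0 || v_protein >= 1) {
    stop("`v_protein` must be a single value in [0, 1) (ml/g brain)",
         call. = FALSE)
  }
  structure(list(v_water = v_water, v_protein = v_protein),
            class = "vascular_params")
}

#' @export
print.vascular_params <- function(x, ...) {
  cat("Vascular spaces (ml/g brain): V_water =", x$v_water,
      ", V_protein =", x$v_protein, "\n")
  invisible(x)
}

#' Total brain-to-plasma partition coefficient Kp
#'
#' Divides the total brain concentration (ng per g brain tissue) by the
#' total plasma concentration (ng/ml), giving the tissue partition ratio
#' \eqn{K_p} in ml/g.
#'
#' @param c_brain_total Total brain concentration, ng/g brain tissue
#'   (residual-blood corrected; see [correct_residual_blood()]).
#' @param c_plasma Total plasma concentration, ng/ml.  Must be strictly
#'   positive.
#' @param animal_id Optional identifier(s) used in error messages when a
#'   record is invalid.
#' @return Numeric vector of Kp values (ml/g).
#' @examples
#' compute_kp(100, 100)  # 1
#' compute_kp(0, 50)     # 0
#' @export
compute_kp <- function(c_brain_total, c_plasma, animal_id = NULL) {
  stopifnot(is.numeric(c_brain_total), is.numeric(c_plasma))
  bad <- !is.finite(c_plasma) | c_plasma <= 0
  if (any(bad)) {
    who <- if (is.null(animal_id)) which(bad) else animal_id[bad]
    stop("non-positive plasma concentration for record(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  if (any(c_brain_total < 0, na.rm = TRUE)) {
    stop("negative brain concentration supplied to compute_kp()",
         call. = FALSE)
  }
  c_brain_total / c_plasma
}

#' Effective plasma space of residual blood
#'
#' The plasma volume apparently contributing drug to a brain homogenate is
#' the unbound-fraction-weighted blend of the vascular plasma-water and
#' plasma-protein spaces:
#' \deqn{V_{eff} = f_{u,p} V_{water} + (1 - f_{u,p}) V_{protein}.}
#' Strongly bound drugs (small \eqn{f_{u,p}}) travel with plasma proteins,
#' unbound drugs with plasma water.
#'
#' @param f_u_plasma Fraction unbound in plasma, in \[0, 1\].
#' @param params A [vascular_params()] object.
#' @return Effective plasma space, ml/g brain.  Always between
#'   `min(v_water, v_protein)` and `max(v_water, v_protein)`.
#' @examples
#' effective_plasma_space(0.5, vascular_params(0.010, 0.008))  # 0.009
#' @export
effective_plasma_space <- function(f_u_plasma, params = vascular_params()) {
  stopifnot(inherits(params, "vascular_params"))
  if (!is.numeric(f_u_plasma) ||
      any(!is.finite(f_u_plasma) | f_u_plasma < 0 | f_u_plasma > 1)) {
    stop("`f_u_plasma` must lie in [0, 1]", call. = FALSE)
  }
  f_u_plasma * params$v_water + (1 - f_u_plasma) * params$v_protein
}

#' Residual blood-volume correction of brain concentrations
#'
#' Removes the contribution of drug carried in residual intravascular blood
#' from the measured brain homogenate concentration:
#' \deqn{A_{brain} = \frac{C_{brain,h} - V_{eff} C_{plasma}}{1 - V_{water}},}
#' with \eqn{V_{eff}} from [effective_plasma_space()].  `c_brain_h_per_g`
#' must already be expressed per g tissue (i.e. multiplied by the
#' homogenization dilution factor).  Negative corrected amounts — which can
#' arise at high plasma and very low brain exposure — are clamped to zero
#' and flagged, since a physical amount cannot be negative.
#'
#' @param c_brain_h_per_g Brain homogenate concentration converted to per g
#'   tissue, ng/g.
#' @param c_plasma Total plasma concentration, ng/ml.
#' @param f_u_plasma Fraction unbound in plasma, in \[0, 1\].
#' @param params A [vascular_params()] object.
#' @return A data.frame with columns `a_brain` (ng/g), `v_eff` (ml/g) and
#'   `clamped` (logical; `TRUE` where the raw correction was negative).
#' @examples
#' correct_residual_blood(1000, 100, 0.5, vascular_params(0.010, 0.008))
#' @export
correct_residual_blood <- function(c_brain_h_per_g, c_plasma, f_u_plasma,
                                   params = vascular_params()) {
  stopifnot(is.numeric(c_brain_h_per_g), is.numeric(c_plasma))
  if (any(c_brain_h_per_g < 0, na.rm = TRUE) ||
      any(c_plasma < 0, na.rm = TRUE)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  v_eff <- effective_plasma_space(f_u_plasma, params)
  raw <- (c_brain_h_per_g - v_eff * c_plasma) / (1 - params$v_water)
  clamped <- raw < 0
  raw[clamped] <- 0
  data.frame(a_brain = raw, v_eff = v_eff, clamped = clamped)
}

#' Unbound brain-to-plasma partition coefficient Kp,uu
#'
#' \deqn{K_{p,uu} = \frac{K_p}{V_{u,brain} \times f_{u,p}}}
#' relates the unbound drug concentration in brain interstitial fluid to
#' the unbound concentration in plasma.  Values below 1 indicate net efflux
#' at the blood-brain barrier, values above 1 net active uptake.
#'
#' @param kp Total partition coefficient, ml/g (treated as dimensionless
#'   relative to `v_u_brain` in ml/g).
#' @param v_u_brain Unbound volume of distribution in brain, ml/g.  Must be
#'   strictly positive.
#' @param f_u_plasma Fraction unbound in plasma.  Must be strictly positive.
#' @return Kp,uu, dimensionless.
#' @examples
#' compute_kpuu(0.05, 44.8, 0.594)  # digoxin-like, strong efflux
#' compute_kpuu(4.8, 3.75, 0.681)   # oxycodone-like, net uptake
#' @export
compute_kpuu <- function(kp, v_u_brain, f_u_plasma) {
  stopifnot(is.numeric(kp), is.numeric(v_u_brain), is.numeric(f_u_plasma))
  if (any(!is.finite(v_u_brain) | v_u_brain <= 0)) {
    stop("`v_u_brain` must be strictly positive (ml/g)", call. = FALSE)
  }
  if (any(!is.finite(f_u_plasma) | f_u_plasma <= 0)) {
    stop("`f_u_plasma` must be strictly positive", call. = FALSE)
  }
  if (any(kp < 0, na.rm = TRUE)) {
    stop("`kp` must be nonnegative", call. = FALSE)
  }
  kp / (v_u_brain * f_u_plasma)
}

#' Per-animal distribution metrics from concentration records
#'
#' Applies the full distribution chain to a table of per-animal
#' concentration records: converts the measured homogenate concentration to
#' per g tissue using the record's homogenization dilution factor, corrects
#' for residual blood, and computes Kp and Kp,uu per animal using the
#' supplied drug-level binding parameters.
#'
#' @param records Data.frame with columns `animal_id`, `genotype`, `drug`,
#'   `treatment`, `c_plasma_ng_ml`, `c_brain_homog_ng_ml`,
#'   `homogenate_dilution` (total fold, tissue to homogenate, w/v; e.g. 5
#'   for 4 added volumes).
#' @param binding Data.frame with columns `drug`, `genotype` (optional;
#'   `NA` meaning all genotypes), `f_u_plasma`, `v_u_brain` giving the
#'   binding parameters per drug (and, where plasma binding differs between
#'   lines, per genotype).
#' @param params A [vascular_params()] object.
#' @return The records with added columns `c_brain_per_g`, `v_eff`,
#'   `a_brain`, `clamped`, `f_u_plasma`, `v_u_brain`, `kp`, `kpuu`.
#' @export
distribution_metrics <- function(records, binding,
                                 params = vascular_params()) {
  req <- c("animal_id", "genotype", "drug", "c_plasma_ng_ml",
           "c_brain_homog_ng_ml", "homogenate_dilution")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$homogenate_dilution < 1, na.rm = TRUE)) {
    stop("homogenate_dilution must be >= 1 (total tissue-to-homogenate fold)",
         call. = FALSE)
  }
  breq <- c("drug", "f_u_plasma", "v_u_brain")
  if (!all(breq %in% names(binding))) {
    stop("binding table needs columns: ", paste(breq, collapse = ", "),
         call. = FALSE)
  }
  fu <- vu <- numeric(nrow(records))
  for (i in seq_len(nrow(records))) {
    cand <- binding[binding$drug == records$drug[i], , drop = FALSE]
    if ("genotype" %in% names(cand) && nrow(cand) > 1L) {
      hit <- cand[!is.na(cand$genotype) &
                    cand$genotype == records$genotype[i], , drop = FALSE]
      if (nrow(hit) == 0L) hit <- cand[is.na(cand$genotype), , drop = FALSE]
      cand <- hit
    }
    if (nrow(cand) == 0L) {
      stop("no binding parameters for drug '", records$drug[i],
           "' (genotype ", records$genotype[i], ")", call. = FALSE)
    }
    fu[i] <- cand$f_u_plasma[1L]
    vu[i] <- cand$v_u_brain[1L]
  }
  per_g <- records$c_brain_homog_ng_ml * records$homogenate_dilution
  corr <- correct_residual_blood(per_g, records$c_plasma_ng_ml, fu, params)
  kp <- compute_kp(corr$a_brain, records$c_plasma_ng_ml,
                   animal_id = records$animal_id)
  out <- records
  out$c_brain_per_g <- per_g
  out$v_eff <- corr$v_eff
  out$a_brain <- corr$a_brain
  out$clamped <- corr$clamped
  out$f_u_plasma <- fu
  out$v_u_brain <- vu
  out$kp <- kp
  out$kpuu <- compute_kpuu(kp, vu, fu)
  out
}
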