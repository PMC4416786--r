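# Multiplicative lognormal noise with mean 1 and coefficient of variation
# `cv` (cv = 0 returns exact 1s without consuming RNG draws).
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Independent substream seed for generator stream k, kept within 32-bit
# integer range so adding a stream never perturbs the others.
stream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 104729 * k) %% 2147483647)
}

#' Ground-truth scenario for the synthetic study
#'
#' Defines the true parameters from which all four synthetic input tables
#' are generated: per drug x genotype the true Kp, Vu,brain, fu,plasma and
#' typical plasma level; the vascular spaces; per-assay measurement CVs; and
#' the true transporter protein abundances with probe-set selectivity for
#' the SRM/MRM generator.  The defaults mirror the study conditions: four
#' drugs (digoxin, verapamil, docetaxel, oxycodone) across four mouse lines,
#' with knockout-to-wild-type Kp folds of 20, 30, 4 and 1.6 and
#' humanized-to-wild-type folds of 2, 16, 2 (P-gp substrates) and 1.6
#' (oxycodone), and P-gp protein abundances of 22.3 (Mdr1a, wild type),
#' 2.45 (Mdr1a, humanized) and 0.355 (human MDR1, humanized) fmol/ug with
#' Mdr1b absent.
#'
#' @param seed Integer seed; fixed seed plus fixed configuration gives
#'   byte-identical generated files.
#' @param cv Named list of measurement CVs per assay: `cohort`, `dialysis`,
#'   `slice`, `srm` (lognormal, applied independently to every measured
#'   concentration or peak area).  A single number is recycled to all four.
#' @param cv_biological Between-animal CV of plasma exposure (cancels in
#'   Kp, present for realism of the raw tables).
#' @param vascular A [vascular_params()] object.
#' @param v_film True adherent surface-fluid volume in the slice assay,
#'   ml/g (default 0).
#' @param drugs Optional replacement for the drug x genotype truth table
#'   (columns `drug`, `genotype`, `kp`, `v_u_brain`, `f_u_plasma`,
#'   `c_plasma_ng_ml`).
#' @param proteins Optional replacement for the protein abundance truth
#'   (columns `protein`, `C57BL6_WT`, `HMDR1`, fmol/ug).
#' @param probes Optional replacement for the probe map (columns
#'   `molecule`, `probe_set`, `targets` — ";"-separated protein names).
#' @param loq Optional replacement for molecule-level true LOQs (named
#'   numeric vector, fmol/ug).
#' @return A list of class `cohort_truth`; the `kpuu` column of `$drugs` is
#'   derived as `kp / (v_u_brain * f_u_plasma)`.
#' @export
cohort_truth <- function(seed = 1L,
                         cv = list(cohort = 0.10, dialysis = 0.10,
                                   slice = 0.10, srm = 0.10),
                         cv_biological = 0.25,
                         vascular = vascular_params(),
                         v_film = 0,
                         drugs = NULL, proteins = NULL, probes = NULL,
                         loq = NULL) {
  if (is.numeric(cv) && length(cv) == 1L) {
    cv <- list(cohort = cv, dialysis = cv, slice = cv, srm = cv)
  }
  stopifnot(all(c("cohort", "dialysis", "slice", "srm") %in% names(cv)))
  if (is.null(drugs)) {
    # Wild-type Kp / Vu,brain / fu from the distribution reference table;
    # knockout and humanized lines scaled by the reported in vivo folds.
    wt <- data.frame(
      drug = c("digoxin", "verapamil", "docetaxel", "oxycodone"),
      kp = c(0.05, 0.6, 0.09, 4.8),
      v_u_brain = c(44.8, 48.2, 789, 3.75),
      f_u_plasma = c(0.594, 0.115, 0.053, 0.681),
      c_plasma_ng_ml = c(50, 80, 500, 30))
    fold_ko <- c(digoxin = 20, verapamil = 30, docetaxel = 4,
                 oxycodone = 1.6)
    fold_h <- c(digoxin = 2.2, verapamil = 15, docetaxel = 1.44,
                oxycodone = 1.6)
    fu_h <- c(digoxin = 0.607, verapamil = 0.117, docetaxel = 0.052,
              oxycodone = 0.681)
    rows <- list()
    for (i in seq_len(nrow(wt))) {
      d <- wt$drug[i]
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, genotype = "C57BL6_WT", kp = wt$kp[i],
        v_u_brain = wt$v_u_brain[i], f_u_plasma = wt$f_u_plasma[i],
        c_plasma_ng_ml = wt$c_plasma_ng_ml[i])
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, genotype = "HMDR1", kp = wt$kp[i] * fold_h[[d]],
        v_u_brain = wt$v_u_brain[i], f_u_plasma = fu_h[[d]],
        c_plasma_ng_ml = wt$c_plasma_ng_ml[i])
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, genotype = "FVB_WT", kp = wt$kp[i],
        v_u_brain = wt$v_u_brain[i], f_u_plasma = wt$f_u_plasma[i],
        c_plasma_ng_ml = wt$c_plasma_ng_ml[i])
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, genotype = "MDR1A1B_KO", kp = wt$kp[i] * fold_ko[[d]],
        v_u_brain = wt$v_u_brain[i], f_u_plasma = wt$f_u_plasma[i],
        c_plasma_ng_ml = wt$c_plasma_ng_ml[i])
    }
    drugs <- do.call(rbind, rows)
  }
  drugs$kpuu <- drugs$kp / (drugs$v_u_brain * drugs$f_u_plasma)
  if (is.null(proteins)) {
    proteins <- data.frame(
      protein = c("MDR1_human", "Mdr1a", "Mdr1b", "Bcrp"),
      C57BL6_WT = c(0, 22.3, 0, 8.69),
      HMDR1 = c(0.355, 2.45, 0, 5.67))
  }
  if (is.null(probes)) {
    probes <- data.frame(
      molecule = c("hMDR1", "Mdr1a", "MDR1_Mdr1a", "Mdr1b", "Bcrp"),
      probe_set = c("human_specific", "mouse_specific", "common",
                    "mouse_specific", "common"),
      targets = c("MDR1_human", "Mdr1a", "MDR1_human;Mdr1a", "Mdr1b",
                  "Bcrp"))
  }
  if (is.null(loq)) {
    loq <- c(hMDR1 = 0.112, Mdr1a = 0.10, MDR1_Mdr1a = 0.10,
             Mdr1b = 0.135, Bcrp = 0.10)
  }
  structure(list(seed = as.integer(seed), cv = cv,
                 cv_biological = cv_biological, vascular = vascular,
                 v_film = v_film, drugs = drugs, proteins = proteins,
                 probes = probes, loq = loq),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("Synthetic study truth: ", nrow(x$drugs), " drug x genotype groups, ",
      nrow(x$probes), " SRM probe sets, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate per-animal concentration records
#'
#' Forward model per animal: the true plasma level varies biologically
#' between animals (lognormal, `cv_biological`); the corrected brain
#' amount follows from the true Kp,uu
#' (\eqn{A = K_{p,uu} f_{u,p} C_{plasma} V_{u,brain}}); the homogenate
#' concentration adds back the residual-blood contribution
#' (\eqn{C_{brain,h} = A (1 - V_{water}) + V_{eff} C_{plasma}}) and is
#' divided by the homogenization dilution; finally, plasma and homogenate
#' measurements each receive independent lognormal measurement error
#' (`cv$cohort`).  With zero noise the analysis chain inverts this model
#' exactly.
#'
#' @param truth A [cohort_truth()] object.
#' @param n_per_group Animals per drug x genotype group (default 5).
#' @param homogenate_dilution Total tissue-to-homogenate fold (default 5,
#'   i.e. 4 added volumes w/v).
#' @return Data.frame in the `concentrations.csv` schema.
#' @export
generate_cohort <- function(truth, n_per_group = 5L,
                            homogenate_dilution = 5) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(stream_seed(truth$seed, 1L))
  vw <- truth$vascular$v_water
  rows <- lapply(seq_len(nrow(truth$drugs)), function(i) {
    tr <- truth$drugs[i, ]
    veff <- effective_plasma_space(tr$f_u_plasma, truth$vascular)
    cp_true <- tr$c_plasma_ng_ml * rlnorm_cv(n_per_group,
                                             truth$cv_biological)
    a_brain <- tr$kpuu * tr$f_u_plasma * cp_true * tr$v_u_brain
    c_brain_g <- a_brain * (1 - vw) + veff * cp_true
    data.frame(
      animal_id = sprintf("%s_%s_%02d", tr$drug, tr$genotype,
                          seq_len(n_per_group)),
      genotype = tr$genotype, drug = tr$drug, treatment = "",
      c_plasma_ng_ml = cp_true * rlnorm_cv(n_per_group, truth$cv$cohort),
      c_brain_homog_ng_ml = c_brain_g / homogenate_dilution *
        rlnorm_cv(n_per_group, truth$cv$cohort),
      homogenate_dilution = homogenate_dilution)
  })
  do.call(rbind, rows)
}

#' Generate equilibrium-dialysis records
#'
#' Both sides of each dialysis well share the equilibrium unbound
#' concentration \eqn{f_{u,p} C_{plasma}}; the plasma side additionally
#' carries the bound fraction, so its total is \eqn{C_{plasma}}.  Each
#' side's measurement receives independent lognormal error
#' (`cv$dialysis`).
#'
#' @param truth A [cohort_truth()] object.
#' @param replicates Replicate wells per drug x genotype (default 3).
#' @param incubation_h Incubation time recorded in the table (default 6).
#' @return Data.frame in the `dialysis.csv` schema.
#' @export
generate_dialysis <- function(truth, replicates = 3L, incubation_h = 6) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(stream_seed(truth$seed, 2L))
  key <- !duplicated(truth$drugs[, c("drug", "genotype")])
  rows <- lapply(which(key), function(i) {
    tr <- truth$drugs[i, ]
    c0 <- tr$c_plasma_ng_ml
    data.frame(
      drug = tr$drug, genotype = tr$genotype,
      replicate_id = seq_len(replicates),
      c_buffer_side = tr$f_u_plasma * c0 *
        rlnorm_cv(replicates, truth$cv$dialysis),
      c_plasma_side = c0 * rlnorm_cv(replicates, truth$cv$dialysis),
      incubation_h = incubation_h)
  })
  do.call(rbind, rows)
}

#' Generate brain-slice assay records
#'
#' Per slice the drug amount per g tissue at equilibrium is
#' \eqn{A_{slice} = (V_{u,brain} + V_{film}) C_{buffer}}; the homogenate
#' concentration divides this by the slice homogenization dilution.  Buffer
#' and homogenate measurements receive independent lognormal error
#' (`cv$slice`).  A `fail_fraction` of slices is generated non-viable
#' (end pH below 7.25, elevated LDH release) with a distorted drug content,
#' to exercise the viability QC.
#'
#' @param truth A [cohort_truth()] object.
#' @param n_slices Slices per drug (default 6).
#' @param fail_fraction Fraction of slices generated non-viable
#'   (default 0).
#' @param c_buffer_ng_ml Nominal final buffer concentration (default 100).
#' @param slice_dilution Slice homogenization fold (default 10, i.e. 9
#'   added volumes w/v).
#' @return Data.frame in the `slices.csv` schema.
#' @export
generate_slices <- function(truth, n_slices = 6L, fail_fraction = 0,
                            c_buffer_ng_ml = 100, slice_dilution = 10) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(stream_seed(truth$seed, 3L))
  n_fail <- round(fail_fraction * n_slices)
  vu_by_drug <- truth$drugs[!duplicated(truth$drugs$drug),
                            c("drug", "v_u_brain")]
  rows <- lapply(seq_len(nrow(vu_by_drug)), function(i) {
    drug <- vu_by_drug$drug[i]
    vu <- vu_by_drug$v_u_brain[i]
    failing <- seq_len(n_slices) <= n_fail
    a_slice <- (vu + truth$v_film) * c_buffer_ng_ml
    # non-viable slices lose barrier integrity; their content is distorted
    a_slice <- a_slice * ifelse(failing, 3, 1)
    data.frame(
      drug = drug, slice_id = sprintf("%s_s%02d", drug, seq_len(n_slices)),
      slice_weight = round(runif(n_slices, 0.025, 0.035), 4),
      c_buffer_final = c_buffer_ng_ml *
        rlnorm_cv(n_slices, truth$cv$slice),
      c_slice_homog = a_slice / slice_dilution *
        rlnorm_cv(n_slices, truth$cv$slice),
      slice_dilution = slice_dilution,
      end_ph = round(ifelse(failing, runif(n_slices, 7.00, 7.20),
                            runif(n_slices, 7.30, 7.60)), 2),
      ldh_release_fraction = round(ifelse(failing,
                                          runif(n_slices, 0.30, 0.50),
                                          runif(n_slices, 0.05, 0.15)), 3))
  })
  do.call(rbind, rows)
}

#' Generate SRM/MRM transition and blank tables
#'
#' Each molecule is monitored with four transition sets in each of
#' `runs` analyses per group.  Probe-set selectivity follows the truth's
#' probe map: a molecule's true signal is the summed abundance of the
#' proteins its probe targets in that group (human-specific probes see no
#' mouse signal and vice versa; common probes sum both).  Present signals
#' produce analyte/IS area ratios that invert exactly to the true amount
#' under zero noise; absent signals produce noise-floor areas whose
#' apparent retention-time match is random.  Blank runs are generated with
#' a noise floor whose standard deviation equals the per-transition true
#' LOQ divided by `k_noise`, so [compute_loq()] recovers the intended
#' LOQs in expectation.
#'
#' @param truth A [cohort_truth()] object.
#' @param runs Analyses per group (default 3).
#' @param n_blanks Blank measurements per transition (default 6).
#' @param k_noise LOQ noise multiplier the blanks are scaled for
#'   (default 3).
#' @param is_amount_fmol,protein_injected_ug Internal-standard amount and
#'   injected protein (defaults 500 fmol / 33.3 ug).
#' @return A list with `transitions` and `blanks` data.frames.
#' @export
generate_srm <- function(truth, runs = 3L, n_blanks = 6L, k_noise = 3,
                         is_amount_fmol = 500, protein_injected_ug = 33.3) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed(stream_seed(truth$seed, 4L))
  groups <- setdiff(names(truth$proteins), "protein")
  tr_mult <- c(1, 1.15, 1.3, 1.5)  # transition 1 is the most sensitive
  ratio_for <- function(amount) amount * protein_injected_ug /
    is_amount_fmol
  t_rows <- list()
  for (g in groups) {
    for (m in seq_len(nrow(truth$probes))) {
      mol <- truth$probes$molecule[m]
      targets <- strsplit(truth$probes$targets[m], ";")[[1L]]
      level <- sum(truth$proteins[[g]][truth$proteins$protein %in% targets])
      loq_t <- truth$loq[[mol]] * tr_mult
      for (tid in 1:4) {
        area_is <- 1e5 * rlnorm_cv(runs, truth$cv$srm)
        if (level > 0) {
          amt <- level * rlnorm_cv(runs, truth$cv$srm)
          rt <- rep(TRUE, runs)
        } else {
          # noise floor: small apparent amounts, inconsistent co-elution
          amt <- abs(rnorm(runs, 0, loq_t[tid] / k_noise))
          rt <- runif(runs) < 0.5
        }
        t_rows[[length(t_rows) + 1L]] <- data.frame(
          molecule = mol, probe_set = truth$probes$probe_set[m],
          group = g, transition_id = paste0("Q1Q3-", tid),
          run_id = paste0("run", seq_len(runs)),
          area_analyte = ratio_for(amt) * area_is, area_is = area_is,
          is_amount_fmol = is_amount_fmol,
          protein_injected_ug = protein_injected_ug, rt_match = rt)
      }
    }
  }
  b_rows <- list()
  for (m in seq_len(nrow(truth$probes))) {
    mol <- truth$probes$molecule[m]
    loq_t <- truth$loq[[mol]] * tr_mult
    for (tid in 1:4) {
      area_is <- 1e5 * rlnorm_cv(n_blanks, truth$cv$srm)
      amt <- pmax(0, 3 * loq_t[tid] / k_noise +
                    rnorm(n_blanks, 0, loq_t[tid] / k_noise))
      b_rows[[length(b_rows) + 1L]] <- data.frame(
        molecule = mol, transition_id = paste0("Q1Q3-", tid),
        run_id = paste0("blank", seq_len(n_blanks)),
        area_analyte = ratio_for(amt) * area_is, area_is = area_is,
        is_amount_fmol = is_amount_fmol,
        protein_injected_ug = protein_injected_ug)
    }
  }
  list(transitions = do.call(rbind, t_rows),
       blanks = do.call(rbind, b_rows))
}

#' Write a complete synthetic study to disk
#'
#' Generates all input tables from one truth object and writes
#' `concentrations.csv`, `dialysis.csv`, `slices.csv`,
#' `srm_transitions.csv`, `srm_blanks.csv` and `truth.json` into `dir`.
#' Identical truth (including seed) gives byte-identical files.
#'
#' @param truth A [cohort_truth()] object.
#' @param dir Output directory (created if missing).
#' @param n_per_group,replicates,n_slices,fail_fraction,runs Sizes passed
#'   to the individual generators.
#' @return Named character vector of file paths, invisibly.
#' @export
simulate_study <- function(truth, dir, n_per_group = 5L, replicates = 3L,
                           n_slices = 6L, fail_fraction = 0, runs = 3L) {
  stopifnot(inherits(truth, "cohort_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  conc <- generate_cohort(truth, n_per_group = n_per_group)
  dia <- generate_dialysis(truth, replicates = replicates)
  sli <- generate_slices(truth, n_slices = n_slices,
                         fail_fraction = fail_fraction)
  srm <- generate_srm(truth, runs = runs)
  paths <- c(concentrations = file.path(dir, "concentrations.csv"),
             dialysis = file.path(dir, "dialysis.csv"),
             slices = file.path(dir, "slices.csv"),
             srm = file.path(dir, "srm_transitions.csv"),
             srm_blanks = file.path(dir, "srm_blanks.csv"),
             truth = file.path(dir, "truth.json"))
  write.csv(conc, paths[["concentrations"]], row.names = FALSE)
  write.csv(dia, paths[["dialysis"]], row.names = FALSE)
  write.csv(sli, paths[["slices"]], row.names = FALSE)
  write.csv(srm$transitions, paths[["srm"]], row.names = FALSE)
  write.csv(srm$blanks, paths[["srm_blanks"]], row.names = FALSE)
  jsonlite::write_json(
    list(seed = truth$seed, cv = truth$cv,
         cv_biological = truth$cv_biological,
         vascular = unclass(truth$vascular), v_film = truth$v_film,
         drugs = truth$drugs, proteins = truth$proteins,
         probes = truth$probes, loq = as.list(truth$loq)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Parameter-recovery simulation study
#'
#' Repeatedly generates a synthetic study at a given measurement CV,
#' re-estimates fu,plasma (dialysis), Vu,brain (slices) and group-level
#' Kp,uu (cohort + estimated binding parameters) with the analysis chain,
#' and records the relative error of each estimate against the generating
#' truth.  Used to characterize the precision attainable under the study's
#' assay sizes.
#'
#' @param n_rep Number of simulated studies (default 200).
#' @param cv Measurement CV applied to every assay (default 0.10).
#' @param n_per_group Animals per group (default 5).
#' @param replicates Dialysis replicates (default 3).
#' @param n_slices Slices per drug (default 6).
#' @param seed Base seed; replicate r uses substream `seed + r`.
#' @param genotypes Genotypes to include (default the two reference-table
#'   lines).
#' @return Data.frame with one row per replicate x drug x genotype:
#'   `rel_err_kpuu`, `rel_err_vu`, `rel_err_fu` (signed relative errors).
#' @export
simulate_recovery <- function(n_rep = 200L, cv = 0.10, n_per_group = 5L,
                              replicates = 3L, n_slices = 6L, seed = 1L,
                              genotypes = c("C57BL6_WT", "HMDR1")) {
  base <- cohort_truth(seed = seed, cv = cv, cv_biological = 0.25)
  keep <- base$drugs$genotype %in% genotypes
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    truth <- cohort_truth(seed = stream_seed(seed, 10L + r), cv = cv,
                          cv_biological = 0.25,
                          drugs = base$drugs[keep, , drop = FALSE])
    conc <- generate_cohort(truth, n_per_group = n_per_group)
    dia <- generate_dialysis(truth, replicates = replicates)
    sli <- generate_slices(truth, n_slices = n_slices)
    fu <- compute_fu_plasma(dia)$summary
    vu <- compute_vu_brain(sli)$summary
    binding <- merge(fu[, c("drug", "genotype", "f_u_plasma")],
                     vu[, c("drug", "v_u_brain")], by = "drug")
    dm <- distribution_metrics(conc, binding, truth$vascular)
    kp_grp <- summarize_groups(dm, "kp")
    res <- merge(truth$drugs, kp_grp[, c("drug", "genotype", "mean")],
                 by = c("drug", "genotype"))
    res <- merge(res, binding, by = c("drug", "genotype"),
                 suffixes = c("_true", "_est"))
    kpuu_est <- res$mean / (res$v_u_brain_est * res$f_u_plasma_est)
    out[[r]] <- data.frame(
      replicate = r, drug = res$drug, genotype = res$genotype,
      rel_err_kpuu = kpuu_est / res$kpuu - 1,
      rel_err_vu = res$v_u_brain_est / res$v_u_brain_true - 1,
      rel_err_fu = res$f_u_plasma_est / res$f_u_plasma_true - 1)
  }
  do.call(rbind, out)
}
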