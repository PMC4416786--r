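#' Pipeline run configuration
#'
#' Collects input paths and all tunable parameters of the analysis chain.
#' The configuration round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param concentrations,dialysis,slices,srm,srm_blanks Input CSV paths
#'   (`srm` and `srm_blanks` may be `NULL` to skip the proteomics stage).
#' @param out_dir Output directory for the report bundle.
#' @param v_water,v_protein Vascular spaces, ml/g (see
#'   [vascular_params()]).
#' @param v_film Slice surface-fluid correction, ml/g.
#' @param ldh_threshold,min_ph Slice viability QC thresholds.
#' @param loq_k LOQ noise multiplier.
#' @param loq_fallback Fallback LOQ when blanks are insufficient.
#' @param ttest_var_equal Pooled-variance Student's test if `TRUE`
#'   (default; Welch's otherwise).
#' @param alpha Significance level for distribution comparisons.
#' @param seed Seed recorded for provenance.
#' @return A list of class `kpuu_config`.
#' @export
run_config <- function(concentrations, dialysis, slices, srm = NULL,
                       srm_blanks = NULL, out_dir = "kpuu_report",
                       v_water = 0.0103, v_protein = 0.0080, v_film = 0,
                       ldh_threshold = 0.25, min_ph = 7.25, loq_k = 3,
                       loq_fallback = NULL, ttest_var_equal = TRUE,
                       alpha = 0.05, seed = 1L) {
  cfg <- list(concentrations = concentrations, dialysis = dialysis,
              slices = slices, srm = srm, srm_blanks = srm_blanks,
              out_dir = out_dir, v_water = v_water, v_protein = v_protein,
              v_film = v_film, ldh_threshold = ldh_threshold,
              min_ph = min_ph, loq_k = loq_k, loq_fallback = loq_fallback,
              ttest_var_equal = ttest_var_equal, alpha = alpha,
              seed = as.integer(seed))
  structure(cfg, class = "kpuu_config")
}

#' @rdname run_config
#' @param config A `kpuu_config` object.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "kpuu_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Validates all inputs (stopping with an itemized report on schema or
#' invariant violations), derives fu,plasma from the dialysis table and
#' Vu,brain from the slice table (with viability QC), computes per-animal
#' residual-blood-corrected Kp and Kp,uu, summarizes groups, performs the
#' knockout-vs-wild-type and humanized-vs-wild-type Student's t-tests,
#' builds the blocker-ratio table where blocker-treated groups exist, and
#' — when SRM tables are configured — the censored protein expression
#' table with between-group comparisons.  Writes a plain-text report
#' bundle (TSV tables plus a machine-readable `results.json` and a
#' provenance log) into `config$out_dir`.  All report tables are
#' deterministic for fixed inputs; timestamps appear only in the log.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with all intermediate and final tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "kpuu_config"))
  paths <- list(concentrations = config$concentrations,
                dialysis = config$dialysis, slices = config$slices)
  if (!is.null(config$srm)) paths$srm <- config$srm
  if (!is.null(config$srm_blanks)) paths$srm_blanks <- config$srm_blanks
  findings <- validate_inputs(paths)
  if (any(findings$severity == "error")) {
    stop("input validation failed:\n",
         paste(sprintf("  [%s row %s] %s: %s", findings$file, findings$row,
                       findings$column, findings$message)[
                         findings$severity == "error"],
               collapse = "\n"), call. = FALSE)
  }
  params <- vascular_params(config$v_water, config$v_protein)
  conc <- read_concentrations(config$concentrations)
  conc$treatment[is.na(conc$treatment)] <- ""
  dia <- read_dialysis(config$dialysis)
  sli <- read_slices(config$slices)

  fu <- compute_fu_plasma(dia)
  vu <- compute_vu_brain(sli, v_film = config$v_film,
                         ldh_threshold = config$ldh_threshold,
                         min_ph = config$min_ph)
  binding <- merge(fu$summary[, c("drug", "genotype", "f_u_plasma")],
                   vu$summary[, c("drug", "v_u_brain")], by = "drug")
  dm <- distribution_metrics(conc, binding, params)
  kp_groups <- summarize_groups(dm, "kp")

  # reference table: untreated groups with group-mean Kp and derived Kp,uu
  untreated <- kp_groups[kp_groups$treatment == "", , drop = FALSE]
  table1 <- merge(untreated[, c("drug", "genotype", "n", "mean")],
                  binding, by = c("drug", "genotype"))
  names(table1)[names(table1) == "mean"] <- "kp"
  table1$kpuu_raw <- compute_kpuu(table1$kp, table1$v_u_brain,
                                  table1$f_u_plasma)
  table1$kpuu <- round_kpuu(table1$kpuu_raw)
  table1 <- table1[order(table1$drug, table1$genotype), , drop = FALSE]

  # genotype contrasts within drug x treatment (knockout vs its control,
  # humanized vs its control)
  contrasts <- list(c("FVB_WT", "MDR1A1B_KO"), c("C57BL6_WT", "HMDR1"))
  tt_rows <- list()
  for (d in unique(dm$drug)) {
    for (trt in unique(dm$treatment[dm$drug == d])) {
      for (ct in contrasts) {
        a <- dm$kp[dm$drug == d & dm$treatment == trt &
                     dm$genotype == ct[1L]]
        b <- dm$kp[dm$drug == d & dm$treatment == trt &
                     dm$genotype == ct[2L]]
        if (length(a) == 0L || length(b) == 0L) next
        res <- ttest_unpaired(a, b, alpha = config$alpha,
                              var_equal = config$ttest_var_equal)
        tt_rows[[length(tt_rows) + 1L]] <- cbind(
          data.frame(drug = d, treatment = trt, group_a = ct[1L],
                     group_b = ct[2L], n_a = length(a), n_b = length(b)),
          res)
      }
    }
  }
  ttests <- if (length(tt_rows)) do.call(rbind, tt_rows) else NULL
  if (!is.null(ttests)) attr(ttests, "n_tests") <- nrow(ttests)

  ratios <- blocker_ratio_table(kp_groups)

  qtap <- NULL
  if (!is.null(config$srm)) {
    srm <- read_srm(config$srm)
    blanks <- if (!is.null(config$srm_blanks))
      read_srm_blanks(config$srm_blanks) else NULL
    expr <- qtap_expression_table(srm, blanks = blanks,
                                  k_noise = config$loq_k,
                                  loq_fallback = config$loq_fallback)
    loq_table <- compute_loq(blanks, k_noise = config$loq_k,
                             loq_fallback = config$loq_fallback)
    q <- quantify_transitions(srm)
    groups <- sort(unique(expr$group))
    comp <- NULL
    fc <- NULL
    if (length(groups) == 2L) {
      comp_rows <- list()
      fc_rows <- list()
      for (mol in unique(expr$molecule)) {
        e1 <- expr[expr$molecule == mol & expr$group == groups[1L], ]
        e2 <- expr[expr$molecule == mol & expr$group == groups[2L], ]
        pool_of <- function(e, g) {
          if (e$status != "expressed") return(NULL)
          d <- q[q$molecule == mol & q$group == g, , drop = FALSE]
          pos <- assess_positivity(d, loq_table)
          keep <- pos$transitions$transition_id[pos$transitions$positive]
          d$amount[d$valid & d$transition_id %in% keep]
        }
        comp_rows[[length(comp_rows) + 1L]] <- cbind(
          data.frame(molecule = mol, group_a = groups[1L],
                     group_b = groups[2L]),
          compare_expression_groups(pool_of(e1, groups[1L]),
                                    pool_of(e2, groups[2L]),
                                    var_equal = config$ttest_var_equal))
        fc_rows[[length(fc_rows) + 1L]] <- fold_change(e2, e1)
      }
      comp <- do.call(rbind, comp_rows)
      fc <- do.call(rbind, fc_rows)
    }
    cells <- vapply(seq_len(nrow(expr)), function(i)
      format_expression_cell(expr[i, ]), character(1L))
    formatted <- data.frame(molecule = expr$molecule, group = expr$group,
                            cell = cells)
    qtap <- list(expression = expr, loq = loq_table, comparisons = comp,
                 fold_changes = fc, formatted = formatted)
  }

  out <- list(config = config, findings = findings, fu = fu, vu = vu,
              binding = binding, distribution = dm, kp_groups = kp_groups,
              table1 = table1, ttests = ttests, ratios = ratios,
              qtap = qtap)
  write_report_bundle(out)
  invisible(out)
}

# Writes the plain-text report bundle; timestamps only in the log.
write_report_bundle <- function(res) {
  cfg <- res$config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  cfg_path <- p("config.yaml")
  write_config(cfg, cfg_path)
  write_tsv(res$distribution, p("distribution_per_animal.tsv"))
  write_tsv(res$table1, p("kpuu_table.tsv"))
  write_tsv(res$kp_groups, p("group_summaries.tsv"))
  if (!is.null(res$ttests)) write_tsv(res$ttests, p("ttests.tsv"))
  if (nrow(res$ratios)) write_tsv(res$ratios, p("blocker_ratios.tsv"))
  write_tsv(res$vu$slices, p("qc_slices.tsv"))
  if (!is.null(res$qtap)) {
    write_tsv(res$qtap$expression, p("qtap_expression.tsv"))
    write_tsv(res$qtap$formatted, p("qtap_formatted.tsv"))
    if (!is.null(res$qtap$comparisons))
      write_tsv(res$qtap$comparisons, p("qtap_comparisons.tsv"))
    if (!is.null(res$qtap$fold_changes))
      write_tsv(res$qtap$fold_changes, p("qtap_fold_changes.tsv"))
  }
  json <- list(
    kpuu = res$table1[, c("drug", "genotype", "kp", "v_u_brain",
                          "f_u_plasma", "kpuu_raw", "kpuu")],
    blocker_ratios = res$ratios,
    n_ttests = if (is.null(res$ttests)) 0L else nrow(res$ttests))
  if (!is.null(res$qtap)) json$expression <- res$qtap$expression
  jsonlite::write_json(json, p("results.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  inputs <- c(concentrations = cfg$concentrations,
              dialysis = cfg$dialysis, slices = cfg$slices,
              srm = cfg$srm, srm_blanks = cfg$srm_blanks)
  inputs <- inputs[!vapply(inputs, is.null, logical(1L))]
  log_lines <- c(
    paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("config md5: ", unname(tools::md5sum(cfg_path))),
    paste0("seed: ", cfg$seed),
    paste0("input md5 ", names(inputs), ": ",
           unname(tools::md5sum(unlist(inputs)))),
    paste0("animals: ", nrow(res$distribution)),
    paste0("t-tests performed (no multiplicity correction): ",
           if (is.null(res$ttests)) 0L else nrow(res$ttests)))
  writeLines(log_lines, p("run.log"))
  invisible(NULL)
}
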