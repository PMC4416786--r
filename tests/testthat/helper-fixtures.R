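# Shared builders for small in-memory fixtures.

# A transition block for one molecule in one group: 4 transition sets x
# `runs` runs at the given per-transition mean amounts, with unit IS
# amount/protein so `amount == area_analyte / area_is`.
make_transitions <- function(molecule = "mol", group = "G",
                             amounts = c(1, 1, 1, 1), runs = 3,
                             rt_match = TRUE, area_is = 1e5) {
  stopifnot(length(amounts) == 4L)
  do.call(rbind, lapply(1:4, function(tid) {
    data.frame(molecule = molecule, probe_set = "common", group = group,
               transition_id = paste0("Q1Q3-", tid),
               run_id = paste0("run", seq_len(runs)),
               area_analyte = amounts[tid] * area_is, area_is = area_is,
               is_amount_fmol = 1, protein_injected_ug = 1,
               rt_match = rt_match)
  }))
}

# A constant LOQ table for one molecule's four transitions.
make_loq_table <- function(molecule = "mol", loq = 0.1) {
  data.frame(molecule = molecule, transition_id = paste0("Q1Q3-", 1:4),
             loq = loq)
}

# One-row expression results for fold-change tests.
expr_row <- function(molecule, group, level = NA, loq = 0.1,
                     status = if (is.na(level)) "ULQ" else "expressed") {
  data.frame(molecule = molecule, group = group, status = status,
             level = level, sem = 0, loq = loq, n_values = 12L,
             positive_count = if (status == "expressed") 4L else 0L)
}

# Slice records at exact equilibrium (no noise) for a given Vu,brain.
make_slices <- function(vu, n = 4, drug = "drugA", c_buffer = 100,
                        dilution = 10, end_ph = 7.4, ldh = 0.1,
                        v_film = 0) {
  data.frame(drug = drug, slice_id = sprintf("s%02d", seq_len(n)),
             slice_weight = 0.03, c_buffer_final = c_buffer,
             c_slice_homog = (vu + v_film) * c_buffer / dilution,
             slice_dilution = dilution, end_ph = end_ph,
             ldh_release_fraction = ldh)
}
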