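# shared fixture builders

# a hand-specified record with sensible defaults for all schema columns;
# override any field by name
make_record <- function(patient_id = "P001", age_years = 67, sex = "male",
                        smoker = 0, alcohol_excess = 0, sbp_mmhg = 175,
                        dbp_mmhg = 95, pulse_bpm = 80, sodium_mmol_l = 139,
                        potassium_mmol_l = 4.1, glucose_mmol_l = 8.1,
                        hb_g_l = 140, wbc_1e9_l = 9.4, platelets_1e9_l = 220,
                        onset_to_ct_h = 4, icv_cm3 = 1344,
                        total_vol_cm3 = 36, parenchymal_vol_cm3 = 30,
                        ivh_vol_cm3 = 6, ivh_present = 1,
                        fu_total_vol_cm3 = 20, fu_icv_cm3 = 1340,
                        fu_ivh_present = 0, death30 = 0,
                        exclusion_codes = "") {
  data.frame(patient_id = patient_id, age_years = age_years, sex = sex,
             smoker = smoker, alcohol_excess = alcohol_excess,
             sbp_mmhg = sbp_mmhg, dbp_mmhg = dbp_mmhg, pulse_bpm = pulse_bpm,
             sodium_mmol_l = sodium_mmol_l,
             potassium_mmol_l = potassium_mmol_l,
             glucose_mmol_l = glucose_mmol_l, hb_g_l = hb_g_l,
             wbc_1e9_l = wbc_1e9_l, platelets_1e9_l = platelets_1e9_l,
             onset_to_ct_h = onset_to_ct_h, icv_cm3 = icv_cm3,
             total_vol_cm3 = total_vol_cm3,
             parenchymal_vol_cm3 = parenchymal_vol_cm3,
             ivh_vol_cm3 = ivh_vol_cm3, ivh_present = ivh_present,
             fu_total_vol_cm3 = fu_total_vol_cm3, fu_icv_cm3 = fu_icv_cm3,
             fu_ivh_present = fu_ivh_present, death30 = death30,
             exclusion_codes = exclusion_codes, stringsAsFactors = FALSE)
}

make_records <- function(...) do.call(rbind, list(...))

# binary-covariate dataset from 2x2 cell counts
# (exposed/unexposed x event/no-event)
data_2x2 <- function(n11, n10, n01, n00) {
  data.frame(
    x = c(rep(1, n11 + n10), rep(0, n01 + n00)),
    death30 = c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00)))
}

# the worked-example patient as a score input
example_patient <- function() suspekt_worked_example()$x
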