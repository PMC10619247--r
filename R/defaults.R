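# Default calibration of the synthetic-hospitalization generator: condition
# prevalences, per-outcome ground-truth effect sizes (odds ratios / log-day
# betas) and marginal outcome rates for a large internal-medicine service.

study_n <- 55946L

# per-condition marginal prevalences (proportions of hospitalizations); the
# two near-empty categories (AIDS/HIV, blood-loss anemia) are carried at
# their exact count-based rates (16/55,946 and 6/55,946)
default_condition_prevalences <- c(
  congestive_heart_failure = 0.27,
  cardiac_arrhythmias = 0.039,
  valvular_disease = 0.14,
  pulmonary_circulation = 0.077,
  peripheral_vascular = 0.22,
  hypertension = 0.46,
  paralysis = 0.015,
  other_neurological = 0.046,
  chronic_pulmonary = 0.12,
  diabetes_uncomplicated = 0.12,
  diabetes_complicated = 0.013,
  hypothyroidism = 0.11,
  renal_failure = 0.022,
  liver_disease = 0.021,
  peptic_ulcer = 0.009,
  aids_hiv = 16 / 55946,
  lymphoma = 0.008,
  metastatic_cancer = 0.024,
  solid_tumor = 0.082,
  rheumatoid_arthritis = 0.021,
  coagulopathy = 0.020,
  obesity = 0.057,
  weight_loss = 0.005,
  fluid_electrolyte = 0.13,
  blood_loss_anemia = 6 / 55946,
  deficiency_anemia = 0.07,
  alcohol_abuse = 0.004,
  drug_abuse = 0.001,
  psychoses = 0.025,
  depression = 0.044)

#' Default comorbidity prevalences
#'
#' Per-condition marginal prevalences used by the synthetic generator,
#' expressed as proportions of hospitalizations (most common: hypertension
#' 46%, congestive heart failure 27%; rarest: blood-loss anemia and AIDS/HIV
#' below 0.05%).
#'
#' @return named numeric vector over the 30 condition keys.
#' @export
default_prevalences <- function() default_condition_prevalences

# ground-truth odds ratios per outcome, analysis conditions only
# (blood-loss anemia is excluded from the models)
default_or_mortality <- c(
  congestive_heart_failure = 1.69, cardiac_arrhythmias = 0.82,
  valvular_disease = 0.94, pulmonary_circulation = 1.10,
  peripheral_vascular = 1.26, hypertension = 1.05, paralysis = 1.39,
  other_neurological = 2.13, chronic_pulmonary = 0.89,
  diabetes_uncomplicated = 0.94, diabetes_complicated = 0.82,
  hypothyroidism = 1.33, renal_failure = 1.58, liver_disease = 1.63,
  peptic_ulcer = 0.90, aids_hiv = 1.38, lymphoma = 1.76,
  metastatic_cancer = 2.45, solid_tumor = 2.43, rheumatoid_arthritis = 1.13,
  coagulopathy = 2.49, obesity = 0.56, weight_loss = 2.16,
  fluid_electrolyte = 2.52, deficiency_anemia = 1.19, alcohol_abuse = 0.60,
  drug_abuse = 0.59, psychoses = 0.83, depression = 0.88)

default_or_escalation <- c(
  congestive_heart_failure = 1.85, cardiac_arrhythmias = 1.09,
  valvular_disease = 1.58, pulmonary_circulation = 1.24,
  peripheral_vascular = 1.15, hypertension = 1.08, paralysis = 1.30,
  other_neurological = 1.96, chronic_pulmonary = 1.55,
  diabetes_uncomplicated = 1.12, diabetes_complicated = 0.84,
  hypothyroidism = 1.02, renal_failure = 1.39, liver_disease = 1.20,
  peptic_ulcer = 0.74, aids_hiv = 4.02, lymphoma = 0.89,
  metastatic_cancer = 1.00, solid_tumor = 0.85, rheumatoid_arthritis = 1.12,
  coagulopathy = 1.32, obesity = 1.28, weight_loss = 1.13,
  fluid_electrolyte = 2.18, deficiency_anemia = 1.06, alcohol_abuse = 1.43,
  drug_abuse = 1.83, psychoses = 1.32, depression = 0.73)

default_or_readmission <- c(
  congestive_heart_failure = 1.43, cardiac_arrhythmias = 0.83,
  valvular_disease = 1.04, pulmonary_circulation = 1.21,
  peripheral_vascular = 1.19, hypertension = 1.04, paralysis = 1.12,
  other_neurological = 1.19, chronic_pulmonary = 1.27,
  diabetes_uncomplicated = 0.99, diabetes_complicated = 1.25,
  hypothyroidism = 1.13, renal_failure = 1.10, liver_disease = 1.14,
  peptic_ulcer = 1.21, aids_hiv = 0.54, lymphoma = 1.38,
  metastatic_cancer = 1.26, solid_tumor = 1.56, rheumatoid_arthritis = 1.07,
  coagulopathy = 1.13, obesity = 0.83, weight_loss = 1.67,
  fluid_electrolyte = 1.33, deficiency_anemia = 1.13, alcohol_abuse = 1.14,
  drug_abuse = 0.77, psychoses = 1.51, depression = 1.04)

# additive effects on log length of stay (log-day scale)
default_beta_log_los <- c(
  congestive_heart_failure = 0.21, cardiac_arrhythmias = 0.02,
  valvular_disease = 0.12, pulmonary_circulation = 0.08,
  peripheral_vascular = 0.10, hypertension = 0.10, paralysis = 0.31,
  other_neurological = 0.27, chronic_pulmonary = 0.05,
  diabetes_uncomplicated = 0.04, diabetes_complicated = 0.15,
  hypothyroidism = 0.08, renal_failure = 0.10, liver_disease = 0.16,
  peptic_ulcer = 0.02, aids_hiv = 0.28, lymphoma = 0.38,
  metastatic_cancer = 0.22, solid_tumor = 0.23, rheumatoid_arthritis = 0.09,
  coagulopathy = 0.25, obesity = 0.00, weight_loss = 0.59,
  fluid_electrolyte = 0.22, deficiency_anemia = 0.20, alcohol_abuse = 0.14,
  drug_abuse = 0.04, psychoses = 0.18, depression = 0.06)

default_outcome_rates <- c(mortality = 0.069, escalation = 0.13,
                           readmission = 0.15)

# diagnosis codes used as non-informative "noise" codes: common acute
# internal-medicine diagnoses (pneumonia, UTI, septicemia, fever, GERD,
# coronary atherosclerosis, hyperlipidemia, low back pain, acute kidney
# injury, URI, syncope) that map to no comorbidity group
default_noise_codes <- c("486", "5990", "0389", "78060", "53081", "41401",
                         "2724", "7242", "5849", "4659", "7802")
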