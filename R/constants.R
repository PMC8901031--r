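# Clinical constants used by the metric functions. Kept in one place so a
# literature revision is a one-line change.

# Symmetrizing blood-glucose risk transform (Kovatchev et al., Diabetes Care
# 1997/1998; ADRR: Kovatchev et al., Diabetes Care 2006). G in mg/dL:
#   f(G) = 1.509 * ((ln G)^1.084 - 5.381), risk = 10 * f^2 split by sign.
risk_constants <- list(scale = 1.509, power = 1.084, offset = 5.381)

# Glucose management indicator (Bergenstal et al., Diabetes Care 2018):
#   GMI(%) = 3.31 + 0.02392 * mean glucose (mg/dL).
gmi_constants <- list(intercept = 3.31, slope = 0.02392)

# Estimated A1c from mean glucose (ADAG study; Nathan et al., Diabetes Care
# 2008): eA1c(%) = (mean glucose + 46.7) / 28.7.
ea1c_constants <- list(offset = 46.7, scale = 28.7)

# Standard clinical thresholds: hypoglycemia < 70 mg/dL, hyperglycemia
# > 180 mg/dL.
clinical_thresholds <- c(hypo = 70, hyper = 180)

# Hard sanity bounds at parse time, deliberately wider than any sensor's
# reportable range (40-400/500 mg/dL) so real exports always pass.
glucose_bounds <- c(lower = 10, upper = 1000)
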