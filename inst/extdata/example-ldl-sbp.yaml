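# Worked-example configuration: effect of LDL cholesterol (mmol/l) on
# systolic blood pressure (mmHg), with body-mass index (kg/m^2) as the
# measured confounder and blood glucose (mmol/l) treated as unmeasured.
#
# The covariance matrix in example-ldl-sbp-cov-synthetic.csv is SYNTHETIC:
# it is an invented, plausibly-scaled stand-in, NOT estimated from any
# cohort. Use it only to exercise the covariance-based generator and the
# two documented prior configurations below.
note: >
  Synthetic stand-in moments; not cohort data. Roles: outcome = sbp,
  exposure = ldl, measured confounder = bmi, unmeasured confounder = bgl.
covariance: example-ldl-sbp-cov-synthetic.csv
means: [140.0, 3.2, 27.0, 6.5]
n: 1000
priors:
  # prior mean from a full-model fit; precision equal to the sample size
  full_model:
    mean: 0.32
    tau: 1000
  # prior mean from external literature; weaker precision
  literature:
    mean: 0.77
    tau: 100
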