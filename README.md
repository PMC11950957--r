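# rtdosepred

Anatomy-driven dose prediction and rectal NTCP estimation for prostate
radiotherapy, as a self-contained, fully tested R pipeline.

## The problem

In prostate VMAT (volumetric modulated arc therapy), late rectal bleeding
risk is largely fixed by the patient's anatomy — above all by the gap
between the planning target volume (PTV) and the anterior rectal wall.
Decisions such as hydrogel-spacer implantation must be made *before* a
treatment plan exists, so estimating the baseline risk directly from
anatomy is clinically useful. `rtdosepred` implements the full chain:

* a **synthetic pelvic phantom generator** emulating a cohort of VMAT
  plans (74.8 Gy in 34 fractions) — CT-like image, six structure masks,
  and an analytic PTV-conformal planned dose with a concave
  rectum-sparing fall-off — so every stage runs and is tested without
  patient data;
* **preprocessing**: body-centred crop/resize, PTV ± 1 cm slice
  selection, coverage rescaling (95% of the PTV receives 95% of the
  prescription), cohort-level dose normalization, 7-channel stack
  assembly (CT, rectum, bladder, femoral heads, PTV, body);
* a **2D U-net** (residual blocks, batch norm, dropout 0.1, skip
  concatenations) predicting the 3D dose slice by slice, trained with
  Adam on voxelwise MSE under 5-fold cross-validation and applied as a
  prediction-averaging fold ensemble — implemented from the ground up in
  Rcpp/RcppArmadillo, no deep-learning framework required;
* **DVH metrics** (D_x%, V_xGy, homogeneity index, R50%) and the
  **isodose Dice similarity coefficient** (iDSC) between planned and
  predicted doses;
* **NTCP models**: per-bin EQD2 conversion (α/β = 3 Gy) feeding the
  Lyman–Kutcher–Burman model
  `NTCP = Φ((Deff − TD50)/(m·TD50))`, `Deff = (Σ v_i EQD2_i^{1/n})^n`,
  and the relative-seriality model
  `NTCP = (1 − Π (1 − P(D_i)^s)^{v_i})^{1/s}` with
  `P(D) = 2^{−exp(e^γ(1−D/D50))}`, for seven published rectal LKB
  endpoints and the RS grade ≥ 2 late-rectal-bleeding endpoint;
* **evaluation**: %MAE in the two field conventions, OLS regression of
  predicted on planned metrics with Wald t-tests, power analysis for a
  target R², and a cohort report in the standard comparison-table
  layout.

## Worked example

```r
library(rtdosepred)

# a small phantom cohort (64 x 64 x 32 voxels at 3 mm)
cfg    <- phantom_config()
cohort <- generate_cohort(cfg, n = 12)

# preprocess; train a 5-fold ensemble; predict a held-out case
pp  <- preprocess_config(target_size = 48)
tr  <- preprocess_cohort(cohort[1:10], pp)
te  <- preprocess_cohort(cohort[11:12], pp, norm_constant = tr$norm_constant)
cv  <- cross_validate(tr$stacks, tr$doses,
                      net_config(base_features = 4, depth = 3),
                      train_config(epochs = 60, seed = 1, folds = 5))
s   <- te$samples[[1]]
pd  <- predict_dose(cv$models, s, te$stacks[[1]], tr$norm_constant, pp)

# compare: NTCP and isodose overlap of planned vs predicted dose
ntcp_suite(s$dose, s$masks$rectum)[2, ]   # planned G2-LRB (LKB): 10.90 %
ntcp_suite(pd,    s$masks$rectum)[2, ]    # predicted:            11.27 %
mean_idsc(s$dose, pd, 50, body = s$masks$body)   # 0.74
```

The planned grade ≥ 2 late-rectal-bleeding NTCP (10.90%) sits in the
cohort's calibrated 8–17% band and the prediction from anatomy alone
tracks it (11.27%); the high-dose isodose Dice (0.74 here) is the
planned/predicted overlap fraction averaged over 1-Gy levels from 50 Gy
to the prescription — a 10-phantom toy training run; accuracy improves
with cohort size. The package's feasibility test runs the same
experiment at 40 training / 10 test phantoms, where predicted vs planned
NTCP over the test cohort reaches R² ≥ 0.5 with a mean absolute error
below 3 percentage points.

A subcommand-style CLI wrapping the same functions
(`simulate | preprocess | train | predict | evaluate`) ships in
`inst/cli/rtdosepred.R`.

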