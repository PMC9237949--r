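# Parameter and initial-condition tables transcribed from the source
# publication for the KIR2DL4/HLA-G signalling model. Units: uM, s,
# uM^-1.s^-1 for bimolecular constants. Bounds are base-10 exponents.
# Conflicting duplicate values between tables are kept verbatim and
# flagged under `conflicts`; this file never resolves a conflict.
T1:
  title: Initial conditions for the FCepsilonRI-gamma sub-model (Tsang protocol)
  units: uM
  provenance: Syk and FCepsilon adapted from Tsang et al.; Grb2 and pLyn estimated during fitting
  values:
    FCe: 1.0
    Syk: 0.005
    Grb2: 6.47
    pLyn: 6.5
T2:
  title: Initial conditions for the FCepsilonRI-gamma sub-model (Faeder protocol)
  units: uM
  provenance: Estimation 1 derived from Faeder et al.; Estimation 2 estimated during model fitting
  estimation1:
    FCe: 0.474
    pLyn: 0.0332
    Syk: 0.432
    Grb2: .na
  estimation2:
    FCe: 0.0474
    pLyn: 0.0474
    Syk: 0.025
    Grb2: 0.01
T3-bounds:
  title: Fitting bounds (base-10 exponents) for the 23-parameter composite calibration
  units: exponent
  provenance: boundaries for fitting the composite model to Rajagopalan et al. data
  note: >
    The source table lists 24 rows; hGactivating/k_f10 appears twice with
    identical bounds, leaving 23 unique parameters.
  rows:
    - {parameter: hGactivating/k_f10, lower: -3, upper: 2}
    - {parameter: hGactivating/k_r10, lower: -3, upper: 2}
    - {parameter: FCepsilonRI/k_f1, lower: -3, upper: 1}
    - {parameter: FCepsilonRI/k_f5, lower: -3, upper: 0}
    - {parameter: FCepsilonRI/k_r1, lower: -3, upper: 3}
    - {parameter: FCepsilonRI/k_r4, lower: -3, upper: 0}
    - {parameter: FCepsilonRI/k_r6, lower: -3, upper: 0}
    - {parameter: hG_FC/k_f21, lower: -3, upper: 2}
    - {parameter: hG_FC/k_r21, lower: -3, upper: 2}
    - {parameter: PI3K/k_f2, lower: -3, upper: 2}
    - {parameter: PI3K/k_r2, lower: -3, upper: 2}
    - {parameter: PI3K/k_f3, lower: -3, upper: 2}
    - {parameter: dupont_NFAT/k_f, lower: -3, upper: 2}
    - {parameter: NFAT_cytokine/k_f4, lower: -5, upper: 5}
    - {parameter: NFAT_cytokine/k_f5, lower: -1, upper: 3}
    - {parameter: NFAT_cytokine/kf_31, lower: -3, upper: 2}
    - {parameter: NFAT_cytokine/kf_32, lower: -10, upper: -6}
    - {parameter: NFAT/kf_21, lower: -3, upper: 2}
    - {parameter: NFAT/kf_22, lower: -3, upper: 2}
    - {parameter: NFAT/kf_23, lower: -3, upper: 2}
    - {parameter: NFAT/kf_24, lower: -3, upper: 2}
    - {parameter: NFAT/kr_21, lower: -3, upper: 2}
    - {parameter: NFAT/kr_23, lower: -3, upper: 2}
    - {parameter: hGactivating/k_f10, lower: -3, upper: 2}
T4:
  title: HLA-G cytokines (composite) model initial conditions
  units: uM
  provenance: KIR2DL4 and HLA-G from Rajagopalan et al.; PI3K from Hatakeyama et al.; plc estimated
  values:
    KIR2DL4: 0.098
    PI3K: 0.01
    HLA-G: 0.1052
    plc: 1.3
T5:
  title: FCepsilonRI-gamma rate constants fitted to Tsang et al. data
  provenance: fitted values; bimolecular constants uM^-1.s^-1, unimolecular s^-1
  values:
    k_f1: 58.3902
    k_f2: 0.0082
    k_f3: 1.0887
    k_f4: 10.5797
    k_f5: 63.6727
    k_f6: 0.4143
    k_f7: 11.4185
    k_r1: 0.0136
    k_r4: 0.0807
    k_r6: 0.7313
  descriptions:
    k_f1: FC-pLyn binding rate
    k_f2: FC phosphorylation rate
    k_f3: Lyn phosphorylation rate
    k_f4: pFC-Syk binding rate
    k_f5: Syk phosphorylation rate
    k_f6: pSyk-Grb2 binding rate
    k_f7: Grb2 phosphorylation rate
    k_r1: FC-pLyn dissociation rate
    k_r4: pFC-Syk dissociation rate
    k_r6: pSyk-Grb2 dissociation rate
T6:
  title: Kinetic parameters held fixed in the Faeder-data refit
  provenance: parameters the Tsang-fitted model was sensitive to
  values:
    k_f2: 0.0081
    k_f4: 10.597
    k_f6: 0.4143
    k_f7: 11.4185
T7:
  title: Fitting bounds (base-10 exponents) for the Faeder-data refit
  units: exponent
  provenance: one-sided ranges chosen so Tsang-data predictions stay insensitive
  rows:
    - {parameter: k_f1, lower: -1.5, upper: 2}
    - {parameter: k_f3, lower: -3, upper: 2}
    - {parameter: k_f5, lower: 1, upper: 2}
    - {parameter: k_r1, lower: -3, upper: 1}
    - {parameter: k_r4, lower: -3, upper: 0.5}
    - {parameter: k_r6, lower: -3, upper: 0}
    - {parameter: Pi, lower: -3, upper: 2}
T8:
  title: Rate constants refitted to Faeder et al. data
  provenance: re-fitted parameters the Tsang-fitted model was not sensitive to
  values:
    k_f1: 54.7678
    k_f3: 0.0035
    k_f5: 33.7157
    k_r1: 0.0031
    k_r4: 0.1174
    k_r6: 0.481
T9:
  title: Consolidated FCepsilonRI-gamma parameters with fit/fix status
  provenance: fitted to Tsang et al. and Faeder et al. data sets
  rows:
    - {parameter: k_f1, value: 54.7678, source: Faeder, status: Fit}
    - {parameter: k_f2, value: 0.0082, source: Tsang, status: Fix}
    - {parameter: k_f3, value: 0.0035, source: Faeder, status: Fix}
    - {parameter: k_f4, value: 10.5797, source: Tsang, status: Fit}
    - {parameter: k_f5, value: 33.7157, source: Faeder, status: Fit}
    - {parameter: k_f6, value: 0.4143, source: Tsang, status: Fit}
    - {parameter: k_f7, value: 11.4185, source: Tsang, status: Fix}
    - {parameter: k_r1, value: 0.0031, source: Faeder, status: Fit}
    - {parameter: k_r4, value: 1.1174, source: Faeder, status: Fit}
    - {parameter: k_r6, value: 0.481, source: Faeder, status: Fit}
T10:
  title: Composite-model rate constants fitted to Rajagopalan et al. data
  provenance: fitted values; bimolecular constants uM^-1.s^-1, unimolecular s^-1
  values:
    hGactivating/k_f10: 0.0141
    hGactivating/k_r10: 0.0140
    FCepsilonRI/k_f1: 6.1804
    FCepsilonRI/k_f5: 0.8040
    FCepsilonRI/k_r1: 0.0015
    FCepsilonRI/k_r4: 0.13486
    FCepsilonRI/k_r6: 0.71853
    hG_FC/k_f21: 0.0165
    hG_FC/k_r21: 0.0517
    PI3K/k_f2: 8.9165
    PI3K/k_r2: 0.0061
    PI3K/k_f3: 14.6231
    dupont_NFAT/k_f: 0.0065
    NFAT_cytokine/k_f4: 0.0684
    NFAT_cytokine/k_f5: 23.1163
    NFAT_cytokine/kf_31: 0.0291
    NFAT_cytokine/kf_32: 9.7858e-03
    NFAT/kf_21: 0.0516
    NFAT/kf_22: 0.0030
    NFAT/kf_23: 0.0022
    NFAT/kf_24: 0.9844
    NFAT/kr_21: 2.0772
    NFAT/kr_23: 0.3345
T11:
  title: Cytokine means and standard deviations for uncertainty quantification
  units: uM
  provenance: experimental data summary used for the feasible-parameter census
  values:
    TNFa_mean: 9.5e-5
    TNFa_sd: 9.5e-5
    IFNg_mean: 1.0e-4
    IFNg_sd: 1.0e-4
conflicts:
  - parameter: k_f2
    readings: {T5: 0.0082, T6: 0.0081}
    note: rounding-level disagreement between tables; both kept, none preferred
  - parameter: k_f4
    readings: {T5: 10.5797, T6: 10.597}
    note: disagreement between the Tsang fit table and the fixed-parameter table
  - parameter: k_r4
    readings: {T8: 0.1174, T9: 1.1174}
    note: order-of-magnitude disagreement between the refit and status tables
  - parameter: hGactivating/k_f10
    readings: {T3-row-1: [-3, 2], T3-row-24: [-3, 2]}
    note: duplicated bounds row; 23 unique parameters
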