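# Hand-coded derivative of the FC-epsilon-RI-gamma cascade, written directly
# from the reaction scheme as an independent oracle for the assembled ODEs.
fc_oracle_deriv <- function(state, p) {
  J1 <- p[["FCepsilonRI/k_f1"]] * state[["FC"]] * state[["pLyn"]] -
    p[["FCepsilonRI/k_r1"]] * state[["FC_pLyn"]]
  J2 <- p[["FCepsilonRI/k_f2"]] * state[["FC_pLyn"]]
  J3 <- p[["FCepsilonRI/k_f3"]] * state[["Lyn"]] * state[["Pi"]]
  J4 <- p[["FCepsilonRI/k_f4"]] * state[["pFC"]] * state[["Syk"]] -
    p[["FCepsilonRI/k_r4"]] * state[["pFC_Syk"]]
  J5 <- p[["FCepsilonRI/k_f5"]] * state[["pFC_Syk"]]
  J6 <- p[["FCepsilonRI/k_f6"]] * state[["pSyk"]] * state[["Grb2"]] -
    p[["FCepsilonRI/k_r6"]] * state[["pSyk_Grb2"]]
  J7 <- p[["FCepsilonRI/k_f7"]] * state[["pSyk_Grb2"]]
  c(FC = -J1,
    pLyn = -J1 + J3,
    Syk = -J4,
    Grb2 = -J6,
    Lyn = J2 - J3,
    pSyk = J5 - J6 + J7,
    pGrb2 = J7,
    Pi = 0,
    FC_pLyn = J1 - J2,
    pFC = J2 - J4 + J5,
    pFC_Syk = J4 - J5,
    pSyk_Grb2 = J6 - J7)
}

random_fc_states <- function(n, seed = 42L) {
  set.seed(seed)
  nm <- c("FC", "pLyn", "Syk", "Grb2", "Lyn", "pSyk", "pGrb2", "Pi",
          "FC_pLyn", "pFC", "pFC_Syk", "pSyk_Grb2")
  lapply(seq_len(n), function(i) stats::setNames(stats::runif(12, 0, 5), nm))
}

tsang_grb2_dataset <- function(times = c(1, 4, 16, 64, 256, 1024, 3600)) {
  sc <- tsang_scenario()
  generate_synthetic_timecourse(sc$model, numeric(), "pGrb2",
                                times)$pGrb2
}
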