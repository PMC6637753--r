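## Shared fixtures (computed once per test run) and independent oracles.

fixtures_cache <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- make_fixtures()
    fx
  }
})

## ---------------------------------------------------------------------
## Flux-bookkeeping oracle: an independent evaluation of the model's time
## derivatives organized as a reaction list. Every elementary reaction is a
## (rate, stoichiometry) pair; the derivative of each species is the sum of
## stoichiometry * rate over all reactions. This is deliberately structured
## differently from grn_rhs (which writes one balance equation per species).
flux_oracle_rhs <- function(state, params) {
  x <- stats::setNames(as.numeric(state), species_names())
  p <- as.list(params)
  sto <- function(...) {
    v <- stats::setNames(numeric(29), species_names())
    kv <- list(...)
    for (nm in names(kv)) v[nm] <- kv[[nm]]
    v
  }
  mm <- function(s, k) s / (k + s)
  pool <- function(tot, act) max(tot - act, 0)

  reactions <- list(
    ## transcription / synthesis
    list(r = p$V_SMCYC * p$V_SMD * (p$e_MD + mm(p$GF, p$K_AGF)), s = sto(Md = 1)),
    list(r = p$V_SMCYC * p$V_SME * (p$e_ME + mm(x[["E2F"]], p$K_AE2F)), s = sto(Me = 1)),
    list(r = p$V_SMCYC * p$V_SMA * (p$e_MA + mm(x[["E2F"]], p$K_AE2F)), s = sto(Ma = 1)),
    list(r = p$V_SMCYC * p$V_SMB, s = sto(Mb = 1)),
    list(r = p$V_SE2F, s = sto(E2Ftot = 1)),
    list(r = p$V_SLET7, s = sto(Let7 = 1)),
    list(r = p$V_SLIN28 * x[["NFKB"]]^p$n_LIN28 /
           (p$K_ALIN28^p$n_LIN28 + x[["NFKB"]]^p$n_LIN28), s = sto(MLin28 = 1)),
    list(r = p$V_S0MIL6 + p$V_SMIL6 * mm(x[["NFKB"]], p$K_AMIL6), s = sto(MIL6 = 1)),
    list(r = p$V_SMIR21 * mm(x[["STAT3"]], p$K_AMIR21), s = sto(miR21 = 1)),
    list(r = p$V_SMPTEN, s = sto(MPTEN = 1)),
    list(r = p$V_SMRAS, s = sto(MRas = 1)),
    ## translation
    list(r = p$kT_CD * x[["Md"]], s = sto(Cd = 1)),
    list(r = p$kT_CE * x[["Me"]], s = sto(Ce = 1)),
    list(r = p$kT_CA * x[["Ma"]], s = sto(Ca = 1)),
    list(r = p$kT_CB * x[["Mb"]] * mm(x[["Ca"]], p$K_ACB), s = sto(Cb = 1)),
    list(r = p$kT_LIN28 * x[["MLin28"]], s = sto(Lin28 = 1)),
    list(r = p$kT_IL6 * x[["MIL6"]], s = sto(IL6 = 1)),
    list(r = p$kT_PTEN * x[["MPTEN"]] * p$K_MIR21PTEN /
           (p$K_MIR21PTEN + x[["miR21"]]), s = sto(PTEN = 1)),
    list(r = (p$kT_RAS + p$k_GFRAS * p$GF) * x[["MRas"]], s = sto(Ras = 1)),
    ## Let-7 binding / unbinding / complex decay (decay removes both partners)
    list(r = p$kA_MD * x[["Let7"]] * x[["Md"]], s = sto(Md = -1, Let7 = -1, CLd = 1)),
    list(r = p$kD_MD * x[["CLd"]], s = sto(Md = 1, Let7 = 1, CLd = -1)),
    list(r = p$kdCL_MD * x[["CLd"]], s = sto(CLd = -1)),
    list(r = p$kA_ME * x[["Let7"]] * x[["Me"]], s = sto(Me = -1, Let7 = -1, CLe = 1)),
    list(r = p$kD_ME * x[["CLe"]], s = sto(Me = 1, Let7 = 1, CLe = -1)),
    list(r = p$kdCL_ME * x[["CLe"]], s = sto(CLe = -1)),
    list(r = p$kA_MA * x[["Let7"]] * x[["Ma"]], s = sto(Ma = -1, Let7 = -1, CLa = 1)),
    list(r = p$kD_MA * x[["CLa"]], s = sto(Ma = 1, Let7 = 1, CLa = -1)),
    list(r = p$kdCL_MA * x[["CLa"]], s = sto(CLa = -1)),
    list(r = p$kA_MB * x[["Let7"]] * x[["Mb"]], s = sto(Mb = -1, Let7 = -1, CLb = 1)),
    list(r = p$kD_MB * x[["CLb"]], s = sto(Mb = 1, Let7 = 1, CLb = -1)),
    list(r = p$kdCL_MB * x[["CLb"]], s = sto(CLb = -1)),
    list(r = p$kA_MIL6 * x[["Let7"]] * x[["MIL6"]],
         s = sto(MIL6 = -1, Let7 = -1, CL_IL6 = 1)),
    list(r = p$kD_MIL6 * x[["CL_IL6"]], s = sto(MIL6 = 1, Let7 = 1, CL_IL6 = -1)),
    list(r = p$kdCL_MIL6 * x[["CL_IL6"]], s = sto(CL_IL6 = -1)),
    list(r = p$kA_MRAS * x[["Let7"]] * x[["MRas"]],
         s = sto(MRas = -1, Let7 = -1, CL_Ras = 1)),
    list(r = p$kD_MRAS * x[["CL_Ras"]], s = sto(MRas = 1, Let7 = 1, CL_Ras = -1)),
    list(r = p$kdCL_MRAS * x[["CL_Ras"]], s = sto(CL_Ras = -1)),
    ## pool activation / inactivation
    list(r = p$V_AE2F * mm(x[["Cd"]] + x[["Ce"]], p$K_AE2FC) *
           mm(pool(x[["E2Ftot"]], x[["E2F"]]), p$K_AE2FP), s = sto(E2F = 1)),
    list(r = (p$V_I0E2F + p$V_IE2F * x[["Ca"]]) * mm(x[["E2F"]], p$K_IE2F),
         s = sto(E2F = -1)),
    list(r = p$V_AAPC * x[["Cb"]] * mm(pool(1, x[["APC"]]), p$K_AAPC),
         s = sto(APC = 1)),
    list(r = p$V_IAPC * mm(x[["APC"]], p$K_IAPC), s = sto(APC = -1)),
    list(r = (p$k_AA1NFKB * p$Src +
              p$k_AA2NFKB * x[["STAT3"]]^p$n_STAT3 /
                (p$K_S3NFKB^p$n_STAT3 + x[["STAT3"]]^p$n_STAT3) +
              p$k_AA3NFKB * x[["Ras"]]) * mm(pool(1, x[["NFKB"]]), p$K_ANFKB),
         s = sto(NFKB = 1)),
    list(r = p$V_INFKB * (1 + p$k_PTENNFKB * x[["PTEN"]]) *
           mm(x[["NFKB"]], p$K_INFKB), s = sto(NFKB = -1)),
    list(r = (p$V_A1STAT3 * x[["IL6"]] + p$V_A2STAT3 * x[["NFKB"]]) *
           mm(pool(1, x[["STAT3"]]), p$K_ASTAT3), s = sto(STAT3 = 1)),
    list(r = p$V_ISTAT3 * mm(x[["STAT3"]], p$K_ISTAT3), s = sto(STAT3 = -1)),
    ## first-order decays
    list(r = p$kd_MD * x[["Md"]], s = sto(Md = -1)),
    list(r = p$kd_ME * x[["Me"]], s = sto(Me = -1)),
    list(r = p$kd_MA * x[["Ma"]], s = sto(Ma = -1)),
    list(r = p$kd_MB * x[["Mb"]], s = sto(Mb = -1)),
    list(r = p$kd_CD * x[["Cd"]], s = sto(Cd = -1)),
    list(r = p$kd_CE * x[["Ce"]], s = sto(Ce = -1)),
    list(r = (p$kd_CA + p$kdAPC_CA * x[["APC"]]) * x[["Ca"]], s = sto(Ca = -1)),
    list(r = (p$kd_CB + p$kdAPC_CB * x[["APC"]]) * x[["Cb"]], s = sto(Cb = -1)),
    list(r = p$kd_E2F * x[["E2F"]], s = sto(E2F = -1)),
    list(r = p$kd_E2F * x[["E2Ftot"]], s = sto(E2Ftot = -1)),
    list(r = (p$kd_LET7 + p$kdL7_LIN28 * x[["Lin28"]]) * x[["Let7"]],
         s = sto(Let7 = -1)),
    list(r = p$kd_MLIN28 * x[["MLin28"]], s = sto(MLin28 = -1)),
    list(r = p$kd_LIN28 * x[["Lin28"]], s = sto(Lin28 = -1)),
    list(r = p$kd_MIL6 * x[["MIL6"]], s = sto(MIL6 = -1)),
    list(r = p$kd_IL6 * x[["IL6"]], s = sto(IL6 = -1)),
    list(r = p$kd_MIR21 * x[["miR21"]], s = sto(miR21 = -1)),
    list(r = p$kd_MPTEN * x[["MPTEN"]], s = sto(MPTEN = -1)),
    list(r = p$kd_PTEN * x[["PTEN"]], s = sto(PTEN = -1)),
    list(r = p$kd_MRAS * x[["MRas"]], s = sto(MRas = -1)),
    list(r = p$kd_RAS * x[["Ras"]], s = sto(Ras = -1))
  )
  d <- stats::setNames(numeric(29), species_names())
  for (rx in reactions) d <- d + rx$r * rx$s
  d
}

## ---------------------------------------------------------------------
## Independent fixed-step classical 4th-order Runge-Kutta integrator over
## the reference R right-hand side.
rk4_integrate <- function(y0, params, t_end, dt) {
  y <- stats::setNames(as.numeric(y0), species_names())
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- grn_rhs(y, 0, params)
    k2 <- grn_rhs(y + dt / 2 * k1, 0, params)
    k3 <- grn_rhs(y + dt / 2 * k2, 0, params)
    k4 <- grn_rhs(y + dt * k3, 0, params)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y
}

## random non-negative state (roughly on the scale of model variables)
random_state <- function() {
  y <- stats::setNames(stats::runif(29, 0, 3), species_names())
  y["Let7"] <- stats::runif(1, 0, 50)
  y["E2Ftot"] <- stats::runif(1, 0.5, 2)
  y["E2F"] <- stats::runif(1, 0, y[["E2Ftot"]])
  for (sp in c("APC", "NFKB", "STAT3")) y[sp] <- stats::runif(1)
  y
}
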