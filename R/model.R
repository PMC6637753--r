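#' Canonical species names of the coupled model
#'
#' The state vector has 29 non-negative components: 15 for the cell-cycle
#' (Cdk) block and 14 for the transformation block, with Let-7 as the shared
#' species. `M*` are free mRNAs, `CL*` are translationally inactive
#' Let-7/mRNA complexes, `C*` are cyclin/Cdk complexes; E2F, E2Ftot, APC,
#' NFKB and STAT3 are (active / total) transcription-factor pools.
#'
#' @return Character vector of length 29, in canonical order.
#' @export
species_names <- function() {
  c(
    ## cell-cycle block (15)
    "Md", "Me", "Ma", "Mb",          # free cyclin D/E/A/B mRNA
    "CLd", "CLe", "CLa", "CLb",      # Let-7 . cyclin mRNA complexes
    "Cd", "Ce", "Ca", "Cb",          # cyclin D/Cdk4-6, E/Cdk2, A/Cdk2, B/Cdk1
    "E2F", "E2Ftot",                 # active and total E2F
    "APC",                           # active APC fraction
    ## transformation block (14)
    "Let7",
    "NFKB",
    "MLin28", "Lin28",
    "MIL6", "CL_IL6", "IL6",
    "STAT3",
    "miR21",
    "MPTEN", "PTEN",
    "MRas", "CL_Ras", "Ras"
  )
}

#' Default initial state
#'
#' A low-activation state: all species zero except small E2Ftot and high
#' free Let-7 (its basal steady level in the absence of sponging), from
#' which the non-transformed quiescent attractor is reached under basal
#' parameters.
#'
#' @param params Parameter vector (used to place Let7 near its basal level).
#' @return Named state vector of length 29.
#' @export
initial_state <- function(params = default_parameters()) {
  s <- stats::setNames(numeric(29), species_names())
  s["E2Ftot"] <- params[["V_SE2F"]] / params[["kd_E2F"]]
  s["Let7"] <- params[["V_SLET7"]] / max(params[["kd_LET7"]], 1e-8)
  s["MPTEN"] <- params[["V_SMPTEN"]] / params[["kd_MPTEN"]]
  s["PTEN"] <- params[["kT_PTEN"]] * s[["MPTEN"]] / params[["kd_PTEN"]]
  s
}

#' Right-hand side of the coupled 29-variable ODE system
#'
#' Reference (pure R) implementation of the kinetic equations. Synthesis and
#' degradation are linear mass action; transcriptional activation by GF,
#' E2F and NF-kB is Michaelis-Menten; Let-7 binds each target mRNA
#' reversibly (second-order mass action) into a translationally inactive
#' complex whose first-order decay consumes both partners; activation /
#' inactivation of the E2F, APC, NF-kB and STAT3 pools uses
#' Michaelis-Menten (zero-order-switch) kinetics, with a Hill term of
#' coefficient `n_STAT3` on the STAT3 branch of NF-kB activation (the
#' source of the irreversible bistable transformation switch).
#'
#' A fast equivalent compiled version is used internally by
#' [integrate_model()]; this function is the readable reference and the two
#' are tested to agree.
#'
#' @param state Named (or canonically ordered) numeric state vector, length 29.
#' @param t Time (h); the system is autonomous, `t` is ignored.
#' @param params Named parameter vector (see [default_parameters()]).
#' @return Named numeric vector of derivatives (a.u./h).
#' @export
grn_rhs <- function(state, t = 0, params = default_parameters()) {
  if (length(state) != 29L)
    stop("state must have 29 components, got ", length(state), call. = FALSE)
  if (!all(is.finite(state))) {
    nm <- species_names()[!is.finite(state)]
    stop("non-finite state component(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  x <- stats::setNames(as.numeric(state), species_names())
  p <- as.list(params)
  with(c(as.list(x), p), {
    ## -- saturating activation inputs --
    s_GF  <- GF / (K_AGF + GF)
    s_E2F <- E2F / (K_AE2F + E2F)

    ## -- Let-7 / mRNA binding fluxes (sponge) --
    bind_d  <- kA_MD * Let7 * Md;     unb_d  <- kD_MD * CLd
    bind_e  <- kA_ME * Let7 * Me;     unb_e  <- kD_ME * CLe
    bind_a  <- kA_MA * Let7 * Ma;     unb_a  <- kD_MA * CLa
    bind_b  <- kA_MB * Let7 * Mb;     unb_b  <- kD_MB * CLb
    bind_i6 <- kA_MIL6 * Let7 * MIL6; unb_i6 <- kD_MIL6 * CL_IL6
    bind_rs <- kA_MRAS * Let7 * MRas; unb_rs <- kD_MRAS * CL_Ras

    ## -- cyclin mRNAs --
    dMd <- V_SMCYC * V_SMD * (e_MD + s_GF) - kd_MD * Md - bind_d + unb_d
    dMe <- V_SMCYC * V_SME * (e_ME + s_E2F) - kd_ME * Me - bind_e + unb_e
    dMa <- V_SMCYC * V_SMA * (e_MA + s_E2F) - kd_MA * Ma - bind_a + unb_a
    dMb <- V_SMCYC * V_SMB - kd_MB * Mb - bind_b + unb_b

    ## -- Let-7 . cyclin mRNA complexes (decay consumes both partners) --
    dCLd <- bind_d - unb_d - kdCL_MD * CLd
    dCLe <- bind_e - unb_e - kdCL_ME * CLe
    dCLa <- bind_a - unb_a - kdCL_MA * CLa
    dCLb <- bind_b - unb_b - kdCL_MB * CLb

    ## -- cyclin/Cdk complexes (Cdk in excess: formed on translation) --
    dCd <- kT_CD * Md - kd_CD * Cd
    dCe <- kT_CE * Me - kd_CE * Ce
    dCa <- kT_CA * Ma - kd_CA * Ca - kdAPC_CA * APC * Ca
    dCb <- kT_CB * Mb * Ca / (K_ACB + Ca) - kd_CB * Cb - kdAPC_CB * APC * Cb

    ## -- E2F: total pool and Cd/Ce-activated, Ca-inactivated active form --
    e2f_in <- max(E2Ftot - E2F, 0)   # inactive pool
    dE2Ftot <- V_SE2F - kd_E2F * E2Ftot
    dE2F <- V_AE2F * ((Cd + Ce) / (K_AE2FC + Cd + Ce)) *
      e2f_in / (K_AE2FP + e2f_in) -
      (V_I0E2F + V_IE2F * Ca) * E2F / (K_IE2F + E2F) - kd_E2F * E2F

    ## -- APC (total = 1), activated by Cb --
    apc_in <- max(1 - APC, 0)
    dAPC <- V_AAPC * Cb * apc_in / (K_AAPC + apc_in) -
      V_IAPC * APC / (K_IAPC + APC)

    ## -- Let-7: synthesis, basal + Lin28-promoted decay, sponge binding --
    dLet7 <- V_SLET7 - (kd_LET7 + kdL7_LIN28 * Lin28) * Let7 -
      (bind_d + bind_e + bind_a + bind_b + bind_i6 + bind_rs) +
      (unb_d + unb_e + unb_a + unb_b + unb_i6 + unb_rs)

    ## -- NF-kB (total = 1): Src, STAT3 (Hill) and Ras branches; PTEN
    ##    promotes inactivation --
    s3h <- STAT3^n_STAT3 / (K_S3NFKB^n_STAT3 + STAT3^n_STAT3)
    nfkb_in <- max(1 - NFKB, 0)
    dNFKB <- (k_AA1NFKB * Src + k_AA2NFKB * s3h + k_AA3NFKB * Ras) *
      nfkb_in / (K_ANFKB + nfkb_in) -
      V_INFKB * (1 + k_PTENNFKB * PTEN) * NFKB / (K_INFKB + NFKB)

    ## -- Lin28 (NF-kB-driven) --
    nfkb_h <- NFKB^n_LIN28 / (K_ALIN28^n_LIN28 + NFKB^n_LIN28)
    dMLin28 <- V_SLIN28 * nfkb_h - kd_MLIN28 * MLin28
    dLin28 <- kT_LIN28 * MLin28 - kd_LIN28 * Lin28

    ## -- IL6 (mRNA is a Let-7 target) --
    dMIL6 <- V_S0MIL6 + V_SMIL6 * NFKB / (K_AMIL6 + NFKB) -
      kd_MIL6 * MIL6 - bind_i6 + unb_i6
    dCL_IL6 <- bind_i6 - unb_i6 - kdCL_MIL6 * CL_IL6
    dIL6 <- kT_IL6 * MIL6 - kd_IL6 * IL6

    ## -- STAT3 (total = 1), activated by IL6 and NF-kB --
    s3_in <- max(1 - STAT3, 0)
    dSTAT3 <- (V_A1STAT3 * IL6 + V_A2STAT3 * NFKB) * s3_in / (K_ASTAT3 + s3_in) -
      V_ISTAT3 * STAT3 / (K_ISTAT3 + STAT3)

    ## -- miR-21 (STAT3-driven) --
    dmiR21 <- V_SMIR21 * STAT3 / (K_AMIR21 + STAT3) - kd_MIR21 * miR21

    ## -- PTEN (miR-21 blocks translation) --
    dMPTEN <- V_SMPTEN - kd_MPTEN * MPTEN
    dPTEN <- kT_PTEN * MPTEN * K_MIR21PTEN / (K_MIR21PTEN + miR21) -
      kd_PTEN * PTEN

    ## -- Ras (mRNA is a Let-7 target; optional GF-mediated activation) --
    dMRas <- V_SMRAS - kd_MRAS * MRas - bind_rs + unb_rs
    dCL_Ras <- bind_rs - unb_rs - kdCL_MRAS * CL_Ras
    dRas <- (kT_RAS + k_GFRAS * GF) * MRas - kd_RAS * Ras

    stats::setNames(
      c(dMd, dMe, dMa, dMb, dCLd, dCLe, dCLa, dCLb,
        dCd, dCe, dCa, dCb, dE2F, dE2Ftot, dAPC,
        dLet7, dNFKB, dMLin28, dLin28, dMIL6, dCL_IL6, dIL6,
        dSTAT3, dmiR21, dMPTEN, dPTEN, dMRas, dCL_Ras, dRas),
      species_names())
  })
}

#' Regulatory edge list of the coupled network
#'
#' Enumerates every regulatory interaction realized by [grn_rhs()], one row
#' per (source, target) pair. `mechanism` is one of `transcription`,
#' `translation-block-by-complexation`, `translation`, `activation`,
#' `inactivation`, `degradation-promotion`.
#'
#' @return data.frame with columns source, target, sign, mechanism.
#' @export
network_topology <- function() {
  e <- rbind(
    c("GF",    "Md",    "+", "transcription"),
    c("E2F",   "Me",    "+", "transcription"),
    c("E2F",   "Ma",    "+", "transcription"),
    c("Let7",  "Md",    "-", "translation-block-by-complexation"),
    c("Let7",  "Me",    "-", "translation-block-by-complexation"),
    c("Let7",  "Ma",    "-", "translation-block-by-complexation"),
    c("Let7",  "Mb",    "-", "translation-block-by-complexation"),
    c("Let7",  "MIL6",  "-", "translation-block-by-complexation"),
    c("Let7",  "MRas",  "-", "translation-block-by-complexation"),
    c("Md",    "Cd",    "+", "translation"),
    c("Me",    "Ce",    "+", "translation"),
    c("Ma",    "Ca",    "+", "translation"),
    c("Mb",    "Cb",    "+", "translation"),
    c("Ca",    "Cb",    "+", "activation"),
    c("Cd",    "E2F",   "+", "activation"),
    c("Ce",    "E2F",   "+", "activation"),
    c("Ca",    "E2F",   "-", "inactivation"),
    c("Cb",    "APC",   "+", "activation"),
    c("APC",   "Ca",    "-", "degradation-promotion"),
    c("APC",   "Cb",    "-", "degradation-promotion"),
    c("Src",   "NFKB",  "+", "activation"),
    c("STAT3", "NFKB",  "+", "activation"),
    c("Ras",   "NFKB",  "+", "activation"),
    c("PTEN",  "NFKB",  "-", "inactivation"),
    c("NFKB",  "MLin28", "+", "transcription"),
    c("NFKB",  "MIL6",  "+", "transcription"),
    c("MLin28", "Lin28", "+", "translation"),
    c("Lin28", "Let7",  "-", "degradation-promotion"),
    c("MIL6",  "IL6",   "+", "translation"),
    c("IL6",   "STAT3", "+", "activation"),
    c("NFKB",  "STAT3", "+", "activation"),
    c("STAT3", "miR21", "+", "transcription"),
    c("miR21", "PTEN",  "-", "translation-block-by-complexation"),
    c("MPTEN", "PTEN",  "+", "translation"),
    c("MRas",  "Ras",   "+", "translation"),
    c("GF",    "Ras",   "+", "activation")
  )
  out <- data.frame(source = e[, 1], target = e[, 2], sign = e[, 3],
                    mechanism = e[, 4], stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("source", "target")]))
    stop("duplicate (source, target) edge")  # internal consistency guard
  out
}

#' Write / read a state vector as CSV with canonical species names
#'
#' @param state Named numeric state vector of length 29.
#' @param path File path.
#' @return `write_state`: invisibly, `path`; `read_state`: the state vector.
#' @export
write_state <- function(state, path) {
  stopifnot(length(state) == 29L)
  df <- as.data.frame(as.list(stats::setNames(as.numeric(state),
                                              species_names())))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!setequal(names(df), species_names()) || nrow(df) != 1L)
    stop("not a canonical single-row state CSV: ", path, call. = FALSE)
  unlist(df[1, species_names()])
}
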