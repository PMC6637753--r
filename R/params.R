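#' Canonical model parameter set
#'
#' Returns the basal parameter set of the coupled Let-7 / cell-cycle /
#' transformation model as a named numeric vector in canonical order.
#' Time is in hours, concentrations in arbitrary units (a.u.); first-order
#' rate constants are in 1/h, synthesis rates in a.u./h, and bimolecular
#' Let-7 binding constants in 1/(a.u. h).
#'
#' The set is calibrated so that, from the non-transformed quiescent state,
#' a transient Src pulse or sufficient cyclin-mRNA overexpression flips the
#' bistable transformation switch, while the quiescent state itself is
#' stable under basal inputs (see the methods vignette for the calibration
#' rationale).
#'
#' Key entries:
#' \describe{
#'   \item{GF}{growth-factor input (a.u.); promotes cyclin D mRNA synthesis.}
#'   \item{Src}{inflammatory input (a.u.); activates NF-kB at rate
#'     \code{k_AA1NFKB * Src}.}
#'   \item{V_SMCYC}{common scaling factor on the synthesis rates of the four
#'     cyclin mRNAs.}
#'   \item{V_SLET7}{basal Let-7 synthesis rate (a.u./h).}
#'   \item{V_SLIN28, V_SMPTEN, V_SMRAS}{Lin28, PTEN mRNA and Ras mRNA
#'     synthesis rates.}
#'   \item{k_AA1NFKB, k_AA2NFKB, k_AA3NFKB}{NF-kB activation rate constants
#'     for the Src, IL6/STAT3 and Ras branches respectively (the
#'     branch-to-constant assignment is a labeled model assumption).}
#'   \item{k_GFRAS}{GF-mediated Ras activation constant; 0 by default (the
#'     GF-to-Ras coupling variant is off).}
#' }
#'
#' @return Named numeric vector of all kinetic constants and inputs.
#' @export
#' @examples
#' p <- default_parameters()
#' p[["V_SLET7"]]
default_parameters <- function() {
  c(
    ## --- inputs and global scalings ---
    GF       = 1,        # growth factor level (a.u.)
    Src      = 1e-7,     # inflammatory input (a.u.)
    V_SMCYC  = 1.5,      # common cyclin mRNA synthesis scaling

    ## --- cyclin mRNA synthesis / decay ---
    V_SMD    = 1,        # cyclin D mRNA max synthesis (x V_SMCYC)
    e_MD     = 0.01,     # GF-independent basal fraction of cyclin D synthesis
    K_AGF    = 2,        # Michaelis constant for GF activation of Md
    kd_MD    = 0.3,
    V_SME    = 4.8,      # cyclin E mRNA synthesis (E2F-driven)
    e_ME     = 0.001,
    V_SMA    = 4.8,      # cyclin A mRNA synthesis (E2F-driven)
    e_MA     = 0.001,
    K_AE2F   = 1,        # Michaelis constant for E2F-driven transcription
    kd_ME    = 0.3,
    kd_MA    = 0.3,
    V_SMB    = 0.015,     # cyclin B mRNA synthesis (constitutive)
    kd_MB    = 0.3,

    ## --- Let-7 binding to cyclin mRNAs (sponge) ---
    kA_MD    = 0.29, kA_ME = 3, kA_MA = 3, kA_MB = 3,
    kD_MD    = 0.01, kD_ME = 0.01, kD_MA = 0.01, kD_MB = 0.01,
    kdCL_MD  = 0.3,  kdCL_ME = 0.3, kdCL_MA = 0.3, kdCL_MB = 0.3,

    ## --- cyclin/Cdk complexes ---
    kT_CD    = 0.25,     # translation of Md into cyclin D/Cdk4-6
    kT_CE    = 0.45,
    kT_CA    = 0.026,
    kT_CB    = 7.7,
    kd_CD    = 0.25,
    kd_CE    = 0.6,
    kd_CA    = 0.2,
    kd_CB    = 0.4,
    K_ACB    = 1.33,     # cyclin A requirement for cyclin B/Cdk1 activation
    kdAPC_CA = 1.23,     # APC-mediated degradation of Ca
    kdAPC_CB = 6.9,      # APC-mediated degradation of Cb

    ## --- E2F module (active + total pools) ---
    V_SE2F   = 0.1,
    kd_E2F   = 0.07,
    V_AE2F   = 440,      # max E2F activation rate (slope V_AE2F/K_AE2FC at low Cd+Ce)
    K_AE2FC  = 50,       # saturation of E2F activation in (Cd + Ce)
    K_AE2FP  = 0.025,
    V_I0E2F  = 0.13,     # basal (Ca-independent) E2F inactivation: ignition threshold
    V_IE2F   = 80,       # inactivation of E2F by Ca
    K_IE2F   = 0.001,

    ## --- APC module (total = 1) ---
    V_AAPC   = 0.3,
    K_AAPC   = 0.046,
    V_IAPC   = 1.76,
    K_IAPC   = 0.013,

    ## --- Let-7 ---
    V_SLET7    = 10,
    kd_LET7    = 0.05,
    kdL7_LIN28 = 40,     # Lin28-promoted Let-7 degradation

    ## --- NF-kB (total = 1) ---
    k_AA1NFKB = 5,       # activation by Src
    k_AA2NFKB = 1.2,     # activation by the IL6/STAT3 branch (Hill)
    k_AA3NFKB = 5,       # activation by Ras
    n_STAT3   = 6,       # Hill coefficient of STAT3 branch (bistability)
    K_S3NFKB  = 0.06,
    K_ANFKB   = 0.05,
    V_INFKB   = 0.35,
    k_PTENNFKB = 2,      # PTEN-promoted NF-kB inactivation
    K_INFKB   = 0.05,

    ## --- Lin28 ---
    V_SLIN28  = 0.1,
    K_ALIN28  = 0.3,
    n_LIN28   = 2,       # Hill coefficient of NF-kB-driven Lin28 synthesis
    kd_MLIN28 = 0.3,
    kT_LIN28  = 0.9,
    kd_LIN28  = 0.3,

    ## --- IL6 (mRNA is a Let-7 target) ---
    V_S0MIL6 = 0.04,     # leak IL6 mRNA synthesis
    V_SMIL6  = 0.6,      # NF-kB-driven IL6 mRNA synthesis
    K_AMIL6  = 0.3,
    kd_MIL6  = 0.3,
    kA_MIL6  = 20,
    kD_MIL6  = 0.01,
    kdCL_MIL6 = 0.3,
    kT_IL6   = 0.3,
    kd_IL6   = 0.3,

    ## --- STAT3 (total = 1) ---
    V_A1STAT3 = 4,       # activation by IL6
    V_A2STAT3 = 0.02,     # activation by NF-kB
    K_ASTAT3  = 0.1,
    V_ISTAT3  = 0.4,
    K_ISTAT3  = 0.1,

    ## --- miR-21 ---
    V_SMIR21 = 1,
    K_AMIR21 = 0.3,
    kd_MIR21 = 0.5,

    ## --- PTEN (translation blocked by miR-21) ---
    V_SMPTEN   = 0.001,
    kd_MPTEN   = 0.1,
    kT_PTEN    = 10,
    K_MIR21PTEN = 0.05,
    kd_PTEN    = 0.1,

    ## --- Ras (mRNA is a Let-7 target) ---
    V_SMRAS  = 0.04,
    kd_MRAS  = 0.15,
    kA_MRAS  = 3,
    kD_MRAS  = 0.01,
    kdCL_MRAS = 0.3,
    kT_RAS   = 1.2,
    kd_RAS   = 0.2,
    k_GFRAS  = 0         # GF-mediated Ras activation (variant; off by default)
  )
}

#' Validate a model parameter vector
#'
#' @param params Named numeric vector.
#' @return Invisibly, `params` (checked).
#' @keywords internal
validate_parameters <- function(params) {
  ref <- names(default_parameters())
  if (is.null(names(params)) || !setequal(names(params), ref)) {
    missing <- setdiff(ref, names(params))
    extra <- setdiff(names(params), ref)
    stop("invalid parameter set; missing: [",
         paste(missing, collapse = ", "), "]; unknown: [",
         paste(extra, collapse = ", "), "]", call. = FALSE)
  }
  if (!all(is.finite(params))) {
    stop("non-finite parameter value(s): ",
         paste(names(params)[!is.finite(params)], collapse = ", "),
         call. = FALSE)
  }
  if (any(params < 0)) {
    stop("negative parameter value(s): ",
         paste(names(params)[params < 0], collapse = ", "), call. = FALSE)
  }
  invisible(params[ref])
}

#' Apply named overrides to a parameter set
#'
#' Returns a new parameter vector equal to `params` except for the entries
#' named in `overrides`. Unknown names are a configuration error.
#'
#' @param params Named numeric parameter vector (see [default_parameters()]).
#' @param overrides Named numeric vector or list of `name = value` pairs.
#' @return The modified parameter vector.
#' @export
#' @examples
#' p <- apply_overrides(default_parameters(), c(V_SLET7 = 0.5))
apply_overrides <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  overrides <- unlist(overrides)
  bad <- setdiff(names(overrides), names(params))
  if (length(bad) > 0 || is.null(names(overrides)) ||
      any(!nzchar(names(overrides)))) {
    stop("unknown parameter name(s) in overrides: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  params[names(overrides)] <- as.numeric(overrides)
  params
}

#' Read a parameter set from a flat key-value config file
#'
#' One `name = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Unknown keys are rejected; keys not present in the file keep
#' their default value.
#'
#' @param path Path to the config file.
#' @param base Parameter set used for defaults (default: [default_parameters()]).
#' @return Named numeric parameter vector.
#' @export
read_parameters <- function(path, base = default_parameters()) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(base)
  parts <- regmatches(lines, regexec("^([A-Za-z0-9_]+)[[:space:]]*=[[:space:]]*(.+)$", lines))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed parameter line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- vapply(parts, `[`, "", 2L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L)))
  if (anyNA(vals)) {
    stop("non-numeric value for parameter(s): ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("duplicated parameter key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  validate_parameters(apply_overrides(base, stats::setNames(vals, keys)))
}

#' Write a parameter set to a flat key-value config file
#'
#' Keys are emitted in canonical order, one `name = value` per line, with
#' full double precision so that read/write round-trips are lossless.
#'
#' @param params Named numeric parameter vector.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_parameters <- function(params, path) {
  params <- validate_parameters(params)
  lines <- sprintf("%s = %s", names(params),
                   formatC(params, format = "g", digits = 17))
  writeLines(lines, path)
  invisible(path)
}
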