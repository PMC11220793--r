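# Physical constants and unit conversions. All internal computation is SI;
# angstrom / mJ m^-2 units appear only at interface boundaries, and every
# conversion goes through these helpers so the factors live in one place.

#' Physical constants used throughout the package
#'
#' `k_boltzmann` is the SI-exact Boltzmann constant (J K^-1). `r_gas` is the
#' molar gas constant rounded to 8.314 J mol^-1 K^-1, the value that
#' reproduces published driving-force tables to their printed 0.01 J mol^-1.
#'
#' @format A named list with elements `k_boltzmann` and `r_gas`.
#' @export
nk_constants <- list(
  k_boltzmann = 1.380649e-23, # J K^-1
  r_gas       = 8.314         # J mol^-1 K^-1
)

# interface-unit helpers ------------------------------------------------

A_to_m   <- function(x) x * 1e-10   # angstrom -> metre
m_to_A   <- function(x) x * 1e10
A3_to_m3 <- function(x) x * 1e-30   # cubic angstrom -> cubic metre
m3_to_A3 <- function(x) x * 1e30
mJm2_to_Jm2 <- function(x) x * 1e-3 # mJ m^-2 -> J m^-2
Jm2_to_mJm2 <- function(x) x * 1e3

stop_domain <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
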