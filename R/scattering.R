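## Atomic scattering factors: 4-Gaussian-plus-constant parameterization of
## f0(sin(theta)/lambda) for the elements needed in a sulfur-SAD protein
## setting (H, C, N, O, S).  Anomalous corrections f' and f'' are user
## inputs (no dispersion calculation from photon energy).

.f0Coefs <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900))

.f0 <- function(element, stol) {
  cf <- .f0Coefs[[toupper(element)]]
  if (is.null(cf))
    stop("no scattering coefficients bundled for element '", element,
         "' (available: ", paste(names(.f0Coefs), collapse = ", "), ")")
  s2 <- stol^2
  out <- rep(cf$c, length(stol))
  for (i in 1:4) out <- out + cf$a[i] * exp(-cf$b[i] * s2)
  out
}

#' Complex atomic scattering factor
#'
#' f(stol) = f0(stol) + f' + i f'' with f0 from the bundled
#' Gaussian-sum parameterization.  `stol` is sin(theta)/lambda = 1/(2d)
#' in 1/Angstrom.
#'
#' @param element element symbol (one of H, C, N, O, S)
#' @param stol sin(theta)/lambda in 1/Angstrom (vectorized, >= 0)
#' @param fPrime real anomalous correction f' in electrons
#' @param fDoublePrime imaginary anomalous correction f'' in electrons
#' @return complex vector
#' @examples
#' atomicF("S", 0)                 # ~16 electrons at zero angle
#' atomicF("S", 0.2, 0, 1.51)      # sulfur with its 4.57 keV f''
#' @export
atomicF <- function(element, stol, fPrime = 0, fDoublePrime = 0) {
  stopifnot(all(stol >= 0))
  complex(real = .f0(element, stol) + fPrime,
          imaginary = rep(fDoublePrime, length(stol)))
}
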