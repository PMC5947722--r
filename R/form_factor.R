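# Atomic scattering factors: the standard four-Gaussian parameterization
# f(s) = sum_i a_i exp(-b_i (s/2)^2) + c with s = 1/d (so s/2 = sin(theta)/
# lambda). Coefficients are the published International Tables values for
# the neutral elements this package's toy crystals use.
cromer_mann <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  Ca = list(a = c(8.62660, 7.38730, 1.58990, 1.02110),
            b = c(10.4421, 0.659900, 85.7484, 178.437), c = 1.37510)
)

#' Atomic scattering factor
#'
#' Elastic X-ray form factor of a neutral atom as a function of the
#' scattering-vector modulus s = 1/d (Angstrom^-1, no 2*pi), using the
#' published four-Gaussian coefficients. `f(0)` equals the electron count to
#' coefficient rounding; `f` is monotone non-increasing in s for the light
#' elements supported.
#'
#' @param element Element symbol (case sensitive, e.g. `"C"`, `"O"`).
#' @param s_mod Numeric vector of |s| values, Angstrom^-1, >= 0.
#' @return Numeric vector of form-factor values (electrons).
#' @examples
#' form_factor("C", 0) # ~ 6
#' @export
form_factor <- function(element, s_mod) {
  cf <- cromer_mann[[element]]
  if (is.null(cf)) {
    stop(sprintf("unknown element '%s'; supported: %s", element,
                 paste(names(cromer_mann), collapse = ", ")), call. = FALSE)
  }
  if (any(s_mod < 0)) stop("s_mod must be >= 0", call. = FALSE)
  q2 <- (s_mod / 2)^2
  out <- rep(cf$c, length(s_mod))
  for (i in seq_along(cf$a)) out <- out + cf$a[i] * exp(-cf$b[i] * q2)
  out
}
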