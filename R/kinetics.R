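#' Protonation on-rate at a given pH
#'
#' Order-of-magnitude estimate treating the proton activity \eqn{10^{-pH}}
#' as a molar concentration: \eqn{k_{on} = k_0 \cdot 10^{-pH}} with the
#' diffusion-limited intrinsic protonation rate \eqn{k_0 = 10^{10}}
#' M^-1 s^-1 for small molecules.
#'
#' @param pH solution pH.
#' @param k0 intrinsic protonation rate (M^-1 s^-1), default 1e10.
#' @return rate in s^-1.
#' @export
on_rate <- function(pH, k0 = 1e10) {
  stopifnot(is.finite(pH))
  k0 * 10^(-pH)
}

#' Deprotonation off-rate from a pKa
#'
#' \eqn{k_{off} = k_0 \cdot 10^{-pK_a}}; combined with \code{\link{on_rate}}
#' this reproduces the Henderson-Hasselbalch ratio
#' \eqn{k_{off}/k_{on} = 10^{pH - pK_a}}.
#'
#' @param pka acid-dissociation exponent of the relevant titration.
#' @param k0 intrinsic protonation rate (M^-1 s^-1), default 1e10.
#' @return rate in s^-1.
#' @export
off_rate <- function(pka, k0 = 1e10) {
  stopifnot(is.finite(pka))
  k0 * 10^(-pka)
}

#' Intrinsic permeation rate of a liposome from apparent permeability
#'
#' In a liposomal fluorescence assay the rate of signal change \eqn{k}
#' relates to the apparent permeability through \eqn{P_{app} = k d / 6},
#' where \eqn{d} is the mean hydrodynamic liposome diameter.
#'
#' @param p_app apparent permeability in cm/s (> 0).
#' @param diameter liposome diameter in nm (> 0), default 167.7.
#' @return rate in s^-1.
#' @export
intrinsic_rate <- function(p_app, diameter = 167.7) {
  if (!is.finite(p_app) || p_app <= 0) stop("p_app must be positive")
  if (!is.finite(diameter) || diameter <= 0) stop("diameter must be positive")
  6 * p_app / (diameter * 1e-7)   # nm -> cm
}

#' Apparent permeability from an intrinsic rate
#'
#' Exact inverse of \code{\link{intrinsic_rate}}: \eqn{P_{app} = k d / 6}.
#'
#' @param k intrinsic rate in s^-1 (> 0).
#' @param diameter liposome diameter in nm (> 0), default 167.7.
#' @return apparent permeability in cm/s.
#' @export
papp_from_rate <- function(k, diameter = 167.7) {
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  if (!is.finite(diameter) || diameter <= 0) stop("diameter must be positive")
  k * diameter * 1e-7 / 6
}

#' Classify the rate-limiting step of a liposomal permeability assay
#'
#' A fluorescence-based permeability readout reflects permeation only if the
#' permeant's protonation and deprotonation are both much faster than the
#' permeation rate inferred from the assay.  The margins
#' \eqn{k_{on}/k_{perm}} and \eqn{k_{off}/k_{perm}} are compared with a
#' threshold (default 10x): permeation-limited when both exceed it,
#' protonation-limited when either falls below its inverse, ambiguous
#' otherwise.
#'
#' @param pH assay pH.
#' @param pka pKa of the titration coupled to the readout.
#' @param p_app measured apparent permeability (cm/s).
#' @param diameter liposome diameter (nm).
#' @param k0 intrinsic protonation rate (M^-1 s^-1).
#' @param threshold margin defining "much faster" (default 10).
#' @return object of class \code{"rate_report"}: \code{k_on}, \code{k_off},
#'   \code{k_perm} (s^-1), \code{p_app}, \code{diameter}, \code{margins},
#'   \code{regime}.
#' @export
classify_regime <- function(pH, pka, p_app, diameter = 167.7, k0 = 1e10,
                            threshold = 10) {
  k_on <- on_rate(pH, k0)
  k_off <- off_rate(pka, k0)
  k_perm <- intrinsic_rate(p_app, diameter)
  margins <- c(on = k_on / k_perm, off = k_off / k_perm)
  regime <- if (min(margins) >= threshold) "permeation-limited"
            else if (min(margins) <= 1 / threshold) "protonation-limited"
            else "ambiguous"
  structure(list(k_on = k_on, k_off = k_off, k_perm = k_perm,
                 p_app = p_app, diameter = diameter,
                 margins = margins, threshold = threshold, regime = regime),
            class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf(paste0("<rate_report> k_on = %.3g, k_off = %.3g, ",
                     "k_perm = %.3g s^-1\n  margins on/off = %.3g / %.3g ",
                     "(threshold %g) -> %s\n"),
              x$k_on, x$k_off, x$k_perm, x$margins["on"], x$margins["off"],
              x$threshold, x$regime))
  invisible(x)
}
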