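#' Default tetracycline ionization constants
#'
#' Macroscopic pKas (3.33, 7.75, 9.61) and the microscopic pk estimates from
#' model-compound assignments: pk21 = 5.97 (tricarbonyl A acidity in the
#' neutral tautomer), pk12 = 8.8 (dimethylammonium B acidity in the
#' zwitterion), pk13 = 7.80 (phenolic diketone C acidity with B protonated,
#' from the tetracycline-methiodide analog), and pk31 = pk21 (the A group is
#' assumed equally acidic whether or not the distal C site is charged).
#'
#' @return list with \code{pka} (length 3) and \code{pk21}, \code{pk12},
#'   \code{pk13}, \code{pk31}.
#' @export
tc_constants <- function() {
  list(pka = c(3.33, 7.75, 9.61),
       pk21 = 5.97, pk12 = 8.8, pk13 = 7.80, pk31 = 5.97)
}

#' Tautomer ratios of the zero-charge tetracycline macrostate
#'
#' pH-independent population ratios of the three zero-net-charge tautomers
#' relative to the zwitterion TC_Z, from thermodynamic cycles:
#' \eqn{f_N/f_Z = 10^{pk_{21} - pk_{12}}} and
#' \eqn{f_{Z'}/f_Z = 10^{pk_{31} - pk_{13}}}.
#' With the default constants these are 10^-2.83 and 10^-1.83.
#'
#' @param const constants list as returned by \code{\link{tc_constants}}.
#' @return named vector \code{c(TC_Z = 1, TC_N = ..., TC_Zp = ...)}.
#' @export
tc_tautomer_ratios <- function(const = tc_constants()) {
  c(TC_Z = 1,
    TC_N = 10^(const$pk21 - const$pk12),
    TC_Zp = 10^(const$pk31 - const$pk13))
}

#' Full eight-microstate tetracycline ionization model
#'
#' Tetracycline has three titratable sites: the tricarbonyl (A, neutral when
#' protonated, -1 when deprotonated), the dimethylammonium (B, +1 when
#' protonated), and the phenolic diketone (C, neutral when protonated).  The
#' eight protonation patterns form four macrostates (+1, 0, -1, -2).  Only
#' four microscopic pks are available from model compounds; the remaining
#' edges are fixed by requiring (i) thermodynamic-cycle closure and (ii)
#' exact agreement of the macrostate weight sums with the three macroscopic
#' pKas.  The zero-charge tautomers are labelled \code{TC_N} (A0B0C0),
#' \code{TC_Z} (A-B+C0) and \code{TC_Zp} (A0B+C-); the other microstates are
#' labelled by their site pattern.
#'
#' @param const constants list as returned by \code{\link{tc_constants}};
#'   replace entries to build assignment variants.
#' @return an \code{\link{ionization_model}}.
#' @export
tc_microstate_model <- function(const = tc_constants()) {
  pka <- const$pka
  if (length(pka) != 3L) stop("three macroscopic pKas required")
  rN  <- 10^(const$pk21 - const$pk12)
  rZp <- 10^(const$pk31 - const$pk13)
  # log10 weight of A-B0C0 (protonate C from the reference A-B0C-) such that
  # the zero-charge macrostate sum matches 10^(pKa2 + pKa3)
  a <- pka[2] + pka[3] - const$pk12 - log10(1 + rN + rZp)
  b <- a + const$pk12 - const$pk13         # A-B+C- weight (cycle closure via TC_Z)
  wc <- 10^pka[3] - 10^a - 10^b            # A0B0C- weight fills the -1 macrostate
  if (wc <= 0)
    stop("infeasible microscopic pks: the -1 macrostate weight is exhausted")
  cc <- log10(wc)
  S <- sum(pka)                            # log10 weight of the +1 state
  micro <- data.frame(
    label = c("A-B0C-", "A-B0C0", "A-B+C-", "A0B0C-",
              "TC_N", "TC_Z", "TC_Zp", "A0B+C0"),
    net_charge = c(-2L, -1L, -1L, -1L, 0L, 0L, 0L, 1L),
    n_protons = c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L),
    stringsAsFactors = FALSE)
  gN <- a + const$pk21; gZ <- a + const$pk12; gZp <- b + const$pk31
  edges <- data.frame(
    donor = c("A-B0C0", "A-B+C-", "A0B0C-",
              "TC_N", "TC_Z", "TC_N", "TC_Zp", "TC_Z", "TC_Zp",
              "A0B+C0", "A0B+C0", "A0B+C0"),
    acceptor = c("A-B0C-", "A-B0C-", "A-B0C-",
                 "A-B0C0", "A-B0C0", "A0B0C-", "A0B0C-", "A-B+C-", "A-B+C-",
                 "TC_N", "TC_Z", "TC_Zp"),
    pk = c(a, b, cc,
           const$pk21, const$pk12, gN - cc, gZp - cc, const$pk13, const$pk31,
           S - gN, S - gZ, S - gZp),
    stringsAsFactors = FALSE)
  ionization_model(micro, edges, reference = "A-B0C-")
}

#' Tetracycline populations at a given pH
#'
#' Convenience wrapper: macrostate fractions from the macroscopic pKas with
#' the zero-charge macrostate split into TC_Z, TC_N and TC_Zp by the
#' thermodynamic-cycle ratios.  Identical (to numerical precision) to
#' \code{microstate_fractions(tc_microstate_model(), tc)} restricted to those
#' labels.
#'
#' @param tc a \code{\link{thermo}} object carrying the pH.
#' @param const constants list as returned by \code{\link{tc_constants}}.
#' @return a \code{\link{populations}} object.
#' @export
tc_populations <- function(tc = thermo(pH = 6), const = tc_constants()) {
  mac <- macrostate_fractions(const$pka, tc, fully_protonated_charge = 1L)
  split_macrostate_by_ratios(mac, "0", tc_tautomer_ratios(const))
}

#' Microscopic-pk assignment variants
#'
#' Builds full microstate models under alternative assignments of the
#' macroscopic pKas to microscopic pks, for sensitivity analysis of the
#' effective permeability:
#' \describe{
#'   \item{leeson}{the default model-compound estimates
#'     (pk12 = 8.8, pk13 = 7.80).}
#'   \item{stephens-like-swap}{swaps the B/C site assignment
#'     (pk12 = 7.80, pk13 = 8.8).}
#'   \item{naive-forward}{equates microscopic with macroscopic values:
#'     pk12 = pKa2, pk13 = pKa3.}
#'   \item{naive-reverse}{the opposite naive order: pk12 = pKa3,
#'     pk13 = pKa2.}
#' }
#' pk21 (and pk31 = pk21) are kept at the model-compound estimate in all
#' variants.
#'
#' @param pkas macroscopic pKas (default tetracycline's).
#' @param scheme character vector of variant names (any subset of the above).
#' @param const base constants providing pk21/pk12/pk13/pk31.
#' @return named list of \code{\link{ionization_model}} objects.
#' @export
assignment_variants <- function(pkas = tc_constants()$pka,
                                scheme = c("leeson", "stephens-like-swap",
                                           "naive-forward", "naive-reverse"),
                                const = tc_constants()) {
  scheme <- match.arg(scheme, several.ok = TRUE)
  const$pka <- pkas
  build <- function(s) {
    v <- const
    if (s == "stephens-like-swap") {
      v$pk12 <- const$pk13; v$pk13 <- const$pk12
    } else if (s == "naive-forward") {
      v$pk12 <- pkas[2]; v$pk13 <- pkas[3]
    } else if (s == "naive-reverse") {
      v$pk12 <- pkas[3]; v$pk13 <- pkas[2]
    }
    tc_microstate_model(v)
  }
  stats::setNames(lapply(scheme, build), scheme)
}
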