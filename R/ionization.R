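#' Ionization model of a multi-protic permeant
#'
#' Represents the full microstate scheme of a molecule with several titratable
#' sites: labelled microstates (protonation patterns) carrying net charges and
#' proton counts, connected by directed protonation edges that carry
#' microscopic acid-dissociation exponents (microscopic pKa values, written
#' pk).  Each edge points from the protonated form (donor, one more proton) to
#' the deprotonated form (acceptor); its pk is the donor's dissociation
#' exponent for that site.  The reference state is the fully deprotonated
#' microstate, from which every state must be reachable.
#'
#' @param microstates data.frame with columns \code{label}, \code{net_charge}
#'   (integer) and \code{n_protons} (integer count of bound titratable
#'   protons).
#' @param edges data.frame with columns \code{donor}, \code{acceptor} and
#'   \code{pk}; for every edge \code{n_protons[donor] == n_protons[acceptor] + 1}.
#' @param reference label of the fully deprotonated microstate; defaults to
#'   the unique state with the fewest protons.
#' @return object of class \code{"ionization_model"}.
#' @export
ionization_model <- function(microstates, edges, reference = NULL) {
  microstates <- as.data.frame(microstates, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "net_charge", "n_protons") %in% names(microstates)),
            all(c("donor", "acceptor", "pk") %in% names(edges)))
  if (anyDuplicated(microstates$label))
    stop("microstate labels must be unique")
  np <- stats::setNames(microstates$n_protons, microstates$label)
  bad <- !(edges$donor %in% microstates$label) |
         !(edges$acceptor %in% microstates$label)
  if (any(bad)) stop("edge references unknown microstate label")
  if (any(np[edges$donor] != np[edges$acceptor] + 1L))
    stop("every edge must remove exactly one proton (donor -> acceptor)")
  if (is.null(reference)) {
    i <- which(microstates$n_protons == min(microstates$n_protons))
    if (length(i) != 1L)
      stop("reference ambiguous: supply the fully deprotonated label")
    reference <- microstates$label[i]
  }
  if (!reference %in% microstates$label) stop("unknown reference label")
  m <- structure(list(microstates = microstates, edges = edges,
                      reference = reference),
                 class = "ionization_model")
  g <- .state_log_weights(m)      # also checks connectivity
  attr(m, "gamma") <- g
  m
}

#' @export
print.ionization_model <- function(x, ...) {
  cat(sprintf("<ionization_model> %d microstates, %d protonation edges, reference '%s'\n",
              nrow(x$microstates), nrow(x$edges), x$reference))
  invisible(x)
}

# log10 statistical weight of every microstate relative to the reference at
# pH = 0, obtained by BFS over protonation edges (+pk towards the donor).
# Path independence holds when all thermodynamic cycles close.
.state_log_weights <- function(model) {
  labs <- model$microstates$label
  gamma <- stats::setNames(rep(NA_real_, length(labs)), labs)
  gamma[model$reference] <- 0
  queue <- model$reference
  e <- model$edges
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    up <- e[e$acceptor == cur, , drop = FALSE]      # protonation: cur -> donor
    for (i in seq_len(nrow(up))) {
      nb <- up$donor[i]
      if (is.na(gamma[nb])) { gamma[nb] <- gamma[cur] + up$pk[i]; queue <- c(queue, nb) }
    }
    dn <- e[e$donor == cur, , drop = FALSE]         # deprotonation: cur -> acceptor
    for (i in seq_len(nrow(dn))) {
      nb <- dn$acceptor[i]
      if (is.na(gamma[nb])) { gamma[nb] <- gamma[cur] - dn$pk[i]; queue <- c(queue, nb) }
    }
  }
  if (anyNA(gamma))
    stop("microstate(s) unreachable from the reference: ",
         paste(names(gamma)[is.na(gamma)], collapse = ", "))
  gamma
}

#' Equilibrium population container
#'
#' @param by_macrostate named numeric vector of macrostate fractions (names
#'   are net charges, e.g. \code{"+1"}, \code{"0"}, \code{"-1"}).
#' @param by_microstate named numeric vector of microstate fractions, or NULL.
#' @param macrostate_of named character vector mapping microstate label to
#'   its macrostate name, or NULL.
#' @param pH the pH at which the fractions hold.
#' @return object of class \code{"populations"}.
#' @export
populations <- function(by_macrostate, by_microstate = NULL,
                        macrostate_of = NULL, pH = NA_real_) {
  chk <- function(v, what) {
    if (any(v < -1e-12 | v > 1 + 1e-12))
      stop(what, " fractions must lie in [0, 1]")
  }
  chk(by_macrostate, "macrostate")
  if (abs(sum(by_macrostate) - 1) > 1e-12)
    stop("macrostate fractions must sum to 1")
  if (!is.null(by_microstate)) chk(by_microstate, "microstate")
  structure(list(by_macrostate = by_macrostate, by_microstate = by_microstate,
                 macrostate_of = macrostate_of, pH = pH),
            class = "populations")
}

#' @export
print.populations <- function(x, ...) {
  cat(sprintf("<populations> pH = %g\n  macrostates: %s\n", x$pH,
              paste(sprintf("%s: %.3g", names(x$by_macrostate), x$by_macrostate),
                    collapse = ", ")))
  if (!is.null(x$by_microstate))
    cat("  microstates:", paste(sprintf("%s: %.3g", names(x$by_microstate),
                                        x$by_microstate), collapse = ", "), "\n")
  invisible(x)
}

#' Look up the fraction of a label
#'
#' Searches microstate fractions first, then macrostates.
#'
#' @param pops a \code{\link{populations}} object.
#' @param label microstate or macrostate name.
#' @return numeric fraction.
#' @export
state_fraction <- function(pops, label) {
  if (!is.null(pops$by_microstate) && label %in% names(pops$by_microstate))
    return(unname(pops$by_microstate[label]))
  if (label %in% names(pops$by_macrostate))
    return(unname(pops$by_macrostate[label]))
  stop("no fraction known for label '", label, "'")
}

.macro_name <- function(q) ifelse(q > 0, paste0("+", q), as.character(q))

#' Macrostate fractions from macroscopic pKas
#'
#' Sequential Henderson-Hasselbalch: for N macroscopic pKas (ordered from the
#' first to the last titration) the unnormalized weight of the state
#' retaining j protons, relative to the fully deprotonated state, is
#' \eqn{10^{\sum_{i > N - j} pK_{a,i} - j\,\mathrm{pH}}}.  Net charges run
#' from \code{fully_protonated_charge} downwards, one unit per proton lost.
#'
#' @param pkas numeric vector of macroscopic pKa values in titration order.
#' @param tc a \code{\link{thermo}} object carrying the pH.
#' @param fully_protonated_charge net charge of the fully protonated
#'   macrostate (default +1, the tetracycline-like case).
#' @return a \code{\link{populations}} object (macrostates only).
#' @export
macrostate_fractions <- function(pkas, tc = thermo(),
                                 fully_protonated_charge = 1L) {
  if (length(pkas) < 1L) stop("at least one macroscopic pKa required")
  if (!all(is.finite(pkas))) stop("pKa values must be finite")
  n <- length(pkas)
  j <- 0:n                                   # protons retained
  lw <- c(0, cumsum(rev(pkas))) - j * tc$pH  # log10 weights vs fully deprotonated
  w <- 10^(lw - max(lw))
  f <- w / sum(w)
  charges <- fully_protonated_charge - (n - j)
  populations(by_macrostate = stats::setNames(rev(f), .macro_name(rev(charges))),
              pH = tc$pH)
}

#' Unnormalized statistical weight of a microstate
#'
#' The weight relative to the fully deprotonated reference is
#' \eqn{10^{\gamma - n_H\,\mathrm{pH}}}, where \eqn{\gamma} is the sum of
#' microscopic pk values along any protonation path from the reference and
#' \eqn{n_H} the number of bound protons.  Path independence is guaranteed
#' when all thermodynamic cycles close (see \code{\link{validate_cycles}}).
#'
#' @param model an \code{\link{ionization_model}}.
#' @param label microstate label.
#' @param tc a \code{\link{thermo}} object carrying the pH.
#' @return unnormalized weight (reference state has weight 1 at pH 0... at
#'   any pH, since it binds no protons).
#' @export
microstate_weight <- function(model, label, tc = thermo()) {
  gamma <- attr(model, "gamma")
  if (!label %in% names(gamma)) stop("unknown microstate '", label, "'")
  np <- model$microstates$n_protons[match(label, model$microstates$label)]
  unname(10^(gamma[label] - np * tc$pH))
}

#' Microstate and macrostate fractions from an ionization model
#'
#' Normalizes the microstate weights at the given pH and aggregates them by
#' net charge into macrostate fractions.
#'
#' @param model an \code{\link{ionization_model}}.
#' @param tc a \code{\link{thermo}} object carrying the pH.
#' @return a \code{\link{populations}} object with both levels filled.
#' @export
microstate_fractions <- function(model, tc = thermo()) {
  gamma <- attr(model, "gamma")
  np <- stats::setNames(model$microstates$n_protons, model$microstates$label)
  lw <- gamma - np[names(gamma)] * tc$pH
  w <- 10^(lw - max(lw))
  f <- w / sum(w)
  mac <- .macro_name(model$microstates$net_charge[
    match(names(f), model$microstates$label)])
  by_mac <- tapply(f, mac, sum)
  by_mac <- stats::setNames(as.numeric(by_mac), names(by_mac))
  populations(by_macrostate = by_mac, by_microstate = f,
              macrostate_of = stats::setNames(mac, names(f)), pH = tc$pH)
}

#' Split a macrostate fraction among tautomers by fixed ratios
#'
#' Tautomers (microstates sharing a net charge) keep pH-independent
#' population ratios; given the macrostate fraction and the ratios of each
#' tautomer to an anchor (ratio 1), the individual fractions are
#' \eqn{f_{\mathrm{label}} = f_{\mathrm{macro}} \cdot r_{\mathrm{label}} / \sum_t r_t}.
#'
#' @param pops a \code{\link{populations}} object.
#' @param macrostate name of the macrostate to split (e.g. \code{"0"}).
#' @param ratios named positive numeric vector of ratios-to-anchor; must
#'   contain the anchor itself with ratio 1.
#' @return a \code{\link{populations}} object whose \code{by_microstate}
#'   gains the tautomer fractions; other macrostates are untouched.
#' @export
split_macrostate_by_ratios <- function(pops, macrostate, ratios) {
  stopifnot(inherits(pops, "populations"))
  if (!macrostate %in% names(pops$by_macrostate))
    stop("unknown macrostate '", macrostate, "'")
  if (is.null(names(ratios)) || any(!nzchar(names(ratios))))
    stop("ratios must be a named vector of tautomer labels")
  if (any(ratios <= 0)) stop("ratios must be positive")
  if (!any(abs(ratios - 1) < 1e-12))
    stop("ratios must include the anchor tautomer with ratio 1")
  fmac <- pops$by_macrostate[macrostate]
  f <- fmac * ratios / sum(ratios)
  micro <- c(pops$by_microstate, stats::setNames(as.numeric(f), names(ratios)))
  mac_of <- c(pops$macrostate_of,
              stats::setNames(rep(macrostate, length(ratios)), names(ratios)))
  populations(by_macrostate = pops$by_macrostate, by_microstate = micro,
              macrostate_of = mac_of, pH = pops$pH)
}

#' Validate thermodynamic-cycle closure of an ionization model
#'
#' Every closed cycle of protonation edges must have zero pk sum (protonation
#' steps counted +pk, deprotonation steps -pk): the free energy of a
#' microstate cannot depend on the titration path.  A spanning tree is built
#' from the reference; every non-tree edge closes one independent cycle whose
#' residual is reported.
#'
#' @param model an \code{\link{ionization_model}}.
#' @param tol residual tolerance in pk units (default 1e-6).
#' @return data.frame with one row per independent cycle: the closing edge
#'   (\code{donor}, \code{acceptor}), its \code{pk}, the tree-implied pk
#'   (\code{pk_tree}), the \code{residual}, and \code{consistent}.
#' @export
validate_cycles <- function(model, tol = 1e-6) {
  gamma <- .tree_log_weights(model)
  e <- model$edges
  pk_tree <- gamma$gamma[e$donor] - gamma$gamma[e$acceptor]
  res <- abs(e$pk - pk_tree)
  out <- data.frame(donor = e$donor, acceptor = e$acceptor, pk = e$pk,
                    pk_tree = as.numeric(pk_tree),
                    residual = as.numeric(res))
  out <- out[!gamma$in_tree, , drop = FALSE]
  out$consistent <- out$residual <= tol
  rownames(out) <- NULL
  out
}

# spanning-tree weights: like .state_log_weights but records tree membership
.tree_log_weights <- function(model) {
  labs <- model$microstates$label
  gamma <- stats::setNames(rep(NA_real_, length(labs)), labs)
  gamma[model$reference] <- 0
  in_tree <- rep(FALSE, nrow(model$edges))
  queue <- model$reference
  e <- model$edges
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (i in seq_len(nrow(e))) {
      if (in_tree[i]) next
      if (e$acceptor[i] == cur && is.na(gamma[e$donor[i]])) {
        gamma[e$donor[i]] <- gamma[cur] + e$pk[i]
        in_tree[i] <- TRUE; queue <- c(queue, e$donor[i])
      } else if (e$donor[i] == cur && is.na(gamma[e$acceptor[i]])) {
        gamma[e$acceptor[i]] <- gamma[cur] - e$pk[i]
        in_tree[i] <- TRUE; queue <- c(queue, e$acceptor[i])
      }
    }
  }
  list(gamma = gamma, in_tree = in_tree)
}
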