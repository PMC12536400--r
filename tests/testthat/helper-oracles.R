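# Independent brute-force oracles used across test files.

# Macrostate fractions computed the other way round: unnormalized weights
# accumulated from the fully protonated state by successive dissociations
# (weight ratio 10^(pH - pKa_i) per step), then normalized.
oracle_macro_fractions <- function(pkas, pH) {
  lw <- c(0, cumsum(pH - pkas))   # fully protonated first
  w <- 10^(lw - max(lw))
  f <- w / sum(w)                 # ordered most -> least protonated
  rev(f)                          # least protonated first, to match j = 0..N
}

# All simple paths between two microstates in an ionization model, as lists
# of signed pk sums (protonation +pk, deprotonation -pk).  Small models only.
oracle_path_sums <- function(model, from, to) {
  e <- model$edges
  sums <- c()
  walk <- function(cur, visited, acc) {
    if (cur == to) { sums <<- c(sums, acc); return(invisible()) }
    up <- e[e$acceptor == cur, , drop = FALSE]
    for (i in seq_len(nrow(up))) if (!up$donor[i] %in% visited)
      walk(up$donor[i], c(visited, up$donor[i]), acc + up$pk[i])
    dn <- e[e$donor == cur, , drop = FALSE]
    for (i in seq_len(nrow(dn))) if (!dn$acceptor[i] %in% visited)
      walk(dn$acceptor[i], c(visited, dn$acceptor[i]), acc - dn$pk[i])
  }
  walk(from, from, 0)
  sums
}

# Default tetracycline species with specific permeabilities taken as direct
# inputs (no profiles), charged macrostates and TC_Zp as proxies of TC_Z.
tc_value_species <- function(p_n = 2.22e-2, p_z = 1.63e-8,
                             level = c("lumped", "microstate")) {
  level <- match.arg(level)
  sp <- list(species_input("TC_N", specific_permeability = p_n),
             species_input("TC_Z", specific_permeability = p_z),
             species_input("TC_Zp", proxy_of = "TC_Z"))
  proxies <- if (level == "lumped") c("+1", "-1", "-2")
             else c("A0B+C0", "A-B0C0", "A-B+C-", "A0B0C-", "A-B0C-")
  for (lab in proxies) sp[[lab]] <- species_input(lab, proxy_of = "TC_Z")
  sp
}

constant_diffusivity <- function(pmf, D) {
  profile1d(pmf$z, rep(D, length(pmf$z)), kind = "diffusivity")
}
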