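# Independent oracles used across tests.

# Brute-force Ward minimum-variance agglomeration: at each step merge the
# pair of clusters minimizing the increase in total within-cluster sum of
# squares; the merge height is sqrt(2 * increase), i.e. the unsquared
# Euclidean dialect.  Returns the cophenetic distance matrix, a complete
# order-free description of the tree.
ward_oracle_cophenetic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  cl <- lapply(seq_len(n), function(i) i)
  coph <- matrix(0, n, n)
  while (length(cl) > 1) {
    best <- Inf
    bi <- bj <- 0L
    for (a in 2:length(cl)) {
      for (b in 1:(a - 1)) {
        A <- cl[[a]]; B <- cl[[b]]
        d2 <- sum((colMeans(x[A, , drop = FALSE]) -
                     colMeans(x[B, , drop = FALSE]))^2)
        cost <- 2 * length(A) * length(B) / (length(A) + length(B)) * d2
        if (cost < best) { best <- cost; bi <- a; bj <- b }
      }
    }
    A <- cl[[bi]]; B <- cl[[bj]]
    coph[A, B] <- coph[B, A] <- sqrt(best)
    cl[[bj]] <- c(A, B)
    cl <- cl[-bi]
  }
  coph
}

# Random valid blood panels for property tests.
random_panels <- function(n) {
  tibble::tibble(
    pH_v = runif(n, 7.0, 7.7),
    pCO2_v = runif(n, 25, 70),
    ctHb = runif(n, 6, 15),
    body_temp = runif(n, 37.5, 40.5),
    cNa = runif(n, 125, 155),
    cK = runif(n, 2.5, 6),
    cCa_ion = runif(n, 0.8, 1.6),
    cCl = runif(n, 90, 115),
    cLactate = runif(n, 0, 3),
    cPi = runif(n, 0.8, 3),
    cMg_total = runif(n, 0.5, 1.5),
    cAlbumin = runif(n, 20, 42),
    cGlobulin = runif(n, 20, 55)
  )
}

# Construct a blood panel that is exactly electroneutral apart from an
# injected amount u of unmeasured strong anion: sodium is set so that all
# measured charge concentrations balance, so the electroneutrality
# residual must recover u.
electroneutral_panel <- function(u, pH = 7.40, pCO2 = 45, cK = 4,
                                 cCa_ion = 1.2, cMg_total = 0.9,
                                 cCl = 104, cPi = 2, cAlbumin = 32,
                                 cGlobulin = 38) {
  k <- acidbase_constants()
  hco3 <- actual_bicarbonate(pH, pCO2, k)
  ch <- weak_acid_charges(cAlbumin, cAlbumin + cGlobulin, cPi, pH, k)
  cNa <- cCl + hco3 + ch$charge_albumin + ch$charge_globulin +
    ch$charge_phosphate + u - cK - 2 * cCa_ion -
    k$mg_net_charge * cMg_total
  tibble::tibble(
    pH_v = pH, pCO2_v = pCO2, ctHb = 10, body_temp = 38.5,
    cNa = cNa, cK = cK, cCa_ion = cCa_ion, cCl = cCl, cLactate = 0,
    cPi = cPi, cMg_total = cMg_total, cAlbumin = cAlbumin,
    cGlobulin = cGlobulin, injected_xa = u
  )
}
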