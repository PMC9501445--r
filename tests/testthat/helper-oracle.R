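# Independent oracles used across the suite.

# Brute-force speciation oracle: dense grid search plus golden-section
# refinement of the total mixture Gibbs energy along the feasible
# composition curve parameterized by the free-ligand activity.  Shares no
# code with the solver under test beyond the Gibbs-energy propagation of
# the parameter records.
oracle_speciation <- function(model, cond, nGrid = 2000) {
  RT <- gas_constant() * cond$T
  ref <- model$ref
  gI <- gibbs_energy(model$transitions[[1]], cond$T, cond$cK, ref)
  gQ <- gI + gibbs_energy(model$transitions[[2]], cond$T, cond$cK, ref)
  g1 <- gibbs_energy(model$sites[[1]], cond$T, ref = ref)
  g2 <- gibbs_energy(model$sites[[2]], cond$T, ref = ref)
  mu0 <- c(U = 0, I = gI, Q = gQ, QL = gQ + g2, IL = gI + g2,
           LI = gI + g1, LIL = gI + g1 + g2)
  nu <- c(0, 0, 0, 1, 1, 1, 2)
  comp <- function(lam) {
    lw <- -mu0 / RT
    if (lam > 0) lw <- lw + nu * log(lam) else lw[nu > 0] <- -Inf
    w <- exp(lw - max(lw))
    cs <- cond$cDNA * w / sum(w)
    list(cs = cs, free = cond$cL - sum(nu * cs))
  }
  Gtot <- function(lam) {
    k <- comp(lam)
    if (k$free < 0) return(Inf)
    xlogx <- function(c) ifelse(c > 0, c * (log(c) - 1), 0)
    sum(k$cs * mu0) + RT * (sum(xlogx(k$cs)) + xlogx(k$free))
  }
  grid <- seq(0, cond$cL, length.out = nGrid)
  i <- which.min(vapply(grid, Gtot, numeric(1)))
  a <- grid[max(i - 1, 1)]; b <- grid[min(i + 1, nGrid)]
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- Gtot(x1); f2 <- Gtot(x2)
  for (it in 1:200) {
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1; x1 <- b - phi * (b - a); f1 <- Gtot(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2; x2 <- a + phi * (b - a); f2 <- Gtot(x2)
    }
    if ((b - a) < 1e-14 * cond$cL) break
  }
  k <- comp(0.5 * (a + b))
  list(fractions = k$cs / cond$cDNA, freeLigand = k$free)
}

# random valid condition with appreciable ligand, for property tests
random_condition <- function() {
  conditions(runif(1, 278, 370), 10^runif(1, -4, -1),
             10^runif(1, -6, -4), 10^runif(1, -6, -4.3))
}

# two-state van't Hoff excess heat capacity peak height: dH^2 / (4 R Tm^2)
vant_hoff_peak <- function(dH, Tm) dH^2 / (4 * gas_constant() * Tm^2)
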