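# Shared fixtures: networks are expensive enough to build once per session.

the <- new.env(parent = emptyenv())

test_net <- function() {
  if (is.null(the$net)) the$net <- build_network(default_config())
  the$net
}

test_ss <- function() {
  if (is.null(the$ss)) the$ss <- steady_state(test_net())
  the$ss
}

# configuration with all sources and sinks disabled (conservation checks)
conservative_config <- function() {
  modify_config(default_config(), list(
    kinetics = list(k_int = 0),
    secretion = list(
      tumor_cell = c(hVEGF121 = 0, hVEGF165 = 0),
      muscle = c(mVEGF120 = 0, mVEGF164 = 0),
      ec_normal = c(mVEGF120 = 0, mVEGF164 = 0),
      ec_blood = c(mVEGF120 = 0, mVEGF164 = 0),
      ec_tumor = c(mVEGF120 = 0, mVEGF164 = 0)),
    soluble = list(sR1_secretion = c(normal = 0, blood = 0, tumor = 0),
                   sR1_clearance = 0, a2m_conc = 0, a2m_turnover = 0),
    clearance = list(ligand = 0),
    drug = list(k_clear = 0)))
}

# independent combinatorial enumeration of the species a config generates
# (deliberately a different construction from build_network)
enumerate_species_count <- function(cfg) {
  n_lig <- length(cfg$ligands)
  n_hep <- sum(vapply(cfg$ligands, function(l) isTRUE(l$heparin),
                      logical(1)))
  n_hum <- sum(vapply(cfg$ligands,
                      function(l) identical(l$origin, "human"), logical(1)))
  total <- n_lig * 3                       # free ligands
  for (p in names(cfg$populations)) {
    dens <- cfg$populations[[p]]$receptors
    R <- sum(dens[c("VEGFR1", "VEGFR2")] > 0)
    N <- sum(dens[c("NRP1", "NRP2")] > 0)
    total <- total + R + N                  # free receptors
    if (isTRUE(cfg$rules$couple_nrp)) total <- total + R * N
    total <- total + n_lig * R              # ligand-VEGFR
    total <- total + n_hep * N              # heparin ligand-NRP
    if (isTRUE(cfg$rules$triples) && isTRUE(cfg$rules$couple_nrp))
      total <- total + n_lig * R * N        # ternary complexes
  }
  total <- total + 3 + 3 * n_lig            # sR1 + complexes
  total <- total + 2 + 2 * n_hep            # GAG sites + complexes
  total <- total + 1 + n_lig                # a2m + complexes
  n_drug_comp <- if (isTRUE(cfg$drug$extravasate)) 3 else 1
  total <- total + n_drug_comp * (1 + n_hum) + 1  # drug, complexes, cleared
  total
}

# independent SVD-based PLS2 oracle (same autoscaling and sign convention,
# but per-component weights from the SVD of the cross-covariance)
svd_pls_oracle <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xa <- scale(X); Ya <- scale(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  W <- matrix(0, p, ncomp); TT <- matrix(0, n, ncomp)
  P <- matrix(0, p, ncomp); Q <- matrix(0, m, ncomp)
  for (a in seq_len(ncomp)) {
    w <- svd(crossprod(Xa, Ya))$u[, 1]
    s <- sign(w[which.max(abs(w))])
    w <- s * w
    tt <- Xa %*% w
    pp <- crossprod(Xa, tt) / sum(tt^2)
    q <- crossprod(Ya, tt) / sum(tt^2)
    Xa <- Xa - tt %*% t(pp)
    Ya <- Ya - tt %*% t(q)
    W[, a] <- w; TT[, a] <- tt; P[, a] <- pp; Q[, a] <- q
  }
  list(W = W, T = TT, P = P, Q = Q)
}
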