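# Independent oracles and small fixtures shared across the suite.

# Node-potential (Laplacian) solve of the strand resistor network: fixes the
# basal node at V_s and the apical node at ground, eliminates the interior
# compartments, and returns R_2D = V_s / I. Independent of the package's
# loop-analysis path.
nodal_r2d <- function(net, R_sections, V_s = 1) {
  sec <- net$sections
  nc <- nrow(net$compartments)
  idx <- function(x) ifelse(x == 0, nc + 1L, ifelse(x == -1, nc + 2L, x))
  n <- nc + 2L
  L <- matrix(0, n, n)
  for (s in seq_len(nrow(sec))) {
    i <- idx(sec$from[s]); j <- idx(sec$to[s])
    g <- 1 / R_sections[s]
    L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
    L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
  }
  free <- seq_len(nc)
  phi <- numeric(n)
  phi[nc + 1L] <- V_s
  if (nc > 0) {
    phi[free] <- solve(L[free, free], -L[free, nc + 1L] * V_s)
  }
  I <- -sum(L[nc + 2L, ] * phi)  # current into the grounded apical node
  V_s / abs(I)
}

# Steady-state flux through a network with a fixed broken/intact pattern:
# direct linear solve of the compartment balance (basal clamped, apical
# absorbing). Returns the permeability implied by Eq-8-style scaling.
static_permeability <- function(net, geom, P_break, states,
                                conc_basal = 6.02214076e23) {
  sec <- net$sections
  A <- net$compartments$area
  nc <- nrow(net$compartments)
  k <- geom$l_break * P_break
  M <- matrix(0, nc, nc); b <- numeric(nc)
  for (s in seq_len(nrow(sec))) {
    if (states[s] == 0) next
    f <- sec$from[s]; t <- sec$to[s]
    if (f > 0 && t > 0) {
      M[t, f] <- M[t, f] + k / A[f]; M[f, f] <- M[f, f] - k / A[f]
      M[f, t] <- M[f, t] + k / A[t]; M[t, t] <- M[t, t] - k / A[t]
    } else if (f == 0) {
      b[t] <- b[t] + k * conc_basal; M[t, t] <- M[t, t] - k / A[t]
    } else {
      M[f, f] <- M[f, f] - k / A[f]
    }
  }
  q <- solve(M, -b)
  flux <- 0
  for (s in seq_len(nrow(sec))) {
    if (states[s] == 1 && sec$to[s] == -1) {
      flux <- flux + k / A[sec$from[s]] * q[sec$from[s]]
    }
  }
  flux / (net$w_model * conc_basal)
}

# Two-state chain distribution after 2^k synchronous updates: the transition
# matrix is squared k times (k = 30 reaches the infinite-time limit to
# machine precision for any admissible probabilities, while keeping the
# accumulated row-sum rounding of order 2^k * eps negligible), then applied
# to the uninformative (1/2, 1/2) start.
chain_power <- function(p_break_l, p_seal, k = 30, start = c(0.5, 0.5)) {
  Tm <- matrix(c(1 - p_break_l, p_break_l, p_seal, 1 - p_seal), 2, 2,
               byrow = TRUE)
  for (i in seq_len(k)) {
    Tm <- Tm %*% Tm
    Tm <- Tm / rowSums(Tm)  # keep the matrix exactly stochastic
  }
  as.numeric(start %*% Tm)  # (intact, broken)
}
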