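# Small randomly perturbed meshes used by the gradient and oracle tests.
# Perturbations are kept small enough that every element stays simple.

perturbed_strip <- function(seed, n = 8, amp = 0.01) {
  set.seed(seed)
  tis <- opticcup:::build_strip(n, length = 1, thickness = 0.15,
                                x_start = 1)
  m <- nrow(tis$vertices)
  tis$vertices$x <- tis$vertices$x + runif(m, -amp, amp)
  tis$vertices$z <- tis$vertices$z + runif(m, -amp, amp)
  tis
}

perturbed_arc <- function(seed, n = 10, amp = 0.005) {
  set.seed(seed)
  tis <- build_vesicle(n, prestress = (seed %% 2 == 0))
  m <- nrow(tis$vertices)
  tis$vertices$x <- tis$vertices$x + runif(m, -amp, amp)
  tis$vertices$z <- tis$vertices$z + runif(m, -amp, amp)
  tis
}

# independent per-term energy oracles, written as plain loops
oracle_elastic <- function(tissue) {
  P <- cbind(tissue$vertices$x, tissue$vertices$z)
  sp <- tissue$springs
  tot <- 0
  for (s in seq_len(nrow(sp))) {
    l <- sqrt(sum((P[sp$i[s], ] - P[sp$j[s], ])^2))
    tot <- tot + 0.5 * sp$k[s] * (l - sp$l0[s])^2
  }
  tot
}

oracle_volume <- function(tissue, element) {
  P <- cbind(tissue$vertices$x, tissue$vertices$z)
  el <- tissue$elements[element, ]
  ids <- c(el$a1, el$a2, el$b2, el$b1)
  x <- P[ids, 1]; z <- P[ids, 2]
  a <- 0
  for (m in 1:4) {
    mn <- m %% 4 + 1
    a <- a + x[m] * z[mn] - x[mn] * z[m]
  }
  2 * pi * mean(x) * abs(a / 2)
}

oracle_volumetric <- function(tissue, k_v) {
  tot <- 0
  for (e in seq_len(nrow(tissue$elements))) {
    V <- oracle_volume(tissue, e)
    Veq <- tissue$elements$V_eq[e]
    tot <- tot + 0.5 * k_v * ((V - Veq) / Veq)^2 * Veq
  }
  tot
}

# interior angle at corner p between neighbours a and b, in (0, pi) for
# convex corners, computed independently with atan2
oracle_angle <- function(P, a, p, b) {
  u <- P[a, ] - P[p, ]
  v <- P[b, ] - P[p, ]
  abs(atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)))
}

oracle_distortion <- function(tissue, k_s) {
  P <- cbind(tissue$vertices$x, tissue$vertices$z)
  el <- tissue$elements
  tot <- 0
  for (e in seq_len(nrow(el))) {
    ids <- c(el$a1[e], el$a2[e], el$b2[e], el$b1[e])
    th_eq <- c(el$th_eq_a1[e], el$th_eq_a2[e], el$th_eq_b2[e],
               el$th_eq_b1[e])
    for (m in 1:4) {
      mp <- (m - 2) %% 4 + 1
      mn <- m %% 4 + 1
      th <- oracle_angle(P, ids[mp], ids[m], ids[mn])
      tot <- tot + 0.5 * k_s * (th - th_eq[m])^2
    }
  }
  tot
}
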