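# Independent closed-form oracle used to cross-check the network solver.
#
# For a beam whose helices all carry the same junction/nick counts at the
# same axial positions (mirror-symmetric two-helix designs), every helix
# deforms identically, rigid ties transmit no load, and the beam reduces to
# identical element chains in parallel. The apparent stiffness is then a
# pure series-parallel expression in the element counts -- no linear algebra.
oracle_series_stiffness <- function(design, material) {
  bp <- design$bp_per_helix
  denom <- vapply(seq_len(design$n_helices), function(h) {
    n_part <- sum(design$junctions$helix_a == h | design$junctions$helix_b == h)
    n_nick <- sum(design$nicks$helix == h)
    n_hj_el <- n_part * material$n_hj
    n_nick_el <- n_nick * material$n_nick
    n_ds <- bp - n_hj_el - n_nick_el
    n_ds + n_hj_el / material$alpha + n_nick_el / material$beta
  }, numeric(1))
  sum(material$EA * bp / denom)
}

# closed-form inversion of the series-parallel expression for alpha on a
# mirror-symmetric ligated two-helix beam
oracle_invert_alpha <- function(target_K, design, material) {
  bp <- design$bp_per_helix
  n_hj_el <- nrow(design$junctions) * material$n_hj  # per helix
  denom <- 2 * material$EA * bp / target_K           # total series compliance units
  n_hj_el / (denom - (bp - n_hj_el))
}

# ... and for beta with alpha fixed, on the nicked counterpart
oracle_invert_beta <- function(target_K, design, material, alpha) {
  bp <- design$bp_per_helix
  n_hj_el <- nrow(design$junctions) * material$n_hj
  n_nick_el <- nrow(design$nicks) / 2 * material$n_nick  # per helix
  denom <- 2 * material$EA * bp / target_K
  n_nick_el / (denom - (bp - n_hj_el - n_nick_el) - n_hj_el / alpha)
}

# brute-force junction enumeration for the two-helix builder: walk every
# multiple of the spacing and keep it if at least half a repeat remains
# before the helix end
brute_force_junctions <- function(bp, spacing) {
  bp <- as.integer(bp)
  spacing <- as.integer(spacing)
  pos <- integer()
  i <- 1L
  repeat {
    p <- spacing * i
    if (p >= bp) break
    if ((bp - p) * 2L >= spacing) pos <- c(pos, p)
    i <- i + 1L
  }
  pos
}
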