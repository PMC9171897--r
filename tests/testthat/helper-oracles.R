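# Independent oracles and small builders shared across tests.

# Exhaustive polynomial-expansion oracle for isotope envelopes: multiply in
# one atom at a time, never truncating, then read off the leading terms.
# Deliberately naive and independent of the package's binary-exponentiation
# convolution.
oracle_envelope <- function(counts, K) {
  poly <- 1
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0) next
    tab <- element_isotopes()
    tab <- tab[tab$element == el, ]
    base <- numeric(max(tab$shift) + 1L)
    base[tab$shift + 1L] <- tab$abundance
    base <- base / sum(base)
    for (i in seq_len(n)) {
      new <- numeric(length(poly) + length(base) - 1L)
      for (a in seq_along(poly))
        for (b in seq_along(base))
          new[a + b - 1L] <- new[a + b - 1L] + poly[a] * base[b]
      poly <- new
    }
  }
  out <- numeric(K + 1L)
  take <- seq_len(min(K + 1L, length(poly)))
  out[take] <- poly[take]
  out
}

# random small elemental composition (kept tiny so the oracle stays fast)
random_composition <- function() {
  structure(list(counts = c(C = sample(1:12, 1), H = sample(1:20, 1),
                            N = sample(0:4, 1), O = sample(0:5, 1),
                            S = sample(0:1, 1)),
                 label = NA_character_,
                 monoisotopic_mass = 500),
            class = "elemental_composition")
}

# wrap a bare abundance vector as an isotope_envelope
make_envelope <- function(abundances, mass = 1000, spacing = 1.00335) {
  structure(list(abundances = abundances, monoisotopic_mass = mass,
                 spacing = spacing, label = "light16O"),
            class = "isotope_envelope")
}

# forward-simulate summed channel intensities from true per-scan species
# totals L and H under the +2-position shift of the heavy envelope
forward_channels <- function(abund, light_channel, heavy_channel, L, H) {
  pos_int <- function(positions) {
    sapply(positions, function(k) {
      l <- if (k >= 0 && k < length(abund)) abund[k + 1L] * L else 0
      h <- if (k - 2L >= 0 && k - 2L < length(abund)) abund[k - 1L] * H else 0
      l + h
    })
  }
  c(light = sum(pos_int(light_channel)), heavy = sum(pos_int(heavy_channel)))
}

# MS1 map with explicitly placed peaks: peak_df has scan, mz, intensity
build_ms1 <- function(rt, peak_df, run_id = "test") {
  peaks <- lapply(seq_along(rt), function(s) {
    p <- peak_df[peak_df$scan == s, c("mz", "intensity"), drop = FALSE]
    as.matrix(p)
  })
  ms1_map(rt, peaks, run_id = run_id)
}

# stoichiometry draw used by null-behavior tests: mostly low values with a
# modest oxidation-prone tail
.default_mos_draw_test <- function(n) {
  pmin(0.9, rbeta(n, 2.5, 50) +
         ifelse(runif(n) < 0.1, runif(n, 0.2, 0.4), 0))
}

# per-run MOS measurements drawn from the carrier-mixing model plus noise
simulate_measurements <- function(design, mos_true, sd = 0.01) {
  design$mos <- design$t + (1 - design$t) * mos_true +
    rnorm(nrow(design), 0, sd)
  design
}
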