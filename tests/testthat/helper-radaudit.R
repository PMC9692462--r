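# shared helpers for the radaudit test suite

fixture <- function(name) radaudit_example(name)

# independent random complete species set (plain uniform draws; the
# identities must hold for ANY species enthalpies)
random_species <- function(id = "m", unit_scale = 1e6) {
  species_enthalpies(
    id, "1-OH",
    H_AXH = -stats::runif(1, 1, 2) * unit_scale,
    H_AXrad = -stats::runif(1, 1, 2) * unit_scale,
    H_AXanion = -stats::runif(1, 1, 2) * unit_scale,
    H_AXHcation = -stats::runif(1, 1, 2) * unit_scale)
}

# is `target` in the row span of `vectors`? (least-squares residual test)
in_span <- function(target, vectors) {
  fit <- qr.solve(t(vectors), target)
  max(abs(t(vectors) %*% fit - target)) < 1e-9
}

# rank oracle independent of the package's exact elimination
rank_oracle <- function(M) qr(M)$rank
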