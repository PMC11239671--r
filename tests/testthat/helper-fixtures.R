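# Shared fixture builders.

# Energy components whose Eq.-style combination gives
# dE_Q = -40, dE_vdW = -77.5 (kJ/mol), i.e. dF = -32.4 kJ/mol.
peComponents <- function() {
  new("EnergyComponents", energies = list(
    "p-L" = c(Q = -50, vdW = -90),
    "p*" = c(Q = -4, vdW = -5),
    "L(g)" = c(Q = -1, vdW = -2),
    "m-L" = c(Q = -10, vdW = -15.5),
    "m*" = c(Q = -4, vdW = -8)),
    burnInDiscarded = 0L)
}

# Components giving dF = -13.2 kJ/mol (dE_Q = -10, dE_vdW = -51.25).
pcComponents <- function() {
  new("EnergyComponents", energies = list(
    "p-L" = c(Q = -20, vdW = -63.75),
    "p*" = c(Q = -4, vdW = -5),
    "L(g)" = c(Q = -1, vdW = -2),
    "m-L" = c(Q = -10, vdW = -15.5),
    "m*" = c(Q = -4, vdW = -8)),
    burnInDiscarded = 0L)
}

zAxis <- function() new("Axis", direction = c(0, 0, 1), anchor = c(0, 0, 0))

# Random rigid rotation matrix.
randomRotation <- function() {
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m)) * sign(det(qr.Q(qr(m))))
}
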