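# Physical constants and residue/modification mass tables.
# Monoisotopic residue masses are derived from elemental compositions with
# H = 1.00782503207, C = 12, N = 14.0030740048, O = 15.9949146196,
# S = 31.972071 Da, so downstream sums are accurate well below 1e-6 Da.

PROTON_MASS <- 1.00727646688
WATER_MASS <- 18.01056468374

RESIDUE_MASSES <- c(
  G = 57.02146372,
  A = 71.03711378,
  S = 87.03202840,
  P = 97.05276385,
  V = 99.06841391,
  T = 101.04767847,
  C = 103.00918478,
  L = 113.08406398,
  I = 113.08406398,
  N = 114.04292744,
  D = 115.02694302,
  Q = 128.05857751,
  K = 128.09496301,
  E = 129.04259309,
  M = 131.04048491,
  H = 137.05891186,
  F = 147.06841391,
  R = 156.10111102,
  Y = 163.06332853,
  W = 186.07931295
)

STANDARD_RESIDUES <- names(RESIDUE_MASSES)

# Built-in modification registry. `aliases` cover the notations met in the
# wild: PeakView short codes, Spectronaut bracket names, UniMod ids.
MODIFICATION_REGISTRY <- data.frame(
  name = c("Carbamidomethyl", "Oxidation", "Acetyl", "Phospho",
           "Deamidated", "Methyl", "Gln->pyro-Glu"),
  delta_mass = c(57.02146372, 15.99491462, 42.01056468, 79.96633052,
                 0.98401558, 14.01565006, -17.02654910),
  unimod_id = c(4L, 35L, 1L, 21L, 7L, 34L, 28L),
  stringsAsFactors = FALSE
)

MODIFICATION_ALIASES <- list(
  Carbamidomethyl = c("carbamidomethyl", "cam", "carbamidomethylation", "iaa"),
  Oxidation = c("oxidation", "oxi", "ox", "hydroxylation"),
  Acetyl = c("acetyl", "ace", "acetylation"),
  Phospho = c("phospho", "pho", "phosphorylation"),
  Deamidated = c("deamidated", "dea", "deamidation"),
  Methyl = c("methyl", "met", "methylation"),
  `Gln->pyro-Glu` = c("gln->pyro-glu", "pyro-glu", "pyroglu", "pgq")
)

DECOY_PREFIXES_DEFAULT <- c("DECOY_", "decoy_", "rev_", "reverse_")
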