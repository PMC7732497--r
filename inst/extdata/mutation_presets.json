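{
  "KCNQ1-S140G": {
    "multipliers": { "g_Ks": 8 },
    "note": "Approximate conductance-level surrogate. S140G makes IKs constitutively active (gain of function); represented here as a strong g_Ks up-scaling. The full Markov kinetics live in the primary electrophysiology literature."
  },
  "KCNQ1-V241F": {
    "multipliers": { "g_Ks": 5 },
    "note": "Approximate conductance-level surrogate for the V241F IKs gain-of-function variant (left-shifted activation, slowed deactivation), represented as g_Ks up-scaling."
  },
  "KCNQ1-G229D": {
    "multipliers": { "g_Ks": 4 },
    "note": "Approximate conductance-level surrogate for the G229D IKs gain-of-function variant, represented as g_Ks up-scaling."
  },
  "hERG-L532P": {
    "multipliers": { "g_Kr": 4 },
    "note": "Approximate conductance-level surrogate for the L532P IKr variant (accelerated recovery from inactivation, net gain of function), represented as g_Kr up-scaling."
  },
  "hERG-N588K": {
    "multipliers": { "g_Kr": 3 },
    "note": "Approximate conductance-level surrogate for the short-QT N588K IKr variant (attenuated inactivation), represented as g_Kr up-scaling."
  }
}
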