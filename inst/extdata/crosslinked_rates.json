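{
  "mechanism_variant": "crosslinked",
  "rates": {
    "k1": {
      "value": 10,
      "units": "uM^-1 s^-1",
      "note": "assumed diffusion-limited DNA association"
    },
    "k-1": {
      "value": 0.93,
      "units": "s^-1",
      "note": "measured dissociation rate of the uncrosslinked binary complex (37 C)"
    },
    "k2": {
      "value": 4.5,
      "units": "s^-1",
      "note": "measured Schiff-base formation rate (25 C)"
    },
    "k3": {
      "value": 50,
      "units": "s^-1",
      "note": "assumed fast exchange between near-isoenergetic binary substates"
    },
    "k-3": {
      "value": 50,
      "units": "s^-1",
      "note": "assumed equal to k3 (substates near-isoenergetic)"
    },
    "k4": {
      "value": 100,
      "units": "uM^-1 s^-1",
      "note": "assumed diffusion-limited nucleotide association"
    },
    "k-4": {
      "value": 38,
      "units": "s^-1",
      "note": "fixed by measured K_d = 0.38 uM and k4"
    },
    "k5": {
      "value": 0.72,
      "units": "s^-1",
      "note": "measured maximal incorporation rate k_p (25 C)"
    },
    "k-5": {
      "value": 0,
      "units": "s^-1",
      "note": "rearrangement treated as irreversible on the assay timescale"
    },
    "k6": {
      "value": 36,
      "units": "s^-1",
      "note": "assumed fast chemistry, 50x k5 (small sulfur elemental effect)"
    },
    "k-6": {
      "value": 18,
      "units": "s^-1",
      "note": "fixed by inferred internal equilibrium k6/k-6 = 2"
    },
    "k7": {
      "value": 0.02,
      "units": "s^-1",
      "note": "assumed slow reopening, below k5 and k6 (stable quench plateau)"
    },
    "k-7": {
      "value": 0,
      "units": "s^-1",
      "note": "treated as irreversible"
    },
    "k8": {
      "value": 10,
      "units": "s^-1",
      "note": "assumed fast pyrophosphate release"
    },
    "k9": {
      "value": 0.14,
      "units": "s^-1",
      "note": "estimated beta-elimination rate"
    },
    "k10": {
      "value": 0.93,
      "units": "s^-1",
      "note": "assumed equal to the measured nicked-product release rate"
    }
  }
}
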