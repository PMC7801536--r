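{
  "_schema": {
    "half_life_h": "physical half-life in hours",
    "emissions": "per-decay emission lines: kind in {alpha, beta_plus, beta_minus, discrete_electron, photon}; energy_mev is the mean energy for continuous beta spectra (endpoint_mev then gives the spectrum endpoint) and the line energy otherwise; yield is emissions per parent decay",
    "daughters": "decay products with branching fraction per parent decay; only nuclides named here are resolvable",
    "_note": "Compact per-decay inventories compiled and rounded from published ICRP-107-style decay tables; minor lines (<~1% of emitted energy) are merged or dropped."
  },
  "nuclides": {
    "F-18": {
      "half_life_h": 1.8295,
      "emissions": [
        {"kind": "beta_plus", "energy_mev": 0.2498, "yield": 0.9686, "endpoint_mev": 0.6335},
        {"kind": "photon", "energy_mev": 0.511, "yield": 1.9372}
      ],
      "daughters": []
    },
    "At-211": {
      "half_life_h": 7.214,
      "emissions": [
        {"kind": "alpha", "energy_mev": 5.8695, "yield": 0.418},
        {"kind": "photon", "energy_mev": 0.0787, "yield": 0.414},
        {"kind": "discrete_electron", "energy_mev": 0.005, "yield": 1.0}
      ],
      "daughters": [
        {"name": "Po-211", "branching": 0.582},
        {"name": "Bi-207", "branching": 0.418}
      ]
    },
    "Po-211": {
      "half_life_h": 1.4333e-4,
      "emissions": [
        {"kind": "alpha", "energy_mev": 7.4503, "yield": 0.9892},
        {"kind": "alpha", "energy_mev": 6.8912, "yield": 0.0055},
        {"kind": "alpha", "energy_mev": 6.5681, "yield": 0.0054},
        {"kind": "photon", "energy_mev": 0.8979, "yield": 0.0055},
        {"kind": "photon", "energy_mev": 0.5695, "yield": 0.0054}
      ],
      "daughters": []
    },
    "Bi-207": {
      "half_life_h": 276400,
      "emissions": [
        {"kind": "photon", "energy_mev": 0.5697, "yield": 0.978},
        {"kind": "photon", "energy_mev": 1.0637, "yield": 0.745},
        {"kind": "discrete_electron", "energy_mev": 0.482, "yield": 0.017}
      ],
      "daughters": []
    },
    "I-131": {
      "half_life_h": 192.6,
      "emissions": [
        {"kind": "beta_minus", "energy_mev": 0.1916, "yield": 1.0, "endpoint_mev": 0.6063},
        {"kind": "photon", "energy_mev": 0.3645, "yield": 0.815},
        {"kind": "photon", "energy_mev": 0.637, "yield": 0.0717},
        {"kind": "photon", "energy_mev": 0.2843, "yield": 0.0614},
        {"kind": "photon", "energy_mev": 0.0802, "yield": 0.0262},
        {"kind": "discrete_electron", "energy_mev": 0.3299, "yield": 0.017},
        {"kind": "discrete_electron", "energy_mev": 0.0456, "yield": 0.035}
      ],
      "daughters": [
        {"name": "Xe-131m", "branching": 0.0118}
      ]
    },
    "Xe-131m": {
      "half_life_h": 284.2,
      "emissions": [
        {"kind": "photon", "energy_mev": 0.1639, "yield": 0.0196},
        {"kind": "discrete_electron", "energy_mev": 0.1429, "yield": 0.961}
      ],
      "daughters": []
    },
    "Lu-177": {
      "half_life_h": 159.53,
      "emissions": [
        {"kind": "beta_minus", "energy_mev": 0.1343, "yield": 1.0, "endpoint_mev": 0.4983},
        {"kind": "photon", "energy_mev": 0.2084, "yield": 0.1041},
        {"kind": "photon", "energy_mev": 0.1129, "yield": 0.0617},
        {"kind": "discrete_electron", "energy_mev": 0.101, "yield": 0.12}
      ],
      "daughters": []
    }
  }
}
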