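{
  "version": 1,
  "comment": "Default parameters of the built-in toy molecular-mechanics model. Units: energies Hartree, lengths Angstrom, angles degrees, force constants Hartree/A^2 or Hartree/rad^2.",
  "bond": {
    "k": {
      "CC": 0.9,
      "CO": 1.0,
      "CH": 0.8,
      "OH": 0.85,
      "CO2": 1.2
    },
    "r0": {
      "CC": 1.52,
      "CO": 1.43,
      "CH": 1.1,
      "OH": 0.97,
      "CO2": 1.21
    },
    "D": {
      "CC": 0.45,
      "CO": 0.45,
      "CH": 0.5,
      "OH": 0.5,
      "CO2": 0.55
    }
  },
  "angle": {
    "k": 0.15,
    "theta0_sp3": 109.47,
    "theta0_sp2": 120.0,
    "theta0_O": 113.0
  },
  "torsion": {
    "k3": 0.0004
  },
  "ring_profile": {
    "k2": 0.0005,
    "k3": 0.0005
  },
  "nonbonded": {
    "eps": 0.008,
    "sigma_HH": 1.8,
    "sigma_XH": 2.2,
    "sigma_XX": 2.7
  }
}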