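{
  "note": "Decision rules for assigning a screening-PCR result panel to a GM petunia group. The branch order is reconstructed from published screening-panel patterns (the exact decision-tree figure is not machine-readable); amend the rules here without code changes. Condition semantics: 'positive' and 'negative' are strict states, 'not_positive' accepts negative and not-tested, 'all_negative_ignoring_not_tested' requires every tested target in the referenced group to be negative.",
  "targets": ["actin", "P-35S", "T-nos", "T-35S", "T-ocs", "P-nos", "nptII", "P-nos/nptII", "dfr-construct", "F35H-construct", "PxhG1", "PxhG2"],
  "gm_targets": ["P-35S", "T-nos", "T-35S", "T-ocs", "P-nos", "nptII", "P-nos/nptII", "dfr-construct", "F35H-construct", "PxhG1", "PxhG2"],
  "rules": [
    {
      "id": "control-check",
      "label": "invalid",
      "when": [{"target": "actin", "is": "negative"}],
      "rationale": "The endogenous actin control failed: the DNA extract did not amplify, so no statement about GM origin is possible.",
      "references": []
    },
    {
      "id": "g1-event-positive",
      "label": "G1",
      "when": [{"target": "PxhG1", "is": "positive"}],
      "rationale": "The G1 event-specific junction assay is positive; the sample carries the orange-flower dfr-MAIZE construct insertion.",
      "references": ["meyer-dfr-construct"]
    },
    {
      "id": "g2-event-positive",
      "label": "G2",
      "when": [{"target": "PxhG2", "is": "positive"}],
      "rationale": "The G2 event-specific junction assay is positive; the sample carries the F3'5'H construct insertion, attributable to either of two Asian constructs.",
      "references": ["ak14-construct", "pcgp1392-construct"]
    },
    {
      "id": "no-gm-signal",
      "label": "non-GM",
      "when": [{"group": "gm_targets", "is": "all_negative_ignoring_not_tested"}],
      "rationale": "Every tested GM element, construct and event target is negative: no evidence of genetic modification.",
      "references": []
    },
    {
      "id": "legacy-dfr",
      "label": "legacy-dfr-event",
      "when": [
        {"target": "P-35S", "is": "positive"},
        {"target": "T-nos", "is": "not_positive"},
        {"target": "PxhG1", "is": "not_positive"}
      ],
      "rationale": "P-35S-positive without T-nos and without the G1 junction: consistent with the original research-line dfr events (RL01-like) rather than the marketed G1 group. A negative T-ocs with positive T-35S does not contradict this: the T-ocs element is truncated in event RL01-17, so T-ocs assays can read negative there.",
      "references": ["meyer-dfr-construct", "rl01-field-trial"]
    },
    {
      "id": "fallback",
      "label": "GM-unassigned",
      "when": [],
      "rationale": "GM targets are positive but the pattern matches neither event-specific assay nor a known legacy pattern; further characterization (e.g. junction sequencing) is required.",
      "references": []
    }
  ],
  "references": {
    "meyer-dfr-construct": "Construct development for the maize dfr (A1) orange-flower petunia lines.",
    "ak14-construct": "Asian F3'5'H construct AK14.",
    "pcgp1392-construct": "Asian F3'5'H construct pCGP1392.",
    "rl01-field-trial": "RL01-17 / RL01-24 research-line events from the early 1990s field trial."
  }
}
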