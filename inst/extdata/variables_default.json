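{
  "comment": "Default linguistic variables. Input set counts are 2,4,3,3,6,4,4,2 (full Cartesian grid 2x4x3x3x6x4x4x2 = 13,824 rules). Breakpoints are an in-package design: plateaus and crossovers sit at the scoring-system bin boundaries (PRA 80, age difference 5/15, survival 1/5, pediatric age limits) so that tree-extracted rules stay faithful, and the broad sets carry long inner ramps so every point of each universe has positive membership in some set (no dead zones). Binary inputs (urgency, ABO) are crisp sets expressed through the same trapezoid machinery. Output sets are symmetric separated plateaus centred at 10/30/50/70/90 on the 0-100 point scale, so a clipped set's centroid is its centre at any clip height.",
  "inputs": [
    {
      "name": "medical_urgency",
      "universe": [0, 1],
      "sets": [
        { "name": "not_urgent", "a": 0, "b": 0, "c": 0, "d": 0.5 },
        { "name": "urgent", "a": 0.5, "b": 1, "c": 1, "d": 1 }
      ]
    },
    {
      "name": "pra",
      "universe": [0, 100],
      "sets": [
        { "name": "unsensitized", "a": 0, "b": 0, "c": 0, "d": 40 },
        { "name": "low", "a": 0, "b": 0, "c": 40, "d": 80 },
        { "name": "medium", "a": 30, "b": 60, "c": 70, "d": 95 },
        { "name": "high", "a": 76, "b": 88, "c": 100, "d": 100 }
      ]
    },
    {
      "name": "recipient_age",
      "universe": [0, 80],
      "sets": [
        { "name": "young", "a": 0, "b": 0, "c": 8, "d": 16 },
        { "name": "adolescent", "a": 8, "b": 12, "c": 14, "d": 17 },
        { "name": "adult", "a": 13, "b": 18, "c": 80, "d": 80 }
      ]
    },
    {
      "name": "age_difference",
      "universe": [0, 60],
      "sets": [
        { "name": "small", "a": 0, "b": 0, "c": 4, "d": 8 },
        { "name": "moderate", "a": 3, "b": 6, "c": 13, "d": 18 },
        { "name": "large", "a": 6, "b": 18, "c": 60, "d": 60 }
      ]
    },
    {
      "name": "hla_mismatch",
      "universe": [0, 5],
      "sets": [
        { "name": "mm0", "a": 0, "b": 0, "c": 0, "d": 1 },
        { "name": "mm1", "a": 0, "b": 1, "c": 1, "d": 2 },
        { "name": "mm2", "a": 1, "b": 2, "c": 2, "d": 3 },
        { "name": "mm3", "a": 2, "b": 3, "c": 3, "d": 4 },
        { "name": "mm4", "a": 3, "b": 4, "c": 4, "d": 5 },
        { "name": "mm5", "a": 4, "b": 5, "c": 5, "d": 5 }
      ]
    },
    {
      "name": "waiting_time",
      "universe": [0, 10],
      "sets": [
        { "name": "short", "a": 0, "b": 0, "c": 0.6, "d": 1.6 },
        { "name": "medium", "a": 0, "b": 1.6, "c": 2.6, "d": 3.4 },
        { "name": "long", "a": 1.6, "b": 3.4, "c": 5.3, "d": 6.5 },
        { "name": "very_long", "a": 3.4, "b": 6.5, "c": 10, "d": 10 }
      ]
    },
    {
      "name": "predicted_survival",
      "universe": [0, 20],
      "sets": [
        { "name": "very_poor", "a": 0, "b": 0, "c": 0.4, "d": 1.2 },
        { "name": "poor", "a": 0.4, "b": 1, "c": 1, "d": 5 },
        { "name": "fair", "a": 1, "b": 3, "c": 4, "d": 7 },
        { "name": "good", "a": 4, "b": 6, "c": 20, "d": 20 }
      ]
    },
    {
      "name": "abo",
      "universe": [0, 1],
      "sets": [
        { "name": "compatible", "a": 0, "b": 0, "c": 0, "d": 0.5 },
        { "name": "identical", "a": 0.5, "b": 1, "c": 1, "d": 1 }
      ]
    }
  ],
  "output": {
    "name": "priority",
    "universe": [0, 100],
    "sets": [
      { "name": "very_low", "a": 0, "b": 5, "c": 15, "d": 20 },
      { "name": "low", "a": 20, "b": 25, "c": 35, "d": 40 },
      { "name": "medium", "a": 40, "b": 45, "c": 55, "d": 60 },
      { "name": "high", "a": 60, "b": 65, "c": 75, "d": 80 },
      { "name": "very_high", "a": 80, "b": 85, "c": 95, "d": 100 }
    ]
  }
}
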