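{
  "schema_version": "1.0",
  "areas": ["I1", "I2", "I3", "I4", "I5", "I6", "I7", "I8", "I9"],
  "temp_hospitals": ["J1", "J2", "J3", "J4", "J5"],
  "general_hospitals": ["K1", "K2", "K3"],
  "casualties": [
    {
      "area": "I1",
      "severity": "serious",
      "count": 59
    },
    {
      "area": "I1",
      "severity": "moderate",
      "count": 143
    },
    {
      "area": "I2",
      "severity": "serious",
      "count": 21
    },
    {
      "area": "I2",
      "severity": "moderate",
      "count": 48
    },
    {
      "area": "I3",
      "severity": "serious",
      "count": 23
    },
    {
      "area": "I3",
      "severity": "moderate",
      "count": 71
    },
    {
      "area": "I4",
      "severity": "serious",
      "count": 29
    },
    {
      "area": "I4",
      "severity": "moderate",
      "count": 116
    },
    {
      "area": "I5",
      "severity": "serious",
      "count": 20
    },
    {
      "area": "I5",
      "severity": "moderate",
      "count": 59
    },
    {
      "area": "I6",
      "severity": "serious",
      "count": 70
    },
    {
      "area": "I6",
      "severity": "moderate",
      "count": 153
    },
    {
      "area": "I7",
      "severity": "serious",
      "count": 12
    },
    {
      "area": "I7",
      "severity": "moderate",
      "count": 46
    },
    {
      "area": "I8",
      "severity": "serious",
      "count": 16
    },
    {
      "area": "I8",
      "severity": "moderate",
      "count": 71
    },
    {
      "area": "I9",
      "severity": "serious",
      "count": 5
    },
    {
      "area": "I9",
      "severity": "moderate",
      "count": 23
    }
  ],
  "road_times": {
    "I1": {
      "J1": 1.25,
      "J2": 0.8,
      "J3": 1.2,
      "J4": 0.95,
      "J5": 0.875
    },
    "I2": {
      "J1": 0.575,
      "J2": 0.525,
      "J3": 0.65,
      "J4": 0.525,
      "J5": 0.45
    },
    "I3": {
      "J1": 1.025,
      "J2": 0.825,
      "J3": 1.1,
      "J4": 0.975,
      "J5": 0.775
    },
    "I4": {
      "J1": 1.325,
      "J2": 0.975,
      "J3": 1.375,
      "J4": 1.125,
      "J5": 1.05
    },
    "I5": {
      "J1": 1.475,
      "J2": 1.125,
      "J3": 1.525,
      "J4": 1.3,
      "J5": 1.2
    },
    "I6": {
      "J1": 1.525,
      "J2": 1.175,
      "J3": 1.575,
      "J4": 1.35,
      "J5": 1.25
    },
    "I7": {
      "J1": 1.75,
      "J2": 1.375,
      "J3": 1.675,
      "J4": 1.55,
      "J5": 1.45
    },
    "I8": {
      "J1": 1.725,
      "J2": 1.525,
      "J3": 1.875,
      "J4": 1.825,
      "J5": 1.6
    },
    "I9": {
      "J1": 2.45,
      "J2": 2.25,
      "J3": 2.45,
      "J4": 2.4,
      "J5": 2.325
    }
  },
  "air_times": {
    "J1": {
      "K1": 0.57,
      "K2": 0.71,
      "K3": 0.59
    },
    "J2": {
      "K1": 0.63,
      "K2": 0.73,
      "K3": 0.61
    },
    "J3": {
      "K1": 0.57,
      "K2": 0.71,
      "K3": 0.59
    },
    "J4": {
      "K1": 0.6,
      "K2": 0.7,
      "K3": 0.58
    },
    "J5": {
      "K1": 0.58,
      "K2": 0.71,
      "K3": 0.59
    }
  },
  "fleet": {
    "vehicles": 280,
    "helicopters": 150,
    "vehicle_capacity": 6,
    "helicopter_capacity": 12
  },
  "capacities": {
    "temp": {
      "J1": 500,
      "J2": 500,
      "J3": 500,
      "J4": 500,
      "J5": 500
    },
    "general": {
      "K1": {
        "serious": 250,
        "moderate": 350
      },
      "K2": {
        "serious": 200,
        "moderate": 300
      },
      "K3": {
        "serious": 200,
        "moderate": 500
      }
    }
  },
  "severity_params": {
    "serious": {
      "label": "serious",
      "urgency_weight": 2,
      "base_deterioration": 0.8
    },
    "moderate": {
      "label": "moderate",
      "urgency_weight": 1,
      "base_deterioration": 0.2
    }
  },
  "post_treatment_factor": 0.2
}
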