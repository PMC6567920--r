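{
  "cohort": {
    "n_referrals": 1000,
    "prevalence": {
      "name": "prevalence",
      "family": "normal",
      "best": 0.32,
      "ci_low": 0.25,
      "ci_high": 0.39,
      "sd": 0.028,
      "mean": 0.32,
      "probability": true
    }
  },
  "tests": {
    "nno": {
      "sensitivity": {
        "name": "nno_sens",
        "family": "beta",
        "best": 0.95,
        "ci_low": 0.91,
        "ci_high": 0.97,
        "mean": 0.95,
        "probability": true
      },
      "specificity": {
        "name": "nno_spec",
        "family": "beta",
        "best": 0.94,
        "ci_low": 0.88,
        "ci_high": 0.97,
        "mean": 0.94,
        "probability": true
      }
    },
    "hsvm": {
      "sensitivity": {
        "name": "hsvm_sens",
        "family": "beta",
        "best": 1,
        "ci_low": 0.89,
        "ci_high": 1,
        "mean": 0.99,
        "probability": true
      },
      "specificity": {
        "name": "hsvm_spec",
        "family": "beta",
        "best": 0.92,
        "ci_low": 0.86,
        "ci_high": 0.96,
        "mean": 0.92,
        "probability": true
      }
    },
    "tem": {
      "sensitivity": {
        "name": "tem_sens",
        "family": "beta",
        "best": 0.74,
        "ci_low": 0.66,
        "ci_high": 0.83,
        "mean": 0.74,
        "probability": true
      },
      "specificity": {
        "name": "tem_spec",
        "family": "beta",
        "best": 0.91,
        "ci_low": 0.86,
        "ci_high": 0.96,
        "mean": 0.91,
        "probability": true
      }
    }
  },
  "costs": {
    "nno_cost": {
      "capital_cost": {
        "name": "nno_capital",
        "family": "gamma",
        "best": 40000,
        "ci_low": 36000,
        "ci_high": 44000,
        "mean": 40000,
        "probability": false
      },
      "equipment_lifespan": {
        "name": "nno_lifespan",
        "family": "normal",
        "best": 15,
        "ci_low": 13,
        "ci_high": 17,
        "sd": 1,
        "mean": 15,
        "probability": false
      },
      "annual_maintenance": {
        "name": "nno_maintenance",
        "family": "gamma",
        "best": 1300,
        "ci_low": 1100,
        "ci_high": 1500,
        "mean": 1300,
        "probability": false
      },
      "consumables": {
        "name": "nno_consumables",
        "family": "gamma",
        "best": 15,
        "ci_low": 9,
        "ci_high": 21,
        "mean": 15,
        "probability": false
      },
      "operator_rate": {
        "name": "nno_operator_rate",
        "family": "gamma",
        "best": 25,
        "ci_low": 10,
        "ci_high": 35,
        "mean": 25,
        "probability": false
      },
      "test_duration": {
        "name": "nno_duration",
        "family": "normal",
        "best": 0.5,
        "ci_low": 0.3,
        "ci_high": 0.7,
        "sd": 0.1,
        "mean": 0.5,
        "probability": false
      },
      "physician_rate": {
        "name": "nno_no_physician",
        "family": "point",
        "best": 0,
        "mean": 0,
        "probability": false
      },
      "sampling_time": {
        "name": "nno_no_sampling",
        "family": "point",
        "best": 0,
        "mean": 0,
        "probability": false
      }
    },
    "hsvm_cost": {
      "capital_cost": {
        "name": "hsvm_capital",
        "family": "gamma",
        "best": 5000,
        "ci_low": 3000,
        "ci_high": 7000,
        "mean": 5000,
        "probability": false
      },
      "equipment_lifespan": {
        "name": "hsvm_lifespan",
        "family": "normal",
        "best": 15,
        "ci_low": 10,
        "ci_high": 20,
        "sd": 2,
        "mean": 15,
        "probability": false
      },
      "annual_maintenance": {
        "name": "hsvm_maintenance",
        "family": "point",
        "best": 0,
        "mean": 0,
        "probability": false
      },
      "consumables": {
        "name": "hsvm_consumables",
        "family": "gamma",
        "best": 30,
        "ci_low": 26,
        "ci_high": 34,
        "mean": 30,
        "probability": false
      },
      "operator_rate": {
        "name": "hsvm_operator_rate",
        "family": "gamma",
        "best": 25,
        "ci_low": 10,
        "ci_high": 35,
        "mean": 25,
        "probability": false
      },
      "test_duration": {
        "name": "hsvm_duration",
        "family": "normal",
        "best": 2,
        "ci_low": 1.6,
        "ci_high": 2.4,
        "sd": 0.2,
        "mean": 2,
        "probability": false
      },
      "physician_rate": {
        "name": "physician_rate",
        "family": "gamma",
        "best": 50,
        "ci_low": 30,
        "ci_high": 70,
        "mean": 50,
        "probability": false
      },
      "sampling_time": {
        "name": "brushing_time",
        "family": "point",
        "best": 0.2,
        "mean": 0.2,
        "probability": false
      }
    },
    "tem_cost": {
      "capital_cost": {
        "name": "tem_capital",
        "family": "gamma",
        "best": 100000,
        "ci_low": 90000,
        "ci_high": 110000,
        "mean": 100000,
        "probability": false
      },
      "equipment_lifespan": {
        "name": "tem_lifespan",
        "family": "normal",
        "best": 30,
        "ci_low": 20,
        "ci_high": 40,
        "sd": 5,
        "mean": 30,
        "probability": false
      },
      "annual_maintenance": {
        "name": "tem_maintenance",
        "family": "gamma",
        "best": 2000,
        "ci_low": 1300,
        "ci_high": 2600,
        "mean": 2000,
        "probability": false
      },
      "consumables": {
        "name": "tem_consumables",
        "family": "gamma",
        "best": 120,
        "ci_low": 90,
        "ci_high": 140,
        "mean": 120,
        "probability": false
      },
      "operator_rate": {
        "name": "tem_operator_rate",
        "family": "gamma",
        "best": 25,
        "ci_low": 10,
        "ci_high": 35,
        "mean": 25,
        "probability": false
      },
      "test_duration": {
        "name": "tem_duration",
        "family": "lognormal",
        "best": 10,
        "ci_low": 6,
        "ci_high": 18,
        "median": 10,
        "gsd": 1.3,
        "mean": 10,
        "probability": false
      },
      "physician_rate": {
        "name": "physician_rate",
        "family": "gamma",
        "best": 50,
        "ci_low": 30,
        "ci_high": 70,
        "mean": 50,
        "probability": false
      },
      "sampling_time": {
        "name": "brushing_time",
        "family": "point",
        "best": 0.2,
        "mean": 0.2,
        "probability": false
      }
    }
  },
  "n_iterations": 3000,
  "seed": 1
}
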