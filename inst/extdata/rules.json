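{
  "rules": [
    {
      "id": "sleeping",
      "target": "sleeping",
      "compartment": "bedroom",
      "priority": 1,
      "duration_min_s": 3600,
      "duration_max_s": 43200,
      "predicates": [
        {
          "feature": "mean_luminance",
          "op": "<=",
          "value": 25
        },
        {
          "feature": "motion_density",
          "op": "<=",
          "value": 0.35
        }
      ]
    },
    {
      "id": "grooming_shower",
      "target": "grooming",
      "compartment": "bathroom",
      "priority": 2,
      "duration_min_s": 600,
      "duration_max_s": 3600,
      "predicates": [
        {
          "feature": "delta_humidity",
          "op": ">=",
          "value": 3
        }
      ]
    },
    {
      "id": "getting_ready_for_bed",
      "target": "getting_ready_for_bed",
      "compartment": "bathroom",
      "priority": 3,
      "duration_min_s": 120,
      "duration_max_s": 1200,
      "predicates": [
        {
          "feature": "mean_luminance",
          "op": ">=",
          "value": 25
        }
      ],
      "requires_fact": {
        "label": "sleeping",
        "relation": "starts_within_after",
        "lag_s": 1800
      }
    },
    {
      "id": "toileting",
      "target": "toileting",
      "compartment": "bathroom",
      "priority": 4,
      "duration_min_s": 120,
      "duration_max_s": 900,
      "predicates": [
        {
          "feature": "n_transients",
          "op": ">=",
          "value": 1
        },
        {
          "feature": "abs_delta_humidity",
          "op": "<",
          "value": 2
        },
        {
          "feature": "abs_delta_temperature",
          "op": "<",
          "value": 1
        },
        {
          "feature": "mean_luminance",
          "op": ">=",
          "value": 25
        }
      ]
    },
    {
      "id": "cooking",
      "target": "cooking",
      "compartment": "kitchen",
      "priority": 5,
      "duration_min_s": 600,
      "duration_max_s": 5400,
      "predicates": [
        {
          "feature": "n_transients",
          "op": ">=",
          "value": 1
        },
        {
          "feature": "delta_temperature",
          "op": ">=",
          "value": 0.5
        }
      ]
    },
    {
      "id": "eating_after_cooking",
      "target": "eating",
      "compartment": "kitchen",
      "priority": 6,
      "duration_min_s": 600,
      "duration_max_s": 3600,
      "predicates": [
        {
          "feature": "n_transients",
          "op": "==",
          "value": 0
        },
        {
          "feature": "motion_density",
          "op": "<=",
          "value": 0.95
        }
      ],
      "requires_fact": {
        "label": "cooking",
        "relation": "ends_within_before",
        "lag_s": 2700
      }
    },
    {
      "id": "watching_tv",
      "target": "watching_tv",
      "compartment": "living_room",
      "priority": 7,
      "duration_min_s": 1200,
      "duration_max_s": 14400,
      "predicates": [
        {
          "feature": "mean_luminance",
          "op": "in_range",
          "value": [25, 90]
        },
        {
          "feature": "tod_mid",
          "op": "in_range",
          "value": [66600, 86100]
        },
        {
          "feature": "motion_density",
          "op": "<=",
          "value": 0.6
        }
      ]
    },
    {
      "id": "seated_activity",
      "target": "seated_activity",
      "compartment": "living_room",
      "priority": 8,
      "duration_min_s": 1200,
      "duration_max_s": 14400,
      "predicates": [
        {
          "feature": "tod_mid",
          "op": "in_range",
          "value": [25200, 68400]
        },
        {
          "feature": "mean_luminance",
          "op": ">",
          "value": 90
        },
        {
          "feature": "motion_density",
          "op": "<=",
          "value": 0.95
        }
      ]
    },
    {
      "id": "eating_standalone",
      "target": "eating",
      "compartment": "kitchen",
      "priority": 9,
      "duration_min_s": 900,
      "duration_max_s": 3600,
      "predicates": [
        {
          "feature": "n_transients",
          "op": "==",
          "value": 0
        },
        {
          "feature": "abs_delta_temperature",
          "op": "<",
          "value": 0.5
        },
        {
          "feature": "motion_density",
          "op": "<=",
          "value": 0.95
        }
      ]
    },
    {
      "id": "grooming_dry",
      "target": "grooming",
      "compartment": "bathroom",
      "priority": 10,
      "duration_min_s": 1080,
      "duration_max_s": 3600,
      "predicates": [
        {
          "feature": "mean_luminance",
          "op": ">=",
          "value": 25
        },
        {
          "feature": "abs_delta_humidity",
          "op": "<",
          "value": 3
        }
      ]
    }
  ]
}
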