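{
  "floating_objects": [
    {
      "name": "a",
      "radius": 0.05,
      "mobility": 0.4,
      "env_concentration": 0.25
    },
    {
      "name": "s",
      "radius": 0.05,
      "mobility": 0.35,
      "env_concentration": 0
    }
  ],
  "glue_relation": [
    ["wall", "wall"],
    ["rim1", "rim1"],
    ["rim2", "rim2"],
    ["septum", "septum"],
    ["scafA", "scafA"],
    ["scafB", "scafB"],
    ["scafC", "scafC"]
  ],
  "tiles": [
    {
      "name": "cap",
      "shape": {
        "kind": "polygon2D",
        "vertices": [
          [1.30656296487638, 0, 0],
          [0.923879532511287, 0.923879532511287, 0],
          [8.00039076410165e-17, 1.30656296487638, 0],
          [-0.923879532511287, 0.923879532511287, 0],
          [-1.30656296487638, 1.60007815282033e-16, 0],
          [-0.923879532511287, -0.923879532511287, 0],
          [-2.4001172292305e-16, -1.30656296487638, 0],
          [0.923879532511287, -0.923879532511287, 0]
        ]
      },
      "connectors": [
        {
          "site": [
            [0.5, -1.20710678118655, 0]
          ],
          "glue": "wall",
          "attach_angle": 3.14159265358979
        }
      ],
      "protions": []
    },
    {
      "name": "sideA",
      "shape": {
        "kind": "polygon2D",
        "vertices": [
          [1.30656296487638, 0, 0],
          [0.923879532511287, 0.923879532511287, 0],
          [8.00039076410165e-17, 1.30656296487638, 0],
          [-0.923879532511287, 0.923879532511287, 0],
          [-1.30656296487638, 1.60007815282033e-16, 0],
          [-0.923879532511287, -0.923879532511287, 0],
          [-2.4001172292305e-16, -1.30656296487638, 0],
          [0.923879532511287, -0.923879532511287, 0]
        ]
      },
      "connectors": [
        {
          "site": [
            [0.5, -1.20710678118655, 0]
          ],
          "glue": "rim1",
          "attach_angle": 3.14159265358979
        }
      ],
      "protions": [
        {
          "name": "pch",
          "site": [0, 0, 0]
        }
      ]
    },
    {
      "name": "sideB",
      "shape": {
        "kind": "polygon2D",
        "vertices": [
          [1.30656296487638, 0, 0],
          [0.923879532511287, 0.923879532511287, 0],
          [8.00039076410165e-17, 1.30656296487638, 0],
          [-0.923879532511287, 0.923879532511287, 0],
          [-1.30656296487638, 1.60007815282033e-16, 0],
          [-0.923879532511287, -0.923879532511287, 0],
          [-2.4001172292305e-16, -1.30656296487638, 0],
          [0.923879532511287, -0.923879532511287, 0]
        ]
      },
      "connectors": [
        {
          "site": [
            [0.5, -1.20710678118655, 0]
          ],
          "glue": "rim2",
          "attach_angle": 3.14159265358979
        }
      ],
      "protions": [
        {
          "name": "pch",
          "site": [0, 0, 0]
        }
      ]
    },
    {
      "name": "septum_face",
      "shape": {
        "kind": "polygon2D",
        "vertices": [
          [1.30656296487638, 0, 0],
          [0.923879532511287, 0.923879532511287, 0],
          [8.00039076410165e-17, 1.30656296487638, 0],
          [-0.923879532511287, 0.923879532511287, 0],
          [-1.30656296487638, 1.60007815282033e-16, 0],
          [-0.923879532511287, -0.923879532511287, 0],
          [-2.4001172292305e-16, -1.30656296487638, 0],
          [0.923879532511287, -0.923879532511287, 0]
        ]
      },
      "connectors": [
        {
          "site": [
            [0.5, -1.20710678118655, 0]
          ],
          "glue": "septum",
          "attach_angle": 3.14159265358979
        }
      ],
      "protions": []
    },
    {
      "name": "rod_seed",
      "shape": {
        "kind": "rod1D",
        "vertices": [
          [0, 0, 0],
          [0.6, 0, 0]
        ]
      },
      "connectors": [
        {
          "site": [
            [0, 0, 0]
          ],
          "glue": "scafA",
          "attach_angle": 3.14159265358979
        }
      ],
      "protions": []
    },
    {
      "name": "rod_arm",
      "shape": {
        "kind": "rod1D",
        "vertices": [
          [0, 0, 0],
          [0.6, 0, 0]
        ]
      },
      "connectors": [
        {
          "site": [
            [0, 0, 0]
          ],
          "glue": "scafB",
          "attach_angle": 3.14159265358979
        }
      ],
      "protions": []
    },
    {
      "name": "rod_bridge",
      "shape": {
        "kind": "rod1D",
        "vertices": [
          [0, 0, 0],
          [0.6, 0, 0]
        ]
      },
      "connectors": [
        {
          "site": [
            [0, 0, 0]
          ],
          "glue": "scafC",
          "attach_angle": 3.14159265358979
        }
      ],
      "protions": []
    }
  ],
  "rules": [
    {
      "kind": "metabolic",
      "protion": "pch",
      "consumed": "a",
      "produced": ["a", "s"],
      "consumed_side": "out",
      "produced_side": "in"
    },
    {
      "kind": "creation",
      "tile": "sideA",
      "at_glue": "rim1",
      "consumed": "a",
      "side": "out",
      "guard": "none"
    },
    {
      "kind": "creation",
      "tile": "sideB",
      "at_glue": "rim2",
      "consumed": "a",
      "side": "out",
      "guard": "none"
    },
    {
      "kind": "creation",
      "tile": "rod_seed",
      "at_glue": "scafA",
      "consumed": "s",
      "side": "in",
      "guard": "none"
    },
    {
      "kind": "creation",
      "tile": "rod_arm",
      "at_glue": "scafB",
      "consumed": "s",
      "side": "in",
      "guard": "none"
    },
    {
      "kind": "creation",
      "tile": "rod_bridge",
      "at_glue": "scafC",
      "consumed": "s",
      "side": "in",
      "guard": "none"
    },
    {
      "kind": "creation",
      "tile": "septum_face",
      "at_glue": "septum",
      "consumed": ["a", "a"],
      "side": "in",
      "guard": "none"
    },
    {
      "kind": "destruction",
      "tile": ["rod_seed", "rod_arm", "rod_bridge"],
      "consumed": [],
      "produced": [],
      "guard": "septum_complete"
    },
    {
      "kind": "division",
      "trigger": "septum_complete"
    }
  ],
  "environment": {
    "bounds": {
      "lower": [-6, -6, -6],
      "upper": [6, 6, 6]
    },
    "nutrient_budget": {
      "a": 1120
    },
    "interaction_radius": 1
  },
  "seed_tiles": [
    {
      "tile": "cap",
      "pose": {
        "position": [0, 0, 0],
        "quaternion": [1, 0, 0, 0]
      }
    }
  ],
  "template": {
    "name": "capsule",
    "interior_radius": 1.5,
    "leak_rate": 0.4,
    "rebond_rate": 0.16
  }
}
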