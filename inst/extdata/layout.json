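{
  "compartments": ["bedroom", "bedroom2", "living_room", "kitchen", "bathroom"],
  "boxes": [
    {
      "node_id": 1,
      "compartment": "bedroom",
      "placement": "wall"
    },
    {
      "node_id": 2,
      "compartment": "bedroom2",
      "placement": "wall"
    },
    {
      "node_id": 3,
      "compartment": "living_room",
      "placement": "wall"
    },
    {
      "node_id": 4,
      "compartment": "kitchen",
      "placement": "wall"
    },
    {
      "node_id": 5,
      "compartment": "bathroom",
      "placement": "wall"
    },
    {
      "node_id": 6,
      "compartment": "kitchen",
      "placement": "fridge_door"
    },
    {
      "node_id": 7,
      "compartment": "bathroom",
      "placement": "flush_handle"
    }
  ]
}
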