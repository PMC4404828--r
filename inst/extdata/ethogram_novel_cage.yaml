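# Novel cage test ethogram: coping-style categories (5-min session).
test_type: novel_cage
session_duration: 300
categories:
  proactive:
    - {behavior: stretched_approach, description: "Walking with a flat, stretched body posture close to the floor"}
    - {behavior: sap, description: "Stretched attend posture: forward stretch with four paws planted, then retract"}
    - {behavior: grooming, description: "Scratching, shaking, wiping or licking body parts"}
  reactive:
    - {behavior: freezing, description: "Sudden suppression of movements"}
    - {behavior: motionless, description: "Sitting or lying still without suppression of movements"}
  exploratory:
    - {behavior: free_rearing, description: "Standing on hind legs without wall support"}
    - {behavior: investigating, description: "Olfactory exploration of floor, walls or air"}
  locomotor:
    - {behavior: wall_rearing, description: "Standing on hind legs with forepaws against a wall"}
    - {behavior: walking, description: "Locomotion with normal body posture"}
standalone: []
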