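# Home cage change test ethogram: social-behavior categories (10-min session).
# Burrowing is a standalone defensive behavior reported in raw seconds/bouts;
# it is excluded from the relative-measure denominators.
test_type: home_cage_change
session_duration: 600
categories:
  neutral:
    - {behavior: head_head, description: "Head touches the partner's head"}
    - {behavior: nose_side, description: "Sniffing between the partner's ventral region and back"}
    - {behavior: nose_nose, description: "Equal nose-to-nose sniff"}
    - {behavior: passing, description: "Passing the partner in a direct meeting or from behind"}
  dominant:
    - {behavior: head_tail, description: "Head touches the partner's tail"}
    - {behavior: nose_genitals, description: "Nose touches the partner's genitals"}
    - {behavior: following, description: "Following the partner for more than two steps"}
    - {behavior: approaching, description: "Direct approach of more than three steps toward the partner"}
    - {behavior: nuzzling, description: "Sniffing/biting/grooming the partner between nose tip and ventral region"}
    - {behavior: mount1, description: "Rearing with front legs on the partner's back from behind"}
  aggressive:
    - {behavior: mount2, description: "Mounting with copulation movements"}
    - {behavior: chasing, description: "Running after the partner for more than two steps"}
    - {behavior: fight, description: "Rapid rolling, jumping and biting in close contact"}
  submissive:
    - {behavior: avoiding, description: "Moving or facing away from an approaching partner"}
    - {behavior: crawling_under, description: "Crawling under the partner"}
    - {behavior: submissive_posture, description: "Lying on the back under the standing/leaning partner"}
standalone:
  - {behavior: burrowing, description: "Shuffling of bedding in front of and beside the rat (defensive)"}
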