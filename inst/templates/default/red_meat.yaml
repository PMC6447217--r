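component: red_meat
direction: decrease
status: >
  Your red and processed meat intake is at {pct}% of the recommended
  maximum. {contributors}
action: >
  Good job including protein in your diet - try swapping some red or
  processed meat for chicken, fish, beans or lentils a few times a week.
benefit: >
  Eating less red and processed meat is linked with a lower risk of bowel
  cancer and heart disease.
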