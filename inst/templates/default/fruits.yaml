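component: fruits
direction: increase
status: >
  You are currently eating {pct}% of the recommended amount of fruit.
  {contributors}
action: >
  Try keeping fruit where you can see it and swapping one snack a day for a
  piece of fruit such as an apple, banana or orange.
benefit: >
  Regular fruit intake supplies fibre, potassium and vitamin C and is
  associated with better heart health and a lower risk of some cancers.
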