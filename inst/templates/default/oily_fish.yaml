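component: oily_fish
direction: increase
status: >
  You are currently eating {pct}% of the recommended amount of oily fish.
  {contributors}
action: >
  Aim for one to two portions of oily fish a week, such as salmon, mackerel,
  sardines or trout - tinned counts too.
benefit: >
  Oily fish is the best dietary source of long-chain omega-3 fats, which
  support a healthy heart and circulation.
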