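# Assertion cue lists (NegEx/ConText style). Cues are token sequences searched
# in a window of `window` tokens on either side of a concept mention; the scan
# stops at scope breakers. Precedence when several classes fire:
# negated > family > hypothetical > planned > positive (default).
window: 6
scope_breakers: ["but", "however", ";", "."]
negation:
  pre: ["no", "not", denies, denied, denying, never, without, negative, none,
        declined, refused]
  post: [not performed, never performed, was not performed, ruled out]
family:
  pre: &kin [mother, mothers, father, fathers, sister, sisters, brother,
        grandmother, grandfather, aunt, uncle, daughter, son, niece, nephew,
        cousin, maternal, paternal, family, familial]
  post: *kin
hypothetical:
  pre: &hyp [discussed, discussing, discussion, consider, considered,
        considering, possibility, possible, option, options, counseled,
        counseling, whether, versus, elect, electing, candidate]
  post: *hyp
planned:
  pre: &plan [scheduled, planned, planning, plans, upcoming, anticipate,
        anticipated, pending]
  post: *plan
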