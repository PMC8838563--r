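# Section segmentation and relevance configuration.
# header_patterns are regexes anchored at line starts (multiline mode is added
# by the segmenter). The whitelist holds normalized headers (lowercased,
# trailing colon stripped) of sections relevant to the patient's own medical
# history and current care; family/social history and medication lists are
# deliberately excluded so their content cannot yield valid patient events.
header_patterns:
  - "^[A-Z][A-Z0-9 ,/&'()-]{2,59}:"
whitelist:
  - history of present illness
  - past medical history
  - past surgical history
  - surgical history
  - procedures
  - operations
  - gynecologic history
  - impression
  - report
  - findings
exclude:
  - family history
  - social history
  - allergies
  - medications
include_unknown: true
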