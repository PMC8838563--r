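# Default surgery concept lexicon. Token-level surface patterns, all lowercase;
# hyphen/slash compounds are single tokens (tah-bso, salpingo-oophorectomy).
# Exclusion tokens veto any match found within `window` tokens of the match.
concepts:
  hysterectomy:
    patterns:
      - hysterectomy
      - total abdominal hysterectomy
      - total vaginal hysterectomy
      - total laparoscopic hysterectomy
      - supracervical hysterectomy
      - partial hysterectomy
      - subtotal hysterectomy
      - vaginal hysterectomy
      - laparoscopic hysterectomy
      - abdominal hysterectomy
      - tah
      - tvh
      - lavh
      - removal of the uterus
      - removal of uterus
  oophorectomy:
    patterns:
      - oophorectomy
      - ovariectomy
      - salpingo-oophorectomy
      - salpingo oophorectomy
      - oophorectomies
      - lso
      - rso
      - uso
      - removal of the left ovary
      - removal of the right ovary
      - removal of left ovary
      - removal of right ovary
      - removal of the remaining ovary
      - removal of remaining ovary
      - ovary removed
      - ovary was removed
      - ovaries removed
      - ovaries were removed
  bilateral_oophorectomy:
    patterns:
      - bilateral salpingo-oophorectomy
      - bilateral salpingo oophorectomy
      - bilateral oophorectomy
      - bilateral ovariectomy
      - bso
      - removal of both ovaries
  hysterectomy_bso_combined:
    patterns:
      - tah-bso
      - tah/bso
      - tah bso
      - tvh-bso
      - tvh/bso
      - lavh-bso
exclusions:
  window: 3
  tokens:
    - hysteroscopy
    - hysteroscopic
    - oophoropexy
    - biopsy
    - biopsies
    - cystectomy
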