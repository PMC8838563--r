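# Sentence template bank for the synthetic EHR generator. Placeholders:
#   {date_phrase}  rendered date ("on 03/12/1994", "on 03/12/94", "in 1994"),
#                  an age phrase ("at age 41"), or empty
#   {side}         "left" or "right"
#   {concept}      a surgery word used in distractor sentences
# Kinds map one-to-one onto the information-gap taxonomy the generator injects.
hyst_pos:
  - "She underwent a total abdominal hysterectomy {date_phrase}."
  - "Status post hysterectomy {date_phrase}."
  - "s/p TAH {date_phrase}."
  - "History of hysterectomy {date_phrase}."
  - "Patient had a vaginal hysterectomy {date_phrase}."
  - "s/p total abdominal hysterectomy {date_phrase}."
  - "Supracervical hysterectomy performed {date_phrase}."
  - "She is status post abdominal hysterectomy {date_phrase}."
ooph_side_pos:
  - "She underwent a {side} salpingo-oophorectomy {date_phrase}."
  - "Status post {side} oophorectomy {date_phrase}."
  - "s/p {side} salpingo-oophorectomy {date_phrase}."
  - "The {side} ovary was removed {date_phrase}."
  - "History of {side} oophorectomy {date_phrase}."
  - "Oophorectomy on the {side} side {date_phrase}."
ooph_unspec_pos:
  - "Status post oophorectomy {date_phrase}."
  - "She underwent oophorectomy {date_phrase}."
  - "History of ovariectomy {date_phrase}."
bso_pos:
  - "She underwent bilateral salpingo-oophorectomy {date_phrase}."
  - "Status post BSO {date_phrase}."
  - "s/p bilateral oophorectomy {date_phrase}."
  - "Both ovaries were removed {date_phrase}."
  - "Bilateral oophorectomy performed {date_phrase}."
tahbso_pos:
  - "s/p TAH-BSO {date_phrase}."
  - "She underwent TAH-BSO {date_phrase}."
  - "Status post TAH/BSO {date_phrase}."
negation:
  - "No history of {concept}."
  - "She denies any {concept}."
  - "She has never had a {concept}."
  - "No prior {concept}."
family:
  - "Her mother had a {concept} at age 45."
  - "Family history significant for {concept}."
  - "Sister underwent {concept}."
  - "Her mother is status post {concept}."
confusable:
  - "She underwent hysteroscopy {date_phrase}."
  - "Diagnostic hysteroscopy was performed."
  - "Endometrial biopsy was performed {date_phrase}."
  - "Ovarian biopsy obtained."
  - "Cervical biopsy performed."
discussion:
  - "We discussed the possibility of {concept}."
  - "Options including {concept} were discussed."
  - "She is considering {concept}."
  - "Risks and benefits of {concept} were discussed."
planned:
  - "She is scheduled for {concept} next month."
  - "Planned {concept}."
  - "{concept} is scheduled for next week."
filler:
  - "Vital signs stable."
  - "She reports feeling well overall."
  - "Follow up in 6 months."
  - "Medications reviewed and reconciled."
  - "No acute distress."
  - "Screening mammogram reviewed."
  - "Blood pressure well controlled."
  - "Patient counseled on diet and exercise."
  - "Annual examination unremarkable."
  - "Labs within normal limits."
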