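subcategory,n
mayo_missing,92
mayo_partial,49
gold_missing,11
gold_partial,45
both_partial,2
correction_over_time,74
partial_vs_complete,17
biopsy_vs_complete,23
planned_vs_real,5
hysterectomy_vs_hysteroscopy,8
incorrect_laterality,12
typo,5
discussion_vs_real,63
family_vs_patient,11
complex_partial_expression,6
complex_laterality_expression,12
negated_as_positive,10
positive_as_negated,1
positive_as_hypothetical,1
irrelevant_section_header,2
unknown_keywords,15
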