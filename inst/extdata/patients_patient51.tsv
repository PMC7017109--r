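patient_id	diagnosis	age_years	age_class
P51	breast carcinoma	38	adult
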