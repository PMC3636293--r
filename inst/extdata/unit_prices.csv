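category,unit_price,price_year,source
general_practitioner,28,2009,standard
medical_specialist,72,2009,standard
hospital,457,2009,standard
alternative_healer,50,2009,lowest
mental_health,94,2009,standard
medication,47.48,2009,real_cost
medical_aids,20,2009,tariff
other_care,30,2009,lowest
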