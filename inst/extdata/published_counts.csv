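measure,numerator,n_missing,denominator,source
any_substance_use,747,40,NA,"one substance only (298) + polydrug (449); missing = polysubstance rows"
alcohol_use,665,48,NA,"alcohol use row"
tobacco_use,351,52,NA,"tobacco use row"
illicit_use,324,45,NA,"illicit substance use row (ATS, cannabis, cocaine, hallucinogens, opioids)"
cocaine_use,35,57,NA,"cocaine use row"
cannabis_in_ats_group,59,0,84,"cannabis users within the ATS-use group"
urge_to_use,559,40,NA,"urge to use at least one substance"
polydrug_use,449,40,NA,"more than one substance incl. tobacco and alcohol"
daily_smoker_cannabis_couse,114,0,166,"daily tobacco smokers who also used cannabis"
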