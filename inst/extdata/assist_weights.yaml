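# WHO-ASSIST 3.0 item weights: response level -> integer weight.
# q2: frequency of use in the past 3 months
# q3: frequency of urge to use
# q4: frequency of use leading to health/social/legal/financial problems
# q5: frequency of failing to do what was normally expected (never asked for tobacco)
# q6: friend/relative/other expressed concern about use
# q7: tried and failed to control, cut down or stop using
q2:
  never: 0
  once_or_twice: 2
  monthly: 3
  weekly: 4
  daily_or_almost_daily: 6
q3:
  never: 0
  once_or_twice: 3
  monthly: 4
  weekly: 5
  daily_or_almost_daily: 6
q4:
  never: 0
  once_or_twice: 4
  monthly: 5
  weekly: 6
  daily_or_almost_daily: 7
q5:
  never: 0
  once_or_twice: 5
  monthly: 6
  weekly: 7
  daily_or_almost_daily: 8
q6:
  never: 0
  yes_not_past_3mo: 3
  yes_past_3mo: 6
q7:
  never: 0
  yes_not_past_3mo: 3
  yes_past_3mo: 6
q5_excluded_for: [tobacco]
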