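# Maintenance daily-dose band table for intravenous colistimethate,
# transcribed from the 2017 population-pharmacokinetic dosing guidance for
# colistin in critically ill patients (Nation et al., Clin Infect Dis 2017,
# 64:565-571). The published table lists mg CBA/day to achieve a target
# colistin Css,avg of 2 mg/L by creatinine-clearance band; cba_per_css below
# is that value divided by 2 (mg CBA/day per mg/L of target), since the daily
# dose scales linearly in the target concentration.
#
# Bands are exclusive upper bounds on CrCl (mL/min); the last band is
# unbounded. Review against the publication before clinical use.
name: nation2017
interpolate: false
max_daily_cba: 300
bands:
  - {crcl_upper: 5,    cba_per_css: 65.0}   # CrCl [0, 5):   130 mg/day at 2 mg/L
  - {crcl_upper: 10,   cba_per_css: 72.5}   # [5, 10):  145
  - {crcl_upper: 20,   cba_per_css: 80.0}   # [10, 20): 160
  - {crcl_upper: 30,   cba_per_css: 87.5}   # [20, 30): 175
  - {crcl_upper: 40,   cba_per_css: 97.5}   # [30, 40): 195
  - {crcl_upper: 50,   cba_per_css: 110.0}  # [40, 50): 220
  - {crcl_upper: 60,   cba_per_css: 122.5}  # [50, 60): 245
  - {crcl_upper: 70,   cba_per_css: 137.5}  # [60, 70): 275
  - {crcl_upper: 80,   cba_per_css: 150.0}  # [70, 80): 300
  - {crcl_upper: 90,   cba_per_css: 170.0}  # [80, 90): 340
  - {crcl_upper: .inf, cba_per_css: 180.0}  # >= 90:    360
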