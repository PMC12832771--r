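analysis,country,dcost,dqaly,icer_published
base,US,86403.43,0.68,127063.87
base,China,35358.47,0.94,37615.40
pfs_only,US,393154.85,0.39,1008089.36
pfs_only,China,81806.42,0.63,129851.46
pfs_investigator,US,114710.87,1.39,82739.12
pfs_investigator,China,34852.17,1.68,20745.34
exclude_ae_disutility,US,86403.43,0.69,124748.49
exclude_ae_disutility,China,35358.47,0.96,36831.74
horizon_4y,US,149277.68,0.20,746388.38
horizon_4y,China,53085.06,0.33,162977.03
horizon_5y,US,131851.71,0.30,439505.70
horizon_5y,China,50325.03,0.52,97176.97
horizon_10y,US,95079.62,0.61,155446.36
horizon_10y,China,45116.30,0.93,48512.15
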