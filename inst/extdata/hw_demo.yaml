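# Demonstration hardware timing for a two-reactor droplet platform.
# Stage durations are deployment-specific and therefore required fields.
n_reactors: 2
t_prep: 300        # liquid-handler droplet preparation, s
t_transit_in: 30   # liquid handler -> reactor (main flowpath), s
t_rinse_a: 60      # flowpath-only rinse/vent after inbound transit, s
t_transit_out: 30  # reactor -> HPLC sampling valve (main flowpath), s
t_rinse_b: 60      # flowpath + reactor rinse/vent after outbound transit, s
t_hplc: 240        # HPLC analysis, s
time_unit: 1       # scheduler shift granularity, s
temp_min: 0
temp_max: 200
heat_rate: 1.0     # degC per s
cool_rate: 0.1     # degC per s
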