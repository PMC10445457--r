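job_id,temperature_C,residence_time_s,mode,led_power
short1,80,600,thermal,
short2,80,120,thermal,
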