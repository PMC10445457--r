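job_id,temperature_C,residence_time_s,mode,led_power
long1,80,1800,thermal,
long2,80,1200,thermal,
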