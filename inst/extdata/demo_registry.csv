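sensor_id,certainty,room
M001,0.6,living
M002,0.9,kitchen
M003,0.3,bath
M004,0.8,bedroom
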