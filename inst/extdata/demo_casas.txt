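2024-01-01 06:32:00.000000 M004 ON
2024-01-01 06:32:05.000000 M004 OFF
2024-01-01 06:48:00.000000 M001 ON
2024-01-01 06:53:00.000000 M001 ON
2024-01-01 07:05:12.000000 T003 21.5
2024-01-01 07:13:00.000000 M001 ON
2024-01-01 07:20:00.000000 M002 ON
2024-01-01 08:13:00.000000 M003 ON
2024-01-01 09:56:00.000000 M001 ON
2024-01-01 09:56:10.000000 M001 OFF
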