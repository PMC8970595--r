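# Paced mouse left ventricle with an APD-prolonging K+ channel blocker
# (emulated as a +19 ms APD80 increment).
scenario: mouse_4ap
pcl: 150
rows: 200
cols: 200
duration_ms: 2000
frame_rate: 977
seed: 1
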