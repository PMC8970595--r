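# Paced mouse left ventricle, control conditions.
# 200x200 px @ 977 FPS, 2 s, PCL 150 ms; raw SNR calibrated to 0.5.
scenario: mouse_control
pcl: 150
rows: 200
cols: 200
duration_ms: 2000
frame_rate: 977
seed: 1
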