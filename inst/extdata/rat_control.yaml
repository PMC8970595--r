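# Paced rat left ventricle, control conditions; raw SNR calibrated to 1.4.
scenario: rat_control
pcl: 150
rows: 200
cols: 200
duration_ms: 2000
frame_rate: 977
seed: 1
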