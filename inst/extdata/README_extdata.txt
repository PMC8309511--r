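# simulated z-shape pursuit recording (degrees, 40 Hz); generated by
# gazeparse::simulate_gaze, seed 42
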