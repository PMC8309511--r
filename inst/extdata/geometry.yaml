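width_px: 1920
height_px: 1080
physical_width_mm: 510.0
physical_height_mm: 287.0
viewing_distance_mm: 600.0
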